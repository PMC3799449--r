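# Deterministic toy references and truth-perturbed SAM files. The fixtures
# emulate the two structures that attract mismapped reads in real data —
# multi-exon transcripts (junction-spanning reads) and paralogous gene pairs
# (high sequence similarity) — so every pipeline stage is testable without
# an external aligner.

#' Specification for a toy reference
#'
#' @param seed RNG seed; all fixture output is a pure function of the spec.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes genes per chromosome.
#' @param exons_per_gene exons per gene (>= 2 so junction reads exist).
#' @param exon_length exon length in bp.
#' @param intron_length intron length in bp.
#' @param paralog_pairs number of paralogous gene pairs (consecutive genes
#'   on the same chromosome are paired; the second member's locus is
#'   overwritten with a diverged copy of the first).
#' @param divergence per-base substitution probability between paralog pair
#'   members (0 = identical copies).
#' @param snp_count number of random exonic SNPs in the generated SNP table.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 2L, chrom_length = 10000L,
                         n_genes = 4L, exons_per_gene = 3L,
                         exon_length = 80L, intron_length = 150L,
                         paralog_pairs = 1L, divergence = 0.05,
                         snp_count = 10L) {
  stopifnot(n_chroms >= 1L, n_genes >= 0L, exons_per_gene >= 1L,
            divergence >= 0, divergence <= 1, snp_count >= 0L,
            paralog_pairs >= 0L)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 paralog_pairs = as.integer(paralog_pairs),
                 divergence = divergence, snp_count = as.integer(snp_count)),
            class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  offs <- sort(sample.int(n, k))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (o in offs) {
    chars[o] <- sample(setdiff(DNA_BASES, chars[o]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a deterministic toy reference
#'
#' Lays `n_genes` multi-exon genes per chromosome on random sequence, makes
#' `paralog_pairs` of them paralogous (the partner locus is a copy of the
#' source locus mutated at `divergence` per base), and draws a table of
#' exonic SNPs. Byte-identical across runs for a fixed spec; the caller's
#' RNG state is untouched.
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (a `genome_ref`), `transcripts` (named list of
#'   [transcript_model()]), `paralogs` (two-column data frame of paired gene
#'   ids), `snps` (`chrom`, `pos` 1-based, `ref`, `alt`) and `spec`.
#' @export
make_toy_reference <- function(spec) {
  gene_span <- spec$exons_per_gene * spec$exon_length +
    (spec$exons_per_gene - 1L) * spec$intron_length
  gap <- 100L
  need <- gap + spec$n_genes * (gene_span + gap)
  if (need > spec$chrom_length) {
    stop("infeasible geometry: ", spec$n_genes, " gene(s) of span ",
         gene_span, " bp exceed chromosome length ", spec$chrom_length)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  chroms <- paste0("chr", seq_len(spec$n_chroms))
  genome <- vapply(chroms, function(c) random_dna(spec$chrom_length),
                   character(1))
  transcripts <- list()
  strands <- c("+", "-")
  for (ci in seq_len(spec$n_chroms)) {
    offset <- gap
    for (gi in seq_len(spec$n_genes)) {
      starts <- offset + (seq_len(spec$exons_per_gene) - 1L) *
        (spec$exon_length + spec$intron_length)
      blocks <- cbind(starts, starts + spec$exon_length)
      id <- paste0("gene", ci, "_", gi)
      transcripts[[id]] <- transcript_model(
        id, chroms[ci], strands[(gi - 1L) %% 2L + 1L], blocks)
      offset <- offset + gene_span + gap
    }
  }

  # Paralog pairs: gene (2k) on chr1 becomes a diverged copy of gene (2k-1).
  paralogs <- data.frame(gene_a = character(0), gene_b = character(0),
                         stringsAsFactors = FALSE)
  ids <- names(transcripts)
  pair_i <- 0L
  k <- 1L
  while (pair_i < spec$paralog_pairs && k + 1L <= length(ids)) {
    a <- transcripts[[ids[k]]]
    b <- transcripts[[ids[k + 1L]]]
    if (a$chrom == b$chrom &&
        sum(a$blocks[, 2L] - a$blocks[, 1L]) ==
        sum(b$blocks[, 2L] - b$blocks[, 1L])) {
      span_a <- substr(genome[[a$chrom]], min(a$blocks) + 1L, max(a$blocks))
      span_b <- mutate_dna(span_a, spec$divergence)
      g <- genome[[b$chrom]]
      genome[[b$chrom]] <- paste0(substr(g, 1L, min(b$blocks)),
                                  span_b,
                                  substr(g, max(b$blocks) + 1L, nchar(g)))
      # copy a's strand so the duplicated locus reads identically
      transcripts[[ids[k + 1L]]]$strand <- a$strand
      paralogs <- rbind(paralogs,
                        data.frame(gene_a = a$id, gene_b = b$id,
                                   stringsAsFactors = FALSE))
      pair_i <- pair_i + 1L
    }
    k <- k + 2L
  }

  snps <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     stringsAsFactors = FALSE)
  if (spec$snp_count > 0L && length(transcripts) > 0L) {
    for (i in seq_len(spec$snp_count)) {
      t <- transcripts[[sample.int(length(transcripts), 1L)]]
      bi <- sample.int(nrow(t$blocks), 1L)
      p0 <- t$blocks[bi, 1L] + sample.int(t$blocks[bi, 2L] - t$blocks[bi, 1L], 1L) - 1L
      ref <- substr(genome[[t$chrom]], p0 + 1L, p0 + 1L)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      snps <- rbind(snps, data.frame(chrom = t$chrom, pos = p0 + 1L,
                                     ref = ref, alt = alt,
                                     stringsAsFactors = FALSE))
    }
    snps <- unique(snps[order(snps$chrom, snps$pos), , drop = FALSE])
    rownames(snps) <- NULL
  }
  class(genome) <- c("genome_ref", class(genome))
  list(genome = genome, transcripts = transcripts, paralogs = paralogs,
       snps = snps, spec = spec)
}

#' Write a toy reference to disk
#'
#' Emits `genome.fa`, `transcripts.bed` (BED12), `paralogs.tsv` and
#' `snps.tsv` under `dir`.
#'
#' @param ref output of [make_toy_reference()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_toy_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(unclass(ref$genome))
  Biostrings::writeXStringSet(seqs, fa)
  bed <- file.path(dir, "transcripts.bed")
  lines <- vapply(ref$transcripts, function(t) {
    cs <- min(t$blocks); ce <- max(t$blocks)
    sizes <- paste(t$blocks[, 2L] - t$blocks[, 1L], collapse = ",")
    starts <- paste(t$blocks[, 1L] - cs, collapse = ",")
    paste(t$chrom, cs, ce, t$id, 0L, t$strand, cs, ce, "0",
          nrow(t$blocks), sizes, starts, sep = "\t")
  }, character(1))
  writeLines(lines, bed)
  par <- file.path(dir, "paralogs.tsv")
  utils::write.table(ref$paralogs, par, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  snp <- file.path(dir, "snps.tsv")
  utils::write.table(ref$snps, snp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genome = fa, transcripts = bed, paralogs = par, snps = snp))
}

#' Describe a perturbation of a SAM fixture
#'
#' @param selector regular expression matched against read names, or a
#'   predicate `function(names)` returning a logical vector.
#' @param action one of `"drop"` (write as unmapped), `"duplicate_at"`
#'   (add a secondary alignment: multimapped), `"relocate_to"` (move the
#'   primary alignment), `"shift"` (offset the primary position by `k` bp).
#' @param chrom,pos0 target location for `duplicate_at` / `relocate_to`
#'   (0-based).
#' @param cigar CIGAR at the target (defaults to full-match).
#' @param k shift in bp for `shift`.
#' @return a `perturbation` list.
#' @export
perturbation <- function(selector, action = c("drop", "duplicate_at",
                                              "relocate_to", "shift"),
                         chrom = NULL, pos0 = NULL, cigar = NULL, k = 0L) {
  action <- match.arg(action)
  structure(list(selector = selector, action = action, chrom = chrom,
                 pos0 = pos0, cigar = cigar, k = as.integer(k)),
            class = "perturbation")
}

cigar_from_blocks <- function(blocks) {
  w <- blocks[, 2L] - blocks[, 1L]
  if (nrow(blocks) == 1L) return(paste0(w, "M"))
  gaps <- blocks[-1L, 1L] - blocks[-nrow(blocks), 2L]
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

#' Write a truth-perturbed SAM fixture
#'
#' Unperturbed reads are written aligned exactly at their encoded truth
#' (splice gaps become `N` CIGAR operations; reads from `-`-strand
#' transcripts are written reverse-complemented with the reverse flag, as a
#' correct aligner would). Perturbations then inject the desired mapping
#' errors. The file is unsorted (`@HD SO:unknown`); downstream stages must
#' not assume sort order.
#'
#' @param reads a `simulated_reads` data frame (SE or PE).
#' @param genome the `genome_ref` the header sequences are taken from.
#' @param path output SAM path.
#' @param perturbations list of [perturbation()] objects, applied in order;
#'   a perturbation matching zero reads raises a warning.
#' @return the path, invisibly.
#' @export
make_sam_fixture <- function(reads, genome, path, perturbations = list()) {
  n <- nrow(reads)
  qname <- sub("/[12]$", "", reads$name)
  dec <- lapply(reads$name, decode_truth)
  paired <- vapply(dec, `[[`, logical(1), "paired")
  mate <- vapply(dec, function(d) if (is.na(d$mate)) 0L else d$mate, integer(1))
  origin <- lapply(seq_len(n), function(i) {
    d <- dec[[i]]
    if (d$paired) d$origins[[mate[i]]] else d$origins[[1L]]
  })
  chrom <- vapply(origin, `[[`, character(1), "chrom")
  pos1 <- vapply(origin, function(o) o$blocks[1L, 1L] + 1L, numeric(1))
  cigar <- vapply(origin, function(o) cigar_from_blocks(o$blocks), character(1))
  strand <- vapply(dec, `[[`, character(1), "strand")

  # Orientation: SE reads from '-' transcripts and PE mate 2 of '+' (or
  # mate 1 of '-') fragments align to the reverse strand; SAM stores the
  # forward-strand sequence.
  rev_aligned <- ifelse(paired,
                        ifelse(mate == 2L, strand == "+", strand == "-"),
                        strand == "-")
  seq_out <- reads$seq
  seq_out[rev_aligned] <- revcomp(seq_out[rev_aligned])

  flags <- integer(n)
  flags[rev_aligned] <- bitwOr(flags[rev_aligned], 16L)
  if (any(paired)) {
    pi <- which(paired)
    flags[pi] <- bitwOr(flags[pi], 1L + 2L)
    flags[pi] <- bitwOr(flags[pi], ifelse(mate[pi] == 1L, 64L, 128L))
    m_rev <- !rev_aligned
    flags[pi] <- bitwOr(flags[pi], ifelse(m_rev[pi], 32L, 0L))
  }
  nh <- rep(1L, n)
  unmapped <- rep(FALSE, n)
  tlen <- rep(0L, n)
  if (any(paired)) {
    for (i in which(paired)) {
      d <- dec[[i]]
      span <- range(rbind(d$origins[[1L]]$blocks, d$origins[[2L]]$blocks))
      tl <- span[2L] - span[1L]
      tlen[i] <- if (mate[i] == 1L) tl else -tl
    }
  }
  extra <- list()

  for (p in perturbations) {
    sel <- if (is.function(p$selector)) p$selector(reads$name) else
      grepl(p$selector, reads$name)
    if (!any(sel)) {
      warning("perturbation '", p$action, "' selector matched no reads")
      next
    }
    idx <- which(sel)
    if (p$action == "drop") {
      unmapped[idx] <- TRUE
    } else if (p$action == "shift") {
      pos1[idx] <- pos1[idx] + p$k
    } else if (p$action == "relocate_to") {
      chrom[idx] <- p$chrom
      pos1[idx] <- p$pos0 + 1L
      cigar[idx] <- if (is.null(p$cigar)) {
        paste0(nchar(reads$seq[idx]), "M")
      } else {
        p$cigar
      }
    } else if (p$action == "duplicate_at") {
      nh[idx] <- 2L
      for (i in idx) {
        extra[[length(extra) + 1L]] <- paste(
          qname[i], bitwOr(flags[i], 256L), p$chrom, p$pos0 + 1L, 0L,
          if (is.null(p$cigar)) paste0(nchar(reads$seq[i]), "M") else p$cigar,
          "*", 0L, 0L, "*", "*", paste0("NH:i:", 2L), sep = "\t")
      }
    }
  }

  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)))
  qual <- strrep("I", nchar(seq_out))
  body <- character(n)
  for (i in seq_len(n)) {
    if (unmapped[i]) {
      fl <- 4L
      if (paired[i]) fl <- bitwOr(fl, 1L + ifelse(mate[i] == 1L, 64L, 128L))
      body[i] <- paste(qname[i], fl, "*", 0L, 0L, "*", "*", 0L, 0L,
                       reads$seq[i], qual[i], sep = "\t")
    } else {
      body[i] <- paste(qname[i], flags[i], chrom[i], format(pos1[i], scientific = FALSE),
                       60L, cigar[i], "*", 0L, format(tlen[i], scientific = FALSE),
                       seq_out[i], qual[i], paste0("NH:i:", nh[i]), sep = "\t")
    }
  }
  writeLines(c(header, body, unlist(extra)), path)
  invisible(path)
}
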