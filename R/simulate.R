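# Exhaustive deterministic read simulation. Every transcript position is a
# read start; truth (chromosome, genomic blocks, strand) is encoded in the
# read name so any downstream SAM can be audited against it.

#' Simulation parameters
#'
#' @param L read length in bp (the study lengths are 36, 50, 75, 100, 200).
#' @param insert paired-end outer fragment length in bp (default 200). The
#'   second mate is the reverse complement of the last `L` bases of the
#'   fragment, so `insert = 2 * L` gives abutting mates.
#' @param error_rate per-base substitution probability for
#'   [inject_errors()] (default `1e-4`).
#' @param seed RNG seed used by the stochastic stages.
#' @return a `sim_params` list.
#' @export
sim_params <- function(L, insert = 200L, error_rate = 1e-4, seed = 1L) {
  L <- as.integer(L)
  insert <- as.integer(insert)
  stopifnot(L >= 1L, error_rate >= 0, error_rate <= 1)
  structure(list(L = L, insert = insert, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Encode a read's true origin into its name
#'
#' Format: `BO|chrom|strand|starts|sizes|tag|mate` with comma-separated
#' 0-based genomic block starts/sizes. Paired-end names carry both mates'
#' blocks as two `;`-separated groups with mate field `P`; FASTQ mates append
#' `/1` or `/2` and the SAM QNAME is the shared stem.
#'
#' @param chrom,strand,starts,sizes,tag,mate character vectors (recycled).
#' @return character vector of names.
#' @export
encode_truth <- function(chrom, strand, starts, sizes, tag = "REF",
                         mate = "0") {
  paste("BO", chrom, strand, starts, sizes, tag, mate, sep = "|")
}

#' Decode a truth-encoded read name
#'
#' @param name a single read name (optionally with a `/1` or `/2` mate
#'   suffix on a paired stem).
#' @return list with `chrom`, `strand`, `tag`, `paired`, `mate` (0 for SE,
#'   1/2 when known, NA for a bare paired stem) and `origins`, a list of one
#'   (`SE`) or two (`PE`) `true_origin` objects.
#' @export
decode_truth <- function(name) {
  mate_suffix <- 0L
  if (grepl("/[12]$", name)) {
    mate_suffix <- as.integer(substring(name, nchar(name)))
    name <- substr(name, 1L, nchar(name) - 2L)
  }
  f <- strsplit(name, "|", fixed = TRUE)[[1L]]
  if (length(f) != 7L || f[1L] != "BO") {
    stop("malformed truth-encoded name: ", name)
  }
  chrom <- f[2L]; strand <- f[3L]; tag <- f[6L]
  if (!strand %in% c("+", "-")) stop("malformed strand in name: ", name)
  paired <- identical(f[7L], "P")
  starts_groups <- strsplit(f[4L], ";", fixed = TRUE)[[1L]]
  sizes_groups <- strsplit(f[5L], ";", fixed = TRUE)[[1L]]
  if (length(starts_groups) != length(sizes_groups) ||
      length(starts_groups) != (if (paired) 2L else 1L)) {
    stop("malformed block groups in name: ", name)
  }
  origins <- lapply(seq_along(starts_groups), function(i) {
    true_origin(chrom, strand,
                blocks_from_strings(starts_groups[i], sizes_groups[i]))
  })
  mate <- if (paired) {
    if (mate_suffix > 0L) mate_suffix else NA_integer_
  } else {
    mate_suffix  # 0 unless a suffix was present
  }
  list(chrom = chrom, strand = strand, tag = tag, paired = paired,
       mate = mate, origins = origins)
}

new_simulated_reads <- function(name, seq, mate, L) {
  structure(data.frame(name = name, seq = seq, mate = mate,
                       stringsAsFactors = FALSE),
            L = L, class = c("simulated_reads", "data.frame"))
}

#' Simulate exhaustive single-end reads
#'
#' Every transcript position is the start of one read of length `L`; a
#' transcript of length `T >= L` yields exactly `T - L + 1` reads and every
#' internal transcript base is covered by exactly `L` reads. Transcripts
#' shorter than `L` yield none. The process is fully deterministic.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param genome a `genome_ref`.
#' @param params a [sim_params()] object.
#' @return a `simulated_reads` data frame with columns `name`, `seq`,
#'   `mate` (all 0 for SE).
#' @export
simulate_se <- function(transcripts, genome, params) {
  L <- params$L
  names_acc <- vector("list", length(transcripts))
  seqs_acc <- vector("list", length(transcripts))
  for (k in seq_along(transcripts)) {
    t <- transcripts[[k]]
    if (t$length < L) next
    tseq <- transcript_sequence(genome, t)
    starts <- 0:(t$length - L)
    seqs_acc[[k]] <- substring(tseq, starts + 1L, starts + L)
    pr <- project_windows(t, starts, L)
    names_acc[[k]] <- encode_truth(t$chrom, t$strand, pr$starts, pr$sizes)
  }
  nm <- unlist(names_acc, use.names = FALSE)
  sq <- unlist(seqs_acc, use.names = FALSE)
  if (is.null(nm)) nm <- character(0)
  if (is.null(sq)) sq <- character(0)
  new_simulated_reads(nm, sq, rep(0L, length(nm)), L)
}

#' Simulate exhaustive paired-end reads with a fixed outer insert size
#'
#' For each fragment start `s` with `s + insert <= T`, mate 1 is transcript
#' bases `[s, s + L)` and mate 2 is the reverse complement of bases
#' `[s + insert - L, s + insert)`; a transcript yields `T - insert + 1`
#' fragments.
#'
#' @inheritParams simulate_se
#' @return a `simulated_reads` data frame; `mate` is 1 or 2 and names share
#'   a per-fragment stem with `/1` / `/2` suffixes.
#' @export
simulate_pe <- function(transcripts, genome, params) {
  L <- params$L
  insert <- params$insert
  if (insert < L) {
    stop("insert (", insert, ") must be >= read length (", L, ")")
  }
  names_acc <- list(); seqs_acc <- list(); mate_acc <- list()
  idx <- 0L
  for (t in transcripts) {
    if (t$length < insert) next
    tseq <- transcript_sequence(genome, t)
    s <- 0:(t$length - insert)
    m1 <- substring(tseq, s + 1L, s + L)
    m2 <- revcomp(substring(tseq, s + insert - L + 1L, s + insert))
    p1 <- project_windows(t, s, L)
    p2 <- project_windows(t, s + insert - L, L)
    stem <- encode_truth(t$chrom, t$strand,
                         paste(p1$starts, p2$starts, sep = ";"),
                         paste(p1$sizes, p2$sizes, sep = ";"),
                         tag = "REF", mate = "P")
    idx <- idx + 1L
    names_acc[[idx]] <- c(paste0(stem, "/1"), paste0(stem, "/2"))
    seqs_acc[[idx]] <- c(m1, m2)
    mate_acc[[idx]] <- rep(c(1L, 2L), each = length(s))
  }
  nm <- unlist(names_acc, use.names = FALSE)
  sq <- unlist(seqs_acc, use.names = FALSE)
  mt <- unlist(mate_acc, use.names = FALSE)
  if (is.null(nm)) { nm <- character(0); sq <- character(0); mt <- integer(0) }
  new_simulated_reads(nm, sq, mt, L)
}

#' Inject random sequencing errors
#'
#' Each base is substituted independently with probability `error_rate`,
#' uniformly to one of the three other bases (sampled as a per-read binomial
#' count of substituted positions, then distinct uniform offsets —
#' distributionally identical to per-base Bernoulli trials). Reads with at
#' least one substitution have their tag set to `ERR`.
#'
#' @param reads a `simulated_reads` data frame.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed; the caller's RNG state is restored on exit.
#' @return list with `reads` (modified copy) and `log`, a data frame of
#'   (`name`, `offset` 0-based, `ref_base`, `new_base`) records.
#' @export
inject_errors <- function(reads, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  k <- stats::rbinom(n, lens, error_rate)
  hit <- which(k > 0L)
  seqv <- reads$seq
  namev <- reads$name
  logs <- vector("list", length(hit))
  for (h in seq_along(hit)) {
    i <- hit[h]
    offs <- sort(sample.int(lens[i], k[i])) - 1L
    s <- seqv[i]
    old_b <- new_b <- character(length(offs))
    for (j in seq_along(offs)) {
      o <- offs[j]
      old_b[j] <- substr(s, o + 1L, o + 1L)
      new_b[j] <- sample(setdiff(DNA_BASES, old_b[j]), 1L)
      substr(s, o + 1L, o + 1L) <- new_b[j]
    }
    seqv[i] <- s
    namev[i] <- retag_name(namev[i], "ERR")
    logs[[h]] <- list(name = rep(namev[i], length(offs)), offset = offs,
                      ref_base = old_b, new_base = new_b)
  }
  out <- reads
  out$seq <- seqv
  out$name <- namev
  log <- if (length(logs) > 0L) {
    data.frame(name = unlist(lapply(logs, `[[`, "name")),
               offset = unlist(lapply(logs, `[[`, "offset")),
               ref_base = unlist(lapply(logs, `[[`, "ref_base")),
               new_base = unlist(lapply(logs, `[[`, "new_base")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), offset = integer(0),
               ref_base = character(0), new_base = character(0),
               stringsAsFactors = FALSE)
  }
  list(reads = out, log = log)
}

# Replace the tag field (6th) of a truth-encoded name.
retag_name <- function(name, tag) {
  f <- strsplit(name, "|", fixed = TRUE)
  vapply(f, function(x) {
    x[6L] <- tag
    paste(x, collapse = "|")
  }, character(1))
}

#' Load a SNP table
#'
#' Accepts a TSV with columns `chrom`, `pos` (1-based), `ref`, `alt` (header
#' optional in that order) or a VCF. Multiallelic and indel rows are dropped
#' with a count in attribute `n_rejected_shape`.
#'
#' @param path path to the SNP table.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
load_snp_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- load_variants(path)
    snps <- v[, c("chrom", "pos", "ref", "alt")]
    attr(snps, "n_rejected_shape") <- attr(v, "n_skipped_indel")
    return(snps)
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  tab <- tab[, 1:4]
  names(tab) <- c("chrom", "pos", "ref", "alt")
  tab$pos <- as.integer(tab$pos)
  keep <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% DNA_BASES & tab$alt %in% DNA_BASES
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected_shape") <- sum(!keep)
  out
}

#' Simulate SNP-injected single-end reads
#'
#' For every exhaustive SE read and every accepted SNP whose genomic position
#' falls in the read's origin, one copy of the read is emitted carrying only
#' that SNP's alternate allele (reads covering several SNPs are duplicated,
#' one per SNP; reads covering none are not emitted). On `"-"` transcripts
#' the complement of the alternate allele is substituted. At internal
#' transcript positions each SNP is therefore covered by exactly `L`
#' alt-carrying reads.
#'
#' SNP rows whose reference allele does not match the genome, or that are not
#' biallelic SNVs, are rejected; counts are kept in attributes
#' `n_rejected_ref` / `n_rejected_shape`.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param genome a `genome_ref`.
#' @param snps data frame (`chrom`, `pos` 1-based, `ref`, `alt`), e.g. from
#'   [load_snp_table()].
#' @param params a [sim_params()].
#' @return a `simulated_reads` data frame; tags are `SNP:chrom:pos:alt`.
#' @export
inject_snps <- function(transcripts, genome, snps, params) {
  L <- params$L
  shape_ok <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
    snps$ref %in% DNA_BASES & snps$alt %in% DNA_BASES & snps$ref != snps$alt
  n_shape <- sum(!shape_ok)
  snps <- snps[shape_ok, , drop = FALSE]
  gbase <- substr(genome[snps$chrom], snps$pos, snps$pos)
  ref_ok <- !is.na(gbase) & gbase == snps$ref
  n_ref <- sum(!ref_ok)
  if (n_ref > 0L) {
    warning(n_ref, " SNP row(s) rejected: reference allele mismatch")
  }
  snps <- snps[ref_ok, , drop = FALSE]

  names_acc <- list(); seqs_acc <- list(); idx <- 0L
  for (t in transcripts) {
    if (t$length < L) next
    cand <- snps[snps$chrom == t$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) next
    toff <- transcript_offset_of(t, cand$pos - 1L)
    cand <- cand[!is.na(toff), , drop = FALSE]
    toff <- toff[!is.na(toff)]
    if (nrow(cand) == 0L) next
    tseq <- transcript_sequence(genome, t)
    for (j in seq_len(nrow(cand))) {
      tp <- toff[j]
      s_lo <- max(0L, tp - L + 1L)
      s_hi <- min(tp, t$length - L)
      if (s_lo > s_hi) next
      s <- s_lo:s_hi
      reads <- substring(tseq, s + 1L, s + L)
      sub_base <- if (t$strand == "-") complement_base(cand$alt[j]) else cand$alt[j]
      off <- tp - s  # 0-based offset within each read
      reads <- paste0(substr(reads, 1L, off),
                      sub_base,
                      substr(reads, off + 2L, L))
      pr <- project_windows(t, s, L)
      tag <- paste("SNP", cand$chrom[j], cand$pos[j], cand$alt[j], sep = ":")
      idx <- idx + 1L
      names_acc[[idx]] <- encode_truth(t$chrom, t$strand, pr$starts, pr$sizes,
                                       tag = tag)
      seqs_acc[[idx]] <- reads
    }
  }
  nm <- unlist(names_acc, use.names = FALSE)
  sq <- unlist(seqs_acc, use.names = FALSE)
  if (is.null(nm)) { nm <- character(0); sq <- character(0) }
  out <- new_simulated_reads(nm, sq, rep(0L, length(nm)), L)
  attr(out, "n_rejected_ref") <- n_ref
  attr(out, "n_rejected_shape") <- n_shape
  out
}

#' Write simulated reads to FASTQ
#'
#' Base qualities are constant `I` (Q40); the downstream variant thresholds
#' set every minimum quality to zero, so qualities are inert.
#'
#' @param reads a `simulated_reads` data frame.
#' @param path output FASTQ path. For paired reads pass `path` as a vector
#'   of two paths (`_1`/`_2`) or call once per mate subset.
#' @return the path(s), invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (length(path) == 2L) {
    write_fastq(reads[reads$mate == 1L, ], path[1L])
    write_fastq(reads[reads$mate == 2L, ], path[2L])
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$name
  quals <- Biostrings::PhredQuality(strrep("I", nchar(reads$seq)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file back into a `simulated_reads` frame
#'
#' @param path FASTQ path.
#' @return a `simulated_reads` data frame (mate inferred from `/1` `/2`
#'   name suffixes when present).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(x)
  mate <- ifelse(grepl("/1$", nm), 1L, ifelse(grepl("/2$", nm), 2L, 0L))
  new_simulated_reads(nm, as.character(x), mate,
                      if (length(x)) Biostrings::width(x)[1L] else NA_integer_)
}
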