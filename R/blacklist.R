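# Pileup, SND calling and blacklist serialization. The pileup is built
# directly from CIGAR-resolved alignments of uniquely mapped reads; an SND
# ("single nucleotide difference") is any reference position covered by at
# least one non-reference base. Aggregating SNDs from reads simulated from
# the reference itself yields the mappability blacklist: by construction
# every entry is a mapping artifact, not biology.

#' Variant-calling thresholds
#'
#' Two presets mirror the standard parameterizations: the SND preset
#' (`min_coverage = 1`, `min_reads2 = 1`, `min_var_freq = 0`, no p-value
#' cutoff) records every mismatch position; the variant preset
#' (`min_coverage = 30`, `min_reads2 = 10`, `min_var_freq = 0.1`,
#' `p_threshold = 1e-20`) records high-coverage positions likely to be
#' called as variants. Base qualities are ignored throughout (all
#' minimum-quality thresholds are zero).
#'
#' @param min_coverage minimum read depth.
#' @param min_reads2 minimum reads supporting the non-reference allele.
#' @param min_var_freq minimum variant allele frequency (alt/depth).
#' @param p_threshold one-sided binomial tail cutoff (`NA` disables it).
#' @param error_rate per-base error rate of the binomial significance model.
#' @return a `variant_thresholds` list.
#' @export
variant_thresholds <- function(min_coverage = 1L, min_reads2 = 1L,
                               min_var_freq = 0, p_threshold = NA_real_,
                               error_rate = 0.001) {
  structure(list(min_coverage = as.integer(min_coverage),
                 min_reads2 = as.integer(min_reads2),
                 min_var_freq = min_var_freq,
                 p_threshold = p_threshold,
                 error_rate = error_rate),
            class = "variant_thresholds")
}

#' @rdname variant_thresholds
#' @export
snd_preset <- function() variant_thresholds(1L, 1L, 0, NA_real_)

#' @rdname variant_thresholds
#' @export
variant_preset <- function() variant_thresholds(30L, 10L, 0.1, 1e-20)

#' Build a base-count pileup from uniquely mapped alignments
#'
#' CIGAR-aware: `M`/`=`/`X` consume reference and query, `I`/`S` query only,
#' `D`/`N` reference only (skipped reference positions contribute no
#' counts). Records whose CIGAR query length disagrees with the sequence
#' length are rejected with a warning (count in attribute `n_rejected`).
#' Overlapping reads add depth; duplicate genomic positions are merged
#' structurally.
#'
#' @param aln data frame of uniquely mapped records (`chrom`, `pos` 1-based,
#'   `cigar`, `seq`), e.g. the uniquely mapped subset of
#'   [read_alignments()] output.
#' @param genome a `genome_ref` (supplies the reference base per column).
#' @return a `pileup` data frame: `chrom`, `pos` (0-based), `ref`, counts
#'   `A`,`C`,`G`,`T`,`N`, and `depth`, sorted by chromosome and position.
#' @export
build_pileup <- function(aln, genome) {
  stopifnot(all(c("chrom", "pos", "cigar", "seq") %in% names(aln)))
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(aln$cigar)
  ok <- qw == nchar(aln$seq)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected: CIGAR/sequence length mismatch")
    aln <- aln[ok, , drop = FALSE]
  }
  empty <- structure(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               A = integer(0), C = integer(0), G = integer(0),
               T = integer(0), N = integer(0), depth = integer(0),
               stringsAsFactors = FALSE),
    n_rejected = sum(!ok), class = c("pileup", "data.frame"))
  if (nrow(aln) == 0L) return(empty)

  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = ops)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(aln$cigar, ops = ops)
  nseg <- S4Vectors::elementNROWS(rr)
  rid <- rep(seq_len(nrow(aln)), nseg)
  rstart <- unlist(IRanges::start(rr), use.names = FALSE)
  qstart <- unlist(IRanges::start(qr), use.names = FALSE)
  w <- unlist(IRanges::width(rr), use.names = FALSE)
  keep <- w > 0L
  rid <- rid[keep]; rstart <- rstart[keep]; qstart <- qstart[keep]; w <- w[keep]
  if (length(w) == 0L) return(empty)
  seg_seq <- substring(aln$seq[rid], qstart, qstart + w - 1L)
  bases <- unlist(strsplit(seg_seq, "", fixed = TRUE), use.names = FALSE)
  pos0 <- rep(rstart - 1L, w) + sequence(w) - 1L
  chroms <- rep(aln$chrom[rid], w)

  key <- paste(chroms, pos0, sep = "\r")
  tab <- table(key, factor(bases, levels = c(DNA_BASES, "N")))
  ks <- strsplit(rownames(tab), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(ks, `[`, character(1), 1L),
    pos = as.integer(vapply(ks, `[`, character(1), 2L)),
    A = as.integer(tab[, "A"]), C = as.integer(tab[, "C"]),
    G = as.integer(tab[, "G"]), T = as.integer(tab[, "T"]),
    N = as.integer(tab[, "N"]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$ref <- substr(genome[out$chrom], out$pos + 1L, out$pos + 1L)
  out$depth <- out$A + out$C + out$G + out$T + out$N
  out <- out[, c("chrom", "pos", "ref", "A", "C", "G", "T", "N", "depth")]
  rownames(out) <- NULL
  structure(out, n_rejected = sum(!ok), class = c("pileup", "data.frame"))
}

# alt allele per column: most frequent non-reference base among A,C,G,T
# (N never calls); ties break lexicographically (which.max returns the
# first, and columns are scanned in A<C<G<T order).
alt_allele <- function(pileup) {
  m <- as.matrix(pileup[, DNA_BASES, drop = FALSE])
  for (i in seq_len(nrow(m))) {
    r <- match(pileup$ref[i], DNA_BASES)
    if (!is.na(r)) m[i, r] <- -1L
  }
  j <- apply(m, 1L, which.max)
  data.frame(alt = DNA_BASES[j],
             alt_count = m[cbind(seq_len(nrow(m)), j)],
             stringsAsFactors = FALSE)
}

#' Call single nucleotide differences (SNDs)
#'
#' Emits one SND per pileup column covered by at least one non-reference,
#' non-N base (under the default SND preset). The alternate allele is the
#' most frequent non-reference base, ties broken lexicographically.
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @param thresholds a [variant_thresholds()]; default [snd_preset()].
#' @return `snd` data frame: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `alt_count`, `depth`, `in_exon` (`NA` until annotated), `db_flags`
#'   (empty string until intersected).
#' @export
call_snds <- function(pileup, thresholds = snd_preset()) {
  aa <- alt_allele(pileup)
  keep <- aa$alt_count >= pmax(1L, thresholds$min_reads2) &
    pileup$depth >= thresholds$min_coverage &
    aa$alt_count / pmax(1L, pileup$depth) >= thresholds$min_var_freq &
    pileup$ref %in% DNA_BASES
  out <- data.frame(
    chrom = pileup$chrom[keep], pos = pileup$pos[keep],
    ref = pileup$ref[keep], alt = aa$alt[keep],
    alt_count = aa$alt_count[keep], depth = pileup$depth[keep],
    in_exon = rep(NA, sum(keep)), db_flags = rep("", sum(keep)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("snd", "data.frame"))
}

#' Call high-coverage variants from a pileup
#'
#' A column is called when depth, supporting reads and allele frequency
#' clear the thresholds and the one-sided binomial tail
#' `P(X >= alt_count | n = depth, p = error_rate)` is at most
#' `p_threshold`.
#'
#' @param pileup a `pileup`.
#' @param thresholds a [variant_thresholds()]; default [variant_preset()].
#' @return data frame of calls: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `depth`, `alt_count`, `p_value`.
#' @export
call_variants <- function(pileup, thresholds = variant_preset()) {
  snds <- call_snds(pileup, variant_thresholds(
    thresholds$min_coverage, thresholds$min_reads2, thresholds$min_var_freq))
  p <- stats::pbinom(snds$alt_count - 1L, snds$depth, thresholds$error_rate,
                     lower.tail = FALSE)
  keep <- if (is.na(thresholds$p_threshold)) rep(TRUE, length(p)) else p <= thresholds$p_threshold
  data.frame(chrom = snds$chrom[keep], pos = snds$pos[keep] + 1L,
             ref = snds$ref[keep], alt = snds$alt[keep],
             depth = snds$depth[keep], alt_count = snds$alt_count[keep],
             p_value = p[keep],
             stringsAsFactors = FALSE)
}

# Merge per-chromosome exon blocks into disjoint sorted intervals.
exon_union <- function(transcripts) {
  by_chrom <- list()
  for (t in transcripts) {
    by_chrom[[t$chrom]] <- rbind(by_chrom[[t$chrom]], t$blocks)
  }
  lapply(by_chrom, function(b) {
    b <- b[order(b[, 1L]), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = b[, 1L] + 1L, end = b[, 2L]))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
}

#' Flag SNDs falling inside annotated exons
#'
#' @param snds an `snd` data frame.
#' @param transcripts annotation as a list of [transcript_model()] objects.
#' @return the SNDs with `in_exon` set (position in the half-open union of
#'   all exon blocks).
#' @export
annotate_exonic <- function(snds, transcripts) {
  ex <- exon_union(transcripts)
  snds$in_exon <- vapply(seq_len(nrow(snds)), function(i) {
    b <- ex[[snds$chrom[i]]]
    if (is.null(b)) return(FALSE)
    j <- findInterval(snds$pos[i], b[, 1L])
    j >= 1L && snds$pos[i] < b[j, 2L]
  }, logical(1))
  snds
}

#' Intersect SNDs with a database position set
#'
#' @param snds an `snd` data frame.
#' @param positions data frame with `chrom` and `pos` (1-based) columns.
#' @param name database name appended to `db_flags` of matching SNDs.
#' @return list with `snds` (flags updated) and `count` of overlaps.
#' @export
intersect_database <- function(snds, positions, name) {
  db_key <- paste(positions$chrom, positions$pos)
  hit <- paste(snds$chrom, snds$pos + 1L) %in% db_key
  snds$db_flags[hit] <- ifelse(snds$db_flags[hit] == "", name,
                               paste(snds$db_flags[hit], name, sep = ","))
  list(snds = snds, count = sum(hit))
}

#' Write / read a blacklist TSV
#'
#' Columns: `chrom`, `pos` (1-based in the file), `ref`, `alt`,
#' `alt_count`, `depth`, `in_exon`, `db_flags` (`.` for none). Reading a
#' written blacklist reproduces the in-memory object exactly (positions are
#' converted back to the internal 0-based convention).
#'
#' @param snds an `snd` data frame.
#' @param path output path.
#' @return `write_blacklist`: the path, invisibly. `read_blacklist`: an
#'   `snd` data frame.
#' @export
write_blacklist <- function(snds, path) {
  out <- data.frame(
    chrom = snds$chrom, pos = snds$pos + 1L, ref = snds$ref, alt = snds$alt,
    alt_count = snds$alt_count, depth = snds$depth,
    in_exon = ifelse(is.na(snds$in_exon), "NA", ifelse(snds$in_exon, "TRUE", "FALSE")),
    db_flags = ifelse(snds$db_flags == "", ".", snds$db_flags),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty blacklist file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  expected <- c("chrom", "pos", "ref", "alt", "alt_count", "depth",
                "in_exon", "db_flags")
  if (!identical(header, expected)) {
    stop("blacklist header mismatch in ", path)
  }
  n <- length(lines) - 1L
  out <- data.frame(chrom = character(n), pos = integer(n),
                    ref = character(n), alt = character(n),
                    alt_count = integer(n), depth = integer(n),
                    in_exon = logical(n), db_flags = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 8L) {
      stop("malformed blacklist row at line ", i + 1L, " of ", path)
    }
    pos1 <- suppressWarnings(as.integer(f[2L]))
    ac <- suppressWarnings(as.integer(f[5L]))
    dp <- suppressWarnings(as.integer(f[6L]))
    if (is.na(pos1) || is.na(ac) || is.na(dp)) {
      stop("malformed numeric field at line ", i + 1L, " of ", path)
    }
    out$chrom[i] <- f[1L]; out$pos[i] <- pos1 - 1L
    out$ref[i] <- f[3L]; out$alt[i] <- f[4L]
    out$alt_count[i] <- ac; out$depth[i] <- dp
    out$in_exon[i] <- switch(f[7L], "TRUE" = TRUE, "FALSE" = FALSE, NA)
    out$db_flags[i] <- if (f[8L] == ".") "" else f[8L]
  }
  structure(out, class = c("snd", "data.frame"))
}
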