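# Alignment audit: classify each simulated read (or read pair) against the
# truth encoded in its name. Categories follow the standard mappability
# taxonomy: unmapped / multimapped / uniquely_correct / uniquely_mismapped,
# where "uniquely mismapped" means a single reported location more than
# `tolerance` bp from the true origin (5 bp by default, so junction slippage
# at a read end is not penalized).

CATEGORIES <- c("unmapped", "multimapped", "uniquely_correct",
                "uniquely_mismapped")

#' Read alignment records from SAM or BAM
#'
#' SAM text is converted with [Rsamtools::asBam()] first. Secondary and
#' supplementary records are kept (the audit needs them to detect
#' multimapping); the `NH` hit-count tag is captured when present.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return data frame with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `cigar`, `tlen`, `seq`, `nh`.
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "isize", "seq"),
    tag = "NH"
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(
    qname = b$qname,
    flag = b$flag,
    chrom = as.character(b$rname),
    pos = b$pos,
    cigar = b$cigar,
    tlen = b$isize,
    seq = as.character(b$seq),
    nh = if (is.null(b$tag$NH)) rep(NA_integer_, length(b$qname)) else b$tag$NH,
    stringsAsFactors = FALSE
  )
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

#' Does a true origin span a splice junction?
#'
#' @param origin a `true_origin`.
#' @return `TRUE` iff the origin covers two or more genomic blocks.
#' @export
spans_junction <- function(origin) nrow(origin$blocks) >= 2L

#' Classify a single-end read against its truth
#'
#' @param recs data frame of alignment records sharing one `qname`.
#' @param truth the read's `true_origin`.
#' @param tolerance maximum allowed shift in bp between the leftmost aligned
#'   base and the leftmost truth base (default 5).
#' @return one of `"unmapped"`, `"multimapped"`, `"uniquely_correct"`,
#'   `"uniquely_mismapped"`.
#' @export
classify_read <- function(recs, truth, tolerance = 5L) {
  if (length(unique(recs$qname)) > 1L) {
    stop("records passed to classify_read span multiple qnames")
  }
  mapped <- recs[!flag_bit(recs$flag, 4L) & !flag_bit(recs$flag, 2048L), ,
                 drop = FALSE]
  if (nrow(mapped) == 0L) return("unmapped")
  nh_max <- suppressWarnings(max(mapped$nh, na.rm = TRUE))
  if (nrow(mapped) > 1L || (is.finite(nh_max) && nh_max > 1L)) {
    return("multimapped")
  }
  same_chrom <- !is.na(mapped$chrom) && mapped$chrom == truth$chrom
  delta <- abs((mapped$pos - 1L) - truth$blocks[1L, 1L])
  if (same_chrom && delta <= tolerance) "uniquely_correct" else "uniquely_mismapped"
}

#' Classify a read pair against both truths
#'
#' A pair with an unmapped mate, a missing mate record, or an absolute
#' template length above `max_insert` (1 Mb by default) is `unmapped`; a
#' multimapped mate makes the pair `multimapped`; otherwise the pair is
#' `uniquely_correct` only if both mates lie within `tolerance` of their own
#' truths.
#'
#' @param recs alignment records for both mates (one shared qname stem).
#' @param truths list of two `true_origin` objects (mate 1, mate 2).
#' @param tolerance per-mate shift tolerance in bp.
#' @param max_insert maximum |template length| in bp (default `1e6`).
#' @return classification category string.
#' @export
classify_pair <- function(recs, truths, tolerance = 5L, max_insert = 1000000L) {
  is_m1 <- flag_bit(recs$flag, 64L)
  is_m2 <- flag_bit(recs$flag, 128L)
  per_mate <- list(recs[is_m1, , drop = FALSE], recs[is_m2, , drop = FALSE])
  cls <- character(2L)
  for (m in 1:2) {
    r <- per_mate[[m]]
    if (nrow(r) == 0L) return("unmapped")  # missing mate record
    if (any(flag_bit(r$flag, 8L))) return("unmapped")  # mate-unmapped flag
    cls[m] <- classify_read(r, truths[[m]], tolerance)
  }
  if (any(cls == "unmapped")) return("unmapped")
  tl <- suppressWarnings(max(abs(recs$tlen), na.rm = TRUE))
  if (is.finite(tl) && tl > max_insert) return("unmapped")
  if (any(cls == "multimapped")) return("multimapped")
  if (all(cls == "uniquely_correct")) "uniquely_correct" else "uniquely_mismapped"
}

#' Did a mismapped read land in a known paralog of its source gene?
#'
#' The source gene(s) are the transcripts whose blocks contain the truth's
#' leftmost base; the read maps to a paralog if its leftmost aligned base
#' falls inside any exon block of a gene paired with a source gene in the
#' paralog table (treated as symmetric).
#'
#' @param mapped_chrom,mapped_pos0 mapped location (0-based leftmost base).
#' @param truth the read's `true_origin`.
#' @param transcripts annotation as a list of [transcript_model()] objects.
#' @param paralogs data frame with two columns of paired gene/transcript ids.
#' @return `TRUE`/`FALSE`, or `NA` if the source gene is absent from the
#'   annotation.
#' @export
maps_to_paralog <- function(mapped_chrom, mapped_pos0, truth, transcripts,
                            paralogs) {
  if (is.null(paralogs) || nrow(paralogs) == 0L) return(FALSE)
  t0 <- truth$blocks[1L, 1L]
  src <- vapply(transcripts, function(t) {
    t$chrom == truth$chrom && any(t$blocks[, 1L] <= t0 & t0 < t$blocks[, 2L])
  }, logical(1))
  src_ids <- names(transcripts)[src]
  if (length(src_ids) == 0L) return(NA)
  partners <- unique(c(paralogs[[2L]][paralogs[[1L]] %in% src_ids],
                       paralogs[[1L]][paralogs[[2L]] %in% src_ids]))
  if (length(partners) == 0L) return(FALSE)
  for (id in partners) {
    t <- transcripts[[id]]
    if (is.null(t) || t$chrom != mapped_chrom) next
    if (any(t$blocks[, 1L] <= mapped_pos0 & mapped_pos0 < t$blocks[, 2L])) {
      return(TRUE)
    }
  }
  FALSE
}

#' Audit a SAM/BAM file of simulated reads
#'
#' Groups records by qname, decodes each read's truth from its name, and
#' classifies every read (SE) or pair (PE). Reads listed in `all_names` but
#' absent from the file are counted as unmapped. In SNP mode
#' (`drop_ref_tag = TRUE`) reads tagged `REF` are removed before
#' classification, mirroring the co-alignment protocol where reference-only
#' reads are aligned alongside SNP reads and then filtered out.
#'
#' @param alignments path to SAM/BAM, or a data frame from
#'   [read_alignments()].
#' @param mode `"se"` or `"pe"`.
#' @param tolerance shift tolerance in bp (default 5).
#' @param max_insert PE template-length cutoff in bp (default `1e6`).
#' @param transcripts,paralogs optional annotation + paralog pair table for
#'   paralog attribution of mismapped reads.
#' @param all_names optional character vector of all simulated read names
#'   (qname stems for PE); names missing from the file become unmapped.
#' @param drop_ref_tag drop reads tagged `REF` before classifying.
#' @return data frame with one row per read/pair: `qname`, `category`,
#'   `spans_junction` (at truth), `mapped_to_paralog`, `tag`.
#' @export
audit_alignments <- function(alignments, mode = c("se", "pe"), tolerance = 5L,
                             max_insert = 1000000L, transcripts = NULL,
                             paralogs = NULL, all_names = NULL,
                             drop_ref_tag = FALSE) {
  mode <- match.arg(mode)
  recs <- if (is.character(alignments)) read_alignments(alignments) else alignments
  groups <- split(seq_len(nrow(recs)), recs$qname)
  qnames <- names(groups)
  if (!is.null(all_names)) {
    missing <- setdiff(unique(all_names), qnames)
  } else {
    missing <- character(0)
  }
  n <- length(groups) + length(missing)
  out <- data.frame(qname = c(qnames, missing),
                    category = character(n),
                    spans_junction = logical(n),
                    mapped_to_paralog = NA,
                    tag = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    g <- recs[groups[[i]], , drop = FALSE]
    truth <- decode_truth(qnames[i])
    out$tag[i] <- truth$tag
    if (mode == "pe") {
      if (!truth$paired) stop("SE-style name in PE audit: ", qnames[i])
      out$category[i] <- classify_pair(g, truth$origins, tolerance, max_insert)
      out$spans_junction[i] <- spans_junction(truth$origins[[1L]]) ||
        spans_junction(truth$origins[[2L]])
      tr <- truth$origins[[1L]]
    } else {
      out$category[i] <- classify_read(g, truth$origins[[1L]], tolerance)
      out$spans_junction[i] <- spans_junction(truth$origins[[1L]])
      tr <- truth$origins[[1L]]
    }
    if (out$category[i] == "uniquely_mismapped" && !is.null(transcripts)) {
      mapped <- g[!flag_bit(g$flag, 4L) & !flag_bit(g$flag, 2048L) &
                    !flag_bit(g$flag, 256L), , drop = FALSE]
      if (nrow(mapped) >= 1L) {
        out$mapped_to_paralog[i] <- maps_to_paralog(
          mapped$chrom[1L], mapped$pos[1L] - 1L, tr, transcripts, paralogs)
      }
    }
  }
  if (length(missing) > 0L) {
    j <- length(groups) + seq_along(missing)
    out$category[j] <- "unmapped"
    for (k in seq_along(missing)) {
      truth <- decode_truth(missing[k])
      out$tag[j[k]] <- truth$tag
      out$spans_junction[j[k]] <- any(vapply(truth$origins, spans_junction,
                                             logical(1)))
    }
  }
  if (drop_ref_tag) out <- out[out$tag != "REF", , drop = FALSE]
  out$category <- factor(out$category, levels = CATEGORIES)
  rownames(out) <- NULL
  out
}

#' Summarize read classifications
#'
#' @param cls data frame from [audit_alignments()].
#' @return list with `counts` and `proportions` per category (summing to 1),
#'   `n`, and — over uniquely mismapped reads only — `junction_fraction` and
#'   `paralog_fraction` (`NA` when there are no mismapped reads).
#' @export
summarize_classifications <- function(cls) {
  if (nrow(cls) == 0L) stop("no classifications to summarize")
  counts <- table(factor(cls$category, levels = CATEGORIES))
  n <- sum(counts)
  mis <- cls[cls$category == "uniquely_mismapped", , drop = FALSE]
  junction_fraction <- if (nrow(mis) > 0L) mean(mis$spans_junction) else NA_real_
  pl <- mis$mapped_to_paralog[!is.na(mis$mapped_to_paralog)]
  paralog_fraction <- if (nrow(mis) > 0L && length(pl) > 0L) mean(pl) else NA_real_
  list(counts = as.integer(counts),
       categories = CATEGORIES,
       proportions = as.numeric(counts) / n,
       n = n,
       junction_fraction = junction_fraction,
       paralog_fraction = paralog_fraction)
}
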