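# End-use filtering: candidate variant lists are intersected across
# replicates, pre-filtered against annotation databases, and matched against
# one or more mappability blacklists. A binomial test measures whether the
# surviving novel variants are enriched for blacklist positions.

#' Load candidate variant calls
#'
#' Accepts VCF (multiallelic rows split; indel rows skipped with a count in
#' attribute `n_skipped_indel`) or a tab-separated table with columns
#' `chrom`, `pos`/`position`, `ref`, `alt`/`var` and optionally
#' `reads1`/`reads2` (supporting-read counts, VarScan style) or
#' `depth`/`alt_count`.
#'
#' @param path input path (`.vcf` or `.tsv`/other delimited text).
#' @param sample sample/replicate label attached to every call.
#' @return data frame of calls: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `depth`, `alt_count`, `sample`.
#' @export
load_variants <- function(path, sample = NA_character_) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    info <- fix[, "INFO"]
    dp <- suppressWarnings(as.integer(sub("^.*DP=([0-9]+).*$", "\\1",
                                          ifelse(grepl("DP=", info), info, NA))))
    ac <- suppressWarnings(as.integer(sub("^.*AC=([0-9]+).*$", "\\1",
                                          ifelse(grepl("AC=", info), info, NA))))
    alts <- strsplit(alt, ",", fixed = TRUE)
    nn <- lengths(alts)
    chrom <- rep(chrom, nn); pos <- rep(pos, nn); ref <- rep(ref, nn)
    dp <- rep(dp, nn); ac <- rep(ac, nn)
    alt <- unlist(alts, use.names = FALSE)
    keep <- nchar(ref) == 1L & nchar(alt) == 1L & alt %in% DNA_BASES
    out <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                      alt = alt[keep], depth = dp[keep], alt_count = ac[keep],
                      sample = sample, stringsAsFactors = FALSE)
    attr(out, "n_skipped_indel") <- sum(!keep)
    return(out)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  pos_col <- intersect(c("pos", "position"), names(tab))[1L]
  alt_col <- intersect(c("alt", "var"), names(tab))[1L]
  if (is.na(pos_col) || is.na(alt_col) || !"chrom" %in% names(tab)) {
    stop("unrecognized variant table dialect in ", path)
  }
  depth <- if ("depth" %in% names(tab)) tab$depth
    else if (all(c("reads1", "reads2") %in% names(tab))) tab$reads1 + tab$reads2
    else NA_integer_
  alt_count <- if ("alt_count" %in% names(tab)) tab$alt_count
    else if ("reads2" %in% names(tab)) tab$reads2
    else NA_integer_
  keep <- nchar(tab$ref) == 1L & nchar(tab[[alt_col]]) == 1L &
    tab[[alt_col]] %in% DNA_BASES
  out <- data.frame(chrom = tab$chrom[keep],
                    pos = as.integer(tab[[pos_col]][keep]),
                    ref = tab$ref[keep], alt = tab[[alt_col]][keep],
                    depth = depth[keep], alt_count = alt_count[keep],
                    sample = sample, stringsAsFactors = FALSE)
  attr(out, "n_skipped_indel") <- sum(!keep)
  out
}

#' Write variant calls as VCF
#'
#' Removed calls can be emitted with `FILTER` set to `BLACKLIST` by passing
#' a logical `blacklisted` vector; retained calls get `PASS`.
#'
#' @param variants data frame of calls (as from [load_variants()]).
#' @param path output path.
#' @param blacklisted optional logical vector marking blacklisted rows.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path, blacklisted = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FILTER=<ID=BLACKLIST,Description=\"Matches a mappability blacklist entry\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- if (is.null(blacklisted)) rep("PASS", nrow(variants)) else
    ifelse(blacklisted, "BLACKLIST", "PASS")
  info <- ifelse(is.na(variants$depth), ".",
                 paste0("DP=", variants$depth,
                        ifelse(is.na(variants$alt_count), "",
                               paste0(";AC=", variants$alt_count))))
  rows <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", filt, info, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$alt)

#' Intersect variant calls across replicates
#'
#' Keeps calls (keyed on chrom, pos, alt) present in every replicate;
#' chromosomes on the exclusion list (chrM by default) are removed first.
#'
#' @param replicates list of variant data frames, one per replicate.
#' @param exclude_chroms chromosomes to drop entirely.
#' @return variant data frame (rows taken from the first replicate).
#' @export
intersect_replicates <- function(replicates, exclude_chroms = "chrM") {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  replicates <- lapply(replicates, function(v)
    v[!v$chrom %in% exclude_chroms, , drop = FALSE])
  if (length(replicates) == 1L) {
    warning("single replicate supplied; intersection is the identity")
    return(replicates[[1L]])
  }
  keys <- lapply(replicates, variant_key)
  common <- Reduce(intersect, keys)
  out <- replicates[[1L]][keys[[1L]] %in% common, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split variants by database membership
#'
#' When `transcripts` is supplied, variants outside the exon union are also
#' set aside (`nonexonic`), mirroring the exon + known-SNP pre-filter.
#'
#' @param variants variant data frame.
#' @param positions database position set (`chrom`, `pos` 1-based).
#' @param transcripts optional annotation for the exon restriction.
#' @return list with `novel`, `known`, `nonexonic` data frames.
#' @export
filter_database <- function(variants, positions, transcripts = NULL) {
  nonexonic <- variants[0L, , drop = FALSE]
  if (!is.null(transcripts)) {
    ex <- exon_union(transcripts)
    inex <- vapply(seq_len(nrow(variants)), function(i) {
      b <- ex[[variants$chrom[i]]]
      if (is.null(b)) return(FALSE)
      p0 <- variants$pos[i] - 1L
      j <- findInterval(p0, b[, 1L])
      j >= 1L && p0 < b[j, 2L]
    }, logical(1))
    nonexonic <- variants[!inex, , drop = FALSE]
    variants <- variants[inex, , drop = FALSE]
  }
  db_key <- paste(positions$chrom, positions$pos)
  known <- paste(variants$chrom, variants$pos) %in% db_key
  list(novel = variants[!known, , drop = FALSE],
       known = variants[known, , drop = FALSE],
       nonexonic = nonexonic)
}

#' Filter variant calls against mappability blacklists
#'
#' Matches on (chrom, pos, alt) by default (`position_allele`) or on
#' (chrom, pos) alone (`position_only`). Multiple blacklists are unioned;
#' the report records which blacklist matched each removed call, and the
#' removal counts under both modes.
#'
#' @param variants variant data frame (1-based `pos`).
#' @param blacklists an `snd` data frame (from [call_snds()] /
#'   [read_blacklist()]), or a named list of them.
#' @param mode `"position_allele"` or `"position_only"`.
#' @return a `filter_report` list: `retained`, `removed` (with a
#'   `matched_blacklist` column), `n_input`, `n_blacklisted`, `n_retained`,
#'   `n_position_allele`, `n_position_only`, `mode`.
#' @export
filter_blacklist <- function(variants, blacklists,
                             mode = c("position_allele", "position_only")) {
  mode <- match.arg(mode)
  if (is.data.frame(blacklists)) blacklists <- list(blacklist = blacklists)
  if (is.null(names(blacklists))) {
    names(blacklists) <- paste0("blacklist", seq_along(blacklists))
  }
  pos_key <- function(chrom, pos) paste(chrom, pos)
  allele_key <- function(chrom, pos, alt) paste(chrom, pos, alt)
  v_pos <- pos_key(variants$chrom, variants$pos)
  v_all <- allele_key(variants$chrom, variants$pos, variants$alt)
  matched <- rep(NA_character_, nrow(variants))
  hit_allele <- rep(FALSE, nrow(variants))
  hit_pos <- rep(FALSE, nrow(variants))
  for (nm in names(blacklists)) {
    b <- blacklists[[nm]]
    b_pos <- pos_key(b$chrom, b$pos + 1L)
    b_all <- allele_key(b$chrom, b$pos + 1L, b$alt)
    ha <- v_all %in% b_all
    hp <- v_pos %in% b_pos
    hit_allele <- hit_allele | ha
    hit_pos <- hit_pos | hp
    this_hit <- if (mode == "position_allele") ha else hp
    matched[this_hit & is.na(matched)] <- nm
  }
  hit <- if (mode == "position_allele") hit_allele else hit_pos
  removed <- variants[hit, , drop = FALSE]
  removed$matched_blacklist <- matched[hit]
  retained <- variants[!hit, , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL
  structure(list(retained = retained, removed = removed,
                 n_input = nrow(variants),
                 n_blacklisted = sum(hit),
                 n_retained = sum(!hit),
                 n_position_allele = sum(hit_allele),
                 n_position_only = sum(hit_pos),
                 mode = mode),
            class = "filter_report")
}

#' Full replicate + database + blacklist filtering pipeline
#'
#' Implements the end-use scheme: intersect calls across replicates
#' (dropping excluded chromosomes), remove non-exonic and database-known
#' positions, then filter the surviving novel calls against the
#' blacklist(s).
#'
#' @param replicates list of per-replicate variant data frames.
#' @param db_positions known-variant position set (`chrom`, `pos`).
#' @param blacklists blacklist(s) as in [filter_blacklist()].
#' @param transcripts optional annotation for the exon restriction.
#' @param exclude_chroms chromosomes dropped up front (default `chrM`).
#' @param mode blacklist matching mode.
#' @return a `filter_report` with the additional counts
#'   `n_after_replicate_intersection` and `n_after_db_filter`.
#' @export
filter_pipeline <- function(replicates, db_positions, blacklists,
                            transcripts = NULL, exclude_chroms = "chrM",
                            mode = "position_allele") {
  stage1 <- if (length(replicates) > 1L) {
    intersect_replicates(replicates, exclude_chroms)
  } else {
    replicates[[1L]][!replicates[[1L]]$chrom %in% exclude_chroms, , drop = FALSE]
  }
  stage2 <- filter_database(stage1, db_positions, transcripts)
  rep_report <- filter_blacklist(stage2$novel, blacklists, mode)
  rep_report$n_input <- nrow(stage1)
  rep_report$n_after_replicate_intersection <- nrow(stage1)
  rep_report$n_after_db_filter <- nrow(stage2$novel)
  rep_report$n_known_db <- nrow(stage2$known)
  rep_report$n_nonexonic <- nrow(stage2$nonexonic)
  rep_report
}

#' Binomial enrichment test for blacklist overlap
#'
#' Tests whether `x` of `n` variants falling on blacklist positions is more
#' than expected when each variant independently lands on a blacklisted
#' exon position with probability `p` (the blacklisted fraction of exon
#' positions). Returns the upper tail `P(X >= x)` for
#' `X ~ Binomial(n, p)`.
#'
#' @param x number of variants at blacklist positions.
#' @param n total number of variants.
#' @param p blacklisted proportion of exon positions.
#' @param log10_p return `log10` of the tail probability instead.
#' @return the tail probability (or its `log10`).
#' @export
enrichment_test <- function(x, n, p, log10_p = FALSE) {
  if (x < 0 || n < 0 || x > n || p <= 0 || p >= 1) {
    stop("require 0 <= x <= n and 0 < p < 1")
  }
  if (log10_p) {
    stats::pbinom(x - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
  } else {
    stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  }
}
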