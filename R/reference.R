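# All internal coordinates are 0-based half-open; SAM/VCF/blacklist
# serialization converts to 1-based at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorized over a character vector; delegates to
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masking is discarded). Chromosome names are
#' taken as the first whitespace-delimited token of each FASTA header.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of uppercase sequences, one per
#'   chromosome, with class `genome_ref`.
#' @export
load_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  g <- toupper(as.character(seqs))
  names(g) <- nm
  class(g) <- c("genome_ref", class(g))
  g
}

#' Construct a transcript model
#'
#' @param id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param blocks two-column integer matrix of genomic exon intervals
#'   (`start`, `end`), 0-based half-open, ascending, non-overlapping. A
#'   single-block `"+"` model doubles as an unspliced WES exon target.
#' @return an object of class `transcript_model` with fields `id`, `chrom`,
#'   `strand`, `blocks` and the cached total `length`.
#' @export
transcript_model <- function(id, chrom, strand, blocks) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(chrom), length(chrom) == 1L,
            strand %in% c("+", "-"))
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(blocks) == 0L) stop("transcript '", id, "' has no blocks")
  if (any(blocks[, 2L] <= blocks[, 1L])) {
    stop("transcript '", id, "' has an empty or inverted block")
  }
  if (is.unsorted(blocks[, 1L], strictly = TRUE) ||
      any(blocks[-1L, 1L, drop = TRUE] < blocks[-nrow(blocks), 2L, drop = TRUE])) {
    stop("transcript '", id, "' blocks must ascend and be disjoint")
  }
  structure(
    list(id = id, chrom = chrom, strand = strand, blocks = blocks,
         length = sum(blocks[, 2L] - blocks[, 1L])),
    class = "transcript_model"
  )
}

#' @method print transcript_model
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%s %d block(s), %d bp\n",
              x$id, x$chrom, x$strand, nrow(x$blocks), x$length))
  invisible(x)
}

#' Load transcript models from BED12
#'
#' Block offsets are converted to absolute genomic 0-based half-open
#' intervals. Transcripts on chromosomes outside `allowed_chroms` are dropped
#' (the count is kept in attribute `n_dropped`).
#'
#' @param path path to a BED12 file.
#' @param allowed_chroms chromosome allow-list; the default keeps the
#'   autosomes plus X and Y. `NULL` keeps everything.
#' @return named list of [transcript_model()] objects.
#' @export
load_transcripts <- function(path,
                             allowed_chroms = c(paste0("chr", 1:22),
                                                "chrX", "chrY")) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("no records in BED file: ", path)
  blocks_rel <- S4Vectors::mcols(gr)$blocks
  has_blocks <- !is.null(blocks_rel)
  out <- vector("list", length(gr))
  ids <- character(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts0 <- GenomicRanges::start(gr) - 1L
  ends0 <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  names_col <- S4Vectors::mcols(gr)$name
  for (i in seq_along(gr)) {
    if (has_blocks && length(blocks_rel[[i]]) > 0L) {
      b <- blocks_rel[[i]]
      bs <- starts0[i] + IRanges::start(b) - 1L
      be <- bs + IRanges::width(b)
    } else {
      bs <- starts0[i]
      be <- ends0[i]
    }
    if (any(be > ends0[i]) || any(bs < starts0[i])) {
      stop("BED record ", i, " (", names_col[i],
           "): block arithmetic exceeds record bounds")
    }
    strand_i <- if (strands[i] %in% c("+", "-")) strands[i] else "+"
    id_i <- if (is.null(names_col) || is.na(names_col[i])) {
      paste0("tx", i)
    } else {
      names_col[i]
    }
    ids[i] <- id_i
    out[[i]] <- transcript_model(id_i, chroms[i], strand_i, cbind(bs, be))
  }
  keep <- if (is.null(allowed_chroms)) rep(TRUE, length(gr)) else chroms %in% allowed_chroms
  res <- out[keep]
  names(res) <- ids[keep]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Extract the strand-aware spliced sequence of a transcript
#'
#' Block sequences are concatenated in genomic order and reverse-complemented
#' for `"-"` transcripts, so position 0 of the returned string is the 5' end
#' of the transcript.
#'
#' @param genome a `genome_ref` from [load_genome()].
#' @param t a [transcript_model()].
#' @return nucleotide string of length `t$length`.
#' @export
transcript_sequence <- function(genome, t) {
  chromseq <- genome[[t$chrom]]
  if (is.null(chromseq)) stop("chromosome '", t$chrom, "' not in genome")
  if (any(t$blocks[, 2L] > nchar(chromseq))) {
    stop("transcript '", t$id, "' block beyond end of ", t$chrom)
  }
  s <- paste(substring(chromseq, t$blocks[, 1L] + 1L, t$blocks[, 2L]),
             collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  s
}

#' Project a transcript window to genomic blocks
#'
#' Maps transcript coordinates `[t_start, t_start + length)` (0-based along
#' the oriented transcript, so offset 0 is the 5' end; for `"-"` transcripts
#' that is the rightmost genomic base) to the genomic intervals it covers.
#' Returned blocks are always in ascending genomic order.
#'
#' @param t a [transcript_model()].
#' @param t_start 0-based transcript offset.
#' @param length number of transcript bases.
#' @return a `true_origin`: list with `chrom`, `strand` and a `blocks`
#'   matrix whose widths sum to `length`.
#' @export
project_to_genome <- function(t, t_start, length) {
  if (t_start < 0L || length < 1L || t_start + length > t$length) {
    stop("window [", t_start, ", ", t_start + length,
         ") outside transcript of length ", t$length)
  }
  pr <- project_windows(t, t_start, length)
  true_origin(t$chrom, t$strand,
              blocks_from_strings(pr$starts, pr$sizes))
}

true_origin <- function(chrom, strand, blocks) {
  structure(list(chrom = chrom, strand = strand, blocks = blocks),
            class = "true_origin")
}

blocks_from_strings <- function(starts_str, sizes_str) {
  bs <- as.integer(strsplit(starts_str, ",", fixed = TRUE)[[1L]])
  sz <- as.integer(strsplit(sizes_str, ",", fixed = TRUE)[[1L]])
  cbind(start = bs, end = bs + sz)
}

# Vectorized projection of many equal-length windows onto one transcript.
# Returns comma-joined genomic block starts/sizes (ascending order) per
# window. Windows on '-' transcripts are mirrored into plus-orientation
# transcript coordinates first.
project_windows <- function(t, t_starts, len) {
  widths <- t$blocks[, 2L] - t$blocks[, 1L]
  cum0 <- c(0L, cumsum(widths))
  ps <- if (t$strand == "-") t$length - t_starts - len else t_starts
  first <- findInterval(ps, cum0)
  last <- findInterval(ps + len - 1L, cum0)
  n <- length(ps)
  starts_str <- character(n)
  sizes_str <- character(n)
  one <- first == last
  if (any(one)) {
    gs <- t$blocks[first[one], 1L] + (ps[one] - cum0[first[one]])
    starts_str[one] <- as.character(gs)
    sizes_str[one] <- as.character(len)
  }
  for (i in which(!one)) {
    j <- first[i]:last[i]
    gs <- t$blocks[j, 1L] + pmax(0L, ps[i] - cum0[j])
    ge <- t$blocks[j, 1L] + pmin(widths[j], ps[i] + len - cum0[j])
    starts_str[i] <- paste(gs, collapse = ",")
    sizes_str[i] <- paste(ge - gs, collapse = ",")
  }
  list(starts = starts_str, sizes = sizes_str)
}

# Transcript (oriented) offset of a genomic 0-based position, or NA if the
# position falls outside the transcript's blocks.
transcript_offset_of <- function(t, gpos0) {
  widths <- t$blocks[, 2L] - t$blocks[, 1L]
  cum0 <- c(0L, cumsum(widths))
  j <- findInterval(gpos0, t$blocks[, 1L])
  ok <- j >= 1L & gpos0 < t$blocks[pmax(j, 1L), 2L]
  plus_off <- ifelse(ok, cum0[pmax(j, 1L)] + gpos0 - t$blocks[pmax(j, 1L), 1L], NA_integer_)
  if (t$strand == "-") {
    ifelse(is.na(plus_off), NA_integer_, t$length - 1L - plus_off)
  } else {
    plus_off
  }
}
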