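# Shared in-code fixtures for the test suite.

# A 10 bp chromosome and the two-exon transcript used throughout the
# projection examples: blocks [(0,4),(6,10)] on chr1 = "ACGTACGTAC".
toy_genome <- function() {
  g <- c(chr1 = "ACGTACGTAC")
  class(g) <- c("genome_ref", class(g))
  g
}

toy_tx <- function(strand = "+") {
  transcript_model("tx1", "chr1", strand, cbind(c(0L, 6L), c(4L, 10L)))
}

# Brute-force per-base transcript -> genome coordinate map (the projection
# oracle): element i+1 is the 0-based genomic position of transcript
# offset i, honouring orientation.
brute_tx_map <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$blocks)), function(j) {
    t$blocks[j, 1L]:(t$blocks[j, 2L] - 1L)
  }))
  if (t$strand == "-") rev(pos) else pos
}

write_fasta <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

write_bed12 <- function(lines, path) {
  writeLines(lines, path)
  path
}

# BED12 line helper: blocks as absolute 0-based (start, end) matrix.
bed12_line <- function(chrom, blocks, id = "tx", strand = "+") {
  cs <- min(blocks); ce <- max(blocks)
  paste(chrom, cs, ce, id, 0, strand, cs, ce, "0", nrow(blocks),
        paste(blocks[, 2] - blocks[, 1], collapse = ","),
        paste(blocks[, 1] - cs, collapse = ","), sep = "\t")
}

# Minimal alignment-record data frame for direct classify_* calls.
rec <- function(qname, flag = 0L, chrom = "chr1", pos = 1L, cigar = "4M",
                tlen = 0L, seq = "ACGT", nh = NA_integer_) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, tlen = tlen, seq = seq, nh = nh,
             stringsAsFactors = FALSE)
}

# Brute-force pileup oracle: walks each CIGAR with a simple per-op loop and
# counts bases per (chrom, 0-based position), independent of build_pileup.
brute_pileup <- function(aln, genome) {
  counts <- list()
  for (i in seq_len(nrow(aln))) {
    ref0 <- aln$pos[i] - 1L
    q <- 1L
    ops <- regmatches(aln$cigar[i], gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          base <- substr(aln$seq[i], q, q)
          key <- paste(aln$chrom[i], ref0)
          if (is.null(counts[[key]])) {
            counts[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
          }
          counts[[key]][base] <- counts[[key]][base] + 1L
          ref0 <- ref0 + 1L
          q <- q + 1L
        }
      } else if (type %in% c("D", "N")) {
        ref0 <- ref0 + n
      } else if (type %in% c("I", "S")) {
        q <- q + n
      }
    }
  }
  if (length(counts) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  ks <- strsplit(names(counts), " ", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(ks, `[`, character(1), 1),
    pos = as.integer(vapply(ks, `[`, character(1), 2)),
    do.call(rbind, counts),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), ]
  out$ref <- substr(genome[out$chrom], out$pos + 1L, out$pos + 1L)
  out$depth <- out$A + out$C + out$G + out$T + out$N
  rownames(out) <- NULL
  out
}

# Arbitrary-precision-style binomial upper tail by direct log-space
# summation (independent of stats::pbinom).
brute_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  terms <- vapply(x:n, function(k) {
    lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  }, numeric(1))
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}
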