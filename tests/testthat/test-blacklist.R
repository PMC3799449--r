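# Pileup construction, SND and variant calling, exon/database annotation,
# blacklist serialization.

test_that("pileup handles mismatches, splice gaps and overlapping reads", {
  g <- c(chr1 = "ACGAACGTAC")
  class(g) <- c("genome_ref", class(g))
  one <- rec("r1", pos = 1L, cigar = "4M", seq = "ACGT")
  p <- build_pileup(one, g)
  expect_equal(nrow(p), 4L)
  col3 <- p[p$pos == 3L, ]
  expect_identical(col3$ref, "A")
  expect_equal(col3$T, 1L)
  expect_equal(col3$depth, 1L)

  spliced <- rec("r2", pos = 1L, cigar = "2M3N2M", seq = "ACCG")
  ps <- build_pileup(spliced, g)
  expect_equal(ps$pos, c(0L, 1L, 5L, 6L))  # intronic 2..4 uncovered

  both <- rbind(one, rec("r3", pos = 3L, cigar = "4M", seq = "GAAC"))
  pb <- build_pileup(both, g)
  expect_equal(pb$depth[pb$pos == 3L], 2L)

  # CIGAR/sequence length mismatch is rejected with a warning
  bad <- rbind(one, rec("r4", pos = 1L, cigar = "6M", seq = "ACGT"))
  expect_warning(pbad <- build_pileup(bad, g), "mismatch")
  expect_equal(attr(pbad, "n_rejected"), 1L)
  expect_identical(pbad$depth, p$depth)
})

test_that("pileup and SND calls equal the brute-force per-base oracle", {
  ref <- make_toy_reference(fixture_spec(seed = 21, n_chroms = 2, n_genes = 4,
                                         paralog_pairs = 1, divergence = 0.03))
  reads <- simulate_se(ref$transcripts, ref$genome, sim_params(L = 35))
  expect_gt(nrow(reads), 1000L)
  # perturb: relocate one junction family to the paralog locus so real
  # mismatches (hence SNDs) exist, and shift a couple of reads
  tx <- ref$transcripts
  jun <- reads$name[grepl(",", sub("^BO\\|[^|]*\\|[^|]*\\|", "", reads$name))]
  sam <- tempfile(fileext = ".sam")
  make_sam_fixture(reads, ref$genome, sam, perturbations = list(
    perturbation("^BO\\|chr1\\|\\+\\|1[0-9][0-9],", "relocate_to",
                 chrom = "chr1", pos0 = 430L),
    perturbation("\\|330\\|", "shift", k = 7L)
  ))
  aln <- read_alignments(sam)
  mapped <- aln[!bitwAnd(aln$flag, 4L) & !bitwAnd(aln$flag, 256L) &
                  !bitwAnd(aln$flag, 2048L), ]
  pile <- build_pileup(mapped, ref$genome)
  oracle <- brute_pileup(mapped, ref$genome)
  expect_equal(nrow(pile), nrow(oracle))
  expect_equal(pile$chrom, oracle$chrom)
  expect_equal(pile$pos, oracle$pos)
  for (b in c("A", "C", "G", "T", "N")) {
    expect_equal(pile[[b]], unname(oracle[[b]]), info = b)
  }
  expect_equal(pile$depth, unname(oracle$depth))

  # SND calls match a direct scan of the oracle counts
  snds <- call_snds(pile)
  o_alt <- apply(oracle, 1L, function(r) {
    counts <- as.integer(r[c("A", "C", "G", "T")])
    names(counts) <- c("A", "C", "G", "T")
    counts[r[["ref"]]] <- -1L
    sum(counts > 0L) > 0L
  })
  expect_equal(nrow(snds), sum(o_alt))
  expect_equal(paste(snds$chrom, snds$pos),
               paste(oracle$chrom, oracle$pos)[o_alt])
})

test_that("a clean alignment of reference reads yields zero SNDs", {
  ref <- make_toy_reference(fixture_spec(seed = 8, n_chroms = 1, n_genes = 3))
  reads <- simulate_se(ref$transcripts, ref$genome, sim_params(L = 30))
  sam <- tempfile(fileext = ".sam")
  make_sam_fixture(reads, ref$genome, sam)
  aln <- read_alignments(sam)
  pile <- build_pileup(aln, ref$genome)
  expect_gt(nrow(pile), 0L)
  expect_equal(nrow(call_snds(pile)), 0L)
})

test_that("SND alt allele ties break lexicographically", {
  g <- c(chr1 = "AAAA")
  class(g) <- c("genome_ref", class(g))
  aln <- rbind(rec("r1", pos = 1L, cigar = "1M", seq = "G"),
               rec("r2", pos = 1L, cigar = "1M", seq = "T"),
               rec("r3", pos = 2L, cigar = "1M", seq = "T"),
               rec("r4", pos = 2L, cigar = "1M", seq = "C"))
  snds <- call_snds(build_pileup(aln, g))
  expect_identical(snds$alt[snds$pos == 0L], "G")  # G before T
  expect_identical(snds$alt[snds$pos == 1L], "C")  # C before T
})

test_that("variant preset enforces depth, support, frequency and the binomial tail", {
  mk <- function(depth, alt) {
    data.frame(chrom = "chr1", pos = 0L, ref = "A",
               A = depth - alt, C = alt, G = 0L, T = 0L, N = 0L,
               depth = depth, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(call_variants(mk(29L, 12L))), 0L)  # min_coverage 30
  expect_equal(nrow(call_variants(mk(90L, 9L))), 0L)   # min_reads2 10
  expect_equal(nrow(call_variants(mk(100L, 9L))), 0L)
  expect_equal(nrow(call_variants(mk(100L, 50L))), 1L)
  expect_equal(nrow(call_variants(mk(200L, 19L))), 0L) # freq 0.095 < 0.1

  # binomial tail against the independent log-space summation oracle
  for (case in list(c(100L, 50L), c(60L, 12L), c(40L, 10L), c(1000L, 15L))) {
    depth <- case[1]; alt <- case[2]
    oracle_p <- brute_binom_tail(alt, depth, 0.001)
    got <- call_variants(mk(depth, alt))
    if (oracle_p <= 1e-20 && alt / depth >= 0.1 && alt >= 10L && depth >= 30L) {
      expect_equal(nrow(got), 1L, info = paste(depth, alt))
      expect_equal(got$p_value, oracle_p, tolerance = 1e-10)
    } else {
      expect_equal(nrow(got), 0L, info = paste(depth, alt))
    }
  }
})

test_that("raising any variant threshold never adds calls", {
  # deterministic grid spanning all threshold boundaries
  grid <- expand.grid(depth = c(20L, 29L, 30L, 31L, 50L, 100L, 200L),
                      alt = c(5L, 9L, 10L, 11L, 15L, 20L, 40L))
  grid <- grid[grid$alt <= grid$depth, ]
  n <- nrow(grid)
  depth <- grid$depth; alt <- grid$alt
  pile <- data.frame(chrom = "chr1", pos = seq_len(n) - 1L, ref = "A",
                     A = depth - alt, C = alt, G = 0L, T = 0L, N = 0L,
                     depth = depth, stringsAsFactors = FALSE)
  base <- variant_thresholds(30L, 10L, 0.1, 1e-10)
  n_base <- nrow(call_variants(pile, base))
  harder <- list(variant_thresholds(50L, 10L, 0.1, 1e-10),
                 variant_thresholds(30L, 15L, 0.1, 1e-10),
                 variant_thresholds(30L, 10L, 0.2, 1e-10),
                 variant_thresholds(30L, 10L, 0.1, 1e-30))
  for (th in harder) {
    calls <- call_variants(pile, th)
    expect_lte(nrow(calls), n_base)
    # nesting: every call under harder thresholds is also called at base
    expect_true(all(calls$pos %in% call_variants(pile, base)$pos))
  }
  # every variant call position is an SND position (threshold nesting);
  # call_variants reports 1-based, call_snds internal 0-based
  vpos0 <- call_variants(pile, base)$pos - 1L
  expect_true(all(vpos0 %in% call_snds(pile)$pos))
})

test_that("exon annotation respects half-open block boundaries", {
  tx <- list(transcript_model("t", "chr1", "+", cbind(10L, 20L)))
  snds <- data.frame(chrom = "chr1", pos = c(9L, 10L, 19L, 20L), ref = "A",
                     alt = "G", alt_count = 1L, depth = 1L, in_exon = NA,
                     db_flags = "", stringsAsFactors = FALSE)
  out <- annotate_exonic(snds, tx)
  expect_equal(out$in_exon, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("database intersection flags and counts overlaps", {
  snds <- data.frame(chrom = "chr1", pos = c(0L, 5L, 9L), ref = "A", alt = "G",
                     alt_count = 1L, depth = 1L, in_exon = NA, db_flags = "",
                     stringsAsFactors = FALSE)
  db1 <- data.frame(chrom = "chr1", pos = 6L)  # 1-based: hits pos0 = 5
  r <- intersect_database(snds, db1, "dbsnp")
  expect_equal(r$count, 1L)
  expect_identical(r$snds$db_flags, c("", "dbsnp", ""))
  r0 <- intersect_database(snds, db1[0, ], "cosmic")
  expect_equal(r0$count, 0L)
  all_db <- data.frame(chrom = "chr1", pos = c(1L, 6L, 10L))
  r2 <- intersect_database(r$snds, all_db, "cosmic")
  expect_equal(r2$count, 3L)
  expect_identical(r2$snds$db_flags, c("cosmic", "dbsnp,cosmic", "cosmic"))
})

test_that("blacklist TSV round trips exactly and serializes 1-based positions", {
  set.seed(9)
  n <- 100L
  snds <- structure(data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(10000L, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_count = sample.int(50L, n, replace = TRUE),
    depth = sample(50:100, n, replace = TRUE),
    in_exon = sample(c(TRUE, FALSE), n, replace = TRUE),
    db_flags = sample(c("", "dbsnp", "dbsnp,cosmic"), n, replace = TRUE),
    stringsAsFactors = FALSE), class = c("snd", "data.frame"))
  path <- tempfile(fileext = ".tsv")
  write_blacklist(snds, path)
  back <- read_blacklist(path)
  expect_equal(back, snds, ignore_attr = TRUE)

  # file positions are 1-based
  one <- snds[1, ]; one$pos <- 0L
  write_blacklist(one, path)
  row <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_identical(row[2], "1")

  # empty list -> header-only file
  write_blacklist(snds[0, ], path)
  expect_equal(length(readLines(path)), 1L)

  # malformed rows error with a line number
  writeLines(c(readLines(path)[1], "chr1\t5\tA"), path)
  expect_error(read_blacklist(path), "line 2")
})
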