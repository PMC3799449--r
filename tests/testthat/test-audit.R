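# Alignment audit: classification of SE reads and PE pairs against their
# encoded truths, junction/paralog attribution, summary statistics.

truth1 <- function(start = 100L, strand = "+", nblocks = 1L) {
  b <- if (nblocks == 1L) cbind(start, start + 50L) else
    cbind(c(start, start + 80L), c(start + 25L, start + 105L))
  mapblack:::true_origin("chr1", strand, b)
}

test_that("single-read classification respects the 5 bp shift tolerance", {
  tr <- truth1(100L)
  exact <- rec("q", pos = 101L)  # 1-based pos for 0-based truth start 100
  expect_identical(classify_read(exact, tr), "uniquely_correct")
  expect_identical(classify_read(rec("q", pos = 101L + 5L), tr), "uniquely_correct")
  expect_identical(classify_read(rec("q", pos = 101L - 5L), tr), "uniquely_correct")
  expect_identical(classify_read(rec("q", pos = 101L + 6L), tr), "uniquely_mismapped")
  # different chromosome: mismapped, never unmapped
  expect_identical(classify_read(rec("q", chrom = "chr2", pos = 101L), tr),
                   "uniquely_mismapped")
  # no mapped record
  expect_identical(classify_read(rec("q", flag = 4L, chrom = NA, pos = NA), tr),
                   "unmapped")
  # primary + secondary, or an NH tag > 1
  two <- rbind(rec("q", pos = 101L), rec("q", flag = 256L, pos = 500L))
  expect_identical(classify_read(two, tr), "multimapped")
  expect_identical(classify_read(rec("q", pos = 101L, nh = 3L), tr), "multimapped")
  # supplementary records are ignored for hit counting
  supp <- rbind(rec("q", pos = 101L), rec("q", flag = 2048L, pos = 900L))
  expect_identical(classify_read(supp, tr), "uniquely_correct")
  expect_error(classify_read(rbind(rec("a"), rec("b")), tr), "qname")
})

test_that("tolerance is monotone: growing it never turns correct into mismapped", {
  tr <- truth1(100L)
  for (shift in 0:12) {
    cls <- vapply(c(2L, 5L, 8L, 15L), function(tol) {
      classify_read(rec("q", pos = 101L + shift), tr, tolerance = tol)
    }, character(1))
    correct <- cls == "uniquely_correct"
    expect_true(all(diff(as.integer(correct)) >= 0L),
                info = paste("shift", shift))
  }
})

test_that("pair classification applies the unmapped-mate, 1 Mb and conjunction rules", {
  truths <- list(truth1(100L), truth1(300L))
  m1 <- rec("q", flag = 64L + 1L, pos = 101L, tlen = 300L)
  m2 <- rec("q", flag = 128L + 1L, pos = 301L, tlen = -300L)
  expect_identical(classify_pair(rbind(m1, m2), truths), "uniquely_correct")

  big <- rbind(transform(m1, tlen = 1000001L), m2)
  expect_identical(classify_pair(big, truths), "unmapped")
  ok_big <- rbind(transform(m1, tlen = 1000000L), m2)
  expect_identical(classify_pair(ok_big, truths), "uniquely_correct")

  # missing mate record and mate-unmapped flag are both unmapped
  expect_identical(classify_pair(m1, truths), "unmapped")
  expect_identical(classify_pair(rbind(transform(m1, flag = 64L + 8L), m2), truths),
                   "unmapped")

  # one correct mate + one mismapped mate -> pair mismapped (conjunction)
  off <- rbind(m1, transform(m2, pos = 351L))
  expect_identical(classify_pair(off, truths), "uniquely_mismapped")

  # a multimapped mate dominates over mismapping
  multi <- rbind(m1, transform(m2, nh = 2L))
  expect_identical(classify_pair(multi, truths), "multimapped")
})

test_that("spans_junction is block-count at the truth", {
  expect_true(spans_junction(truth1(nblocks = 2L)))
  expect_false(spans_junction(truth1(nblocks = 1L)))
  three <- mapblack:::true_origin("chr1", "+",
                                  cbind(c(0L, 10L, 20L), c(5L, 15L, 25L)))
  expect_true(spans_junction(three))
})

test_that("paralog attribution uses the annotation and symmetric pair table", {
  tx <- list(
    geneA = transcript_model("geneA", "chr1", "+", cbind(c(0L, 100L), c(50L, 150L))),
    geneB = transcript_model("geneB", "chr1", "+", cbind(c(500L, 600L), c(550L, 650L))),
    geneC = transcript_model("geneC", "chr2", "+", cbind(0L, 100L))
  )
  par <- data.frame(gene_a = "geneA", gene_b = "geneB")
  tr <- mapblack:::true_origin("chr1", "+", cbind(10L, 60L))
  expect_true(maps_to_paralog("chr1", 510L, tr, tx, par))    # into geneB exon
  expect_true(maps_to_paralog("chr1", 110L,
                              mapblack:::true_origin("chr1", "+", cbind(505L, 545L)),
                              tx, par))                      # symmetric: B read into A exon
  expect_false(maps_to_paralog("chr1", 560L, tr, tx, par))   # geneB intron
  expect_false(maps_to_paralog("chr1", 200L, tr, tx, par))   # intergenic
  expect_false(maps_to_paralog("chr1", 510L, tr, tx,
                               data.frame(gene_a = character(0),
                                          gene_b = character(0))))
  # unknown source gene -> NA
  orphan <- mapblack:::true_origin("chr1", "+", cbind(900L, 950L))
  expect_true(is.na(maps_to_paralog("chr1", 510L, orphan, tx, par)))
})

test_that("audit over an engineered SAM reproduces the planted ground truth", {
  ref <- make_toy_reference(fixture_spec(seed = 11, n_chroms = 1, n_genes = 4,
                                         paralog_pairs = 1, divergence = 0.05))
  reads <- simulate_se(ref$transcripts, ref$genome, sim_params(L = 40))
  # plant: 3 dropped, 2 duplicated (multimapped), shift +6 on one family
  drop_names <- reads$name[1:3]
  dup_names <- reads$name[4:5]
  shift_name <- reads$name[6]
  sam <- tempfile(fileext = ".sam")
  esc <- function(x) gsub("\\|", "\\\\|", gsub("\\+", "\\\\+", x))
  make_sam_fixture(reads, ref$genome, sam, perturbations = list(
    perturbation(paste0("^(", paste(esc(drop_names), collapse = "|"), ")$"), "drop"),
    perturbation(paste0("^(", paste(esc(dup_names), collapse = "|"), ")$"),
                 "duplicate_at", chrom = "chr1", pos0 = 9000L),
    perturbation(paste0("^", esc(shift_name), "$"), "shift", k = 6L)
  ))
  cls <- audit_alignments(sam, "se", transcripts = ref$transcripts,
                          paralogs = ref$paralogs)
  got <- table(cls$category)
  expect_equal(unname(got["unmapped"]), 3L)
  expect_equal(unname(got["multimapped"]), 2L)
  expect_equal(unname(got["uniquely_mismapped"]), 1L)
  expect_equal(sum(got), nrow(reads))  # partition conserves the input
  expect_identical(as.character(cls$category[cls$qname == shift_name]),
                   "uniquely_mismapped")

  # shift of exactly 5 stays correct
  sam5 <- tempfile(fileext = ".sam")
  make_sam_fixture(reads, ref$genome, sam5, perturbations = list(
    perturbation(paste0("^", esc(shift_name), "$"), "shift", k = 5L)
  ))
  cls5 <- audit_alignments(sam5, "se")
  expect_identical(as.character(cls5$category[cls5$qname == shift_name]),
                   "uniquely_correct")
})

test_that("reads absent from the SAM are counted as unmapped via all_names", {
  ref <- make_toy_reference(fixture_spec(seed = 4, n_chroms = 1, n_genes = 2))
  reads <- simulate_se(ref$transcripts, ref$genome, sim_params(L = 40))
  sam <- tempfile(fileext = ".sam")
  make_sam_fixture(reads[-(1:5), ], ref$genome, sam)
  cls <- audit_alignments(sam, "se", all_names = reads$name)
  expect_equal(sum(cls$category == "unmapped"), 5L)
  expect_equal(nrow(cls), nrow(reads))
})

test_that("summaries report proportions and junction/paralog fractions", {
  cls <- data.frame(
    qname = paste0("q", 1:10),
    category = factor(c(rep("uniquely_correct", 8), "uniquely_mismapped",
                        "unmapped"), levels = mapblack:::CATEGORIES),
    spans_junction = c(rep(FALSE, 8), TRUE, FALSE),
    mapped_to_paralog = c(rep(NA, 8), TRUE, NA),
    tag = "REF", stringsAsFactors = FALSE
  )
  s <- summarize_classifications(cls)
  expect_equal(s$proportions[match(c("uniquely_correct", "uniquely_mismapped",
                                     "unmapped"), s$categories)],
               c(0.8, 0.1, 0.1))
  expect_equal(sum(s$proportions), 1, tolerance = 1e-12)
  expect_equal(s$junction_fraction, 1)
  expect_equal(s$paralog_fraction, 1)

  none <- cls[cls$category != "uniquely_mismapped", ]
  s2 <- summarize_classifications(none)
  expect_true(is.na(s2$junction_fraction))
  expect_error(summarize_classifications(cls[0, ]), "summarize")
})

test_that("REF-tagged reads are excluded from SNP-mode statistics", {
  ref <- make_toy_reference(fixture_spec(seed = 6, n_chroms = 1, n_genes = 2,
                                         snp_count = 4))
  params <- sim_params(L = 30)
  ref_reads <- simulate_se(ref$transcripts, ref$genome, params)
  snp_reads <- inject_snps(ref$transcripts, ref$genome, ref$snps, params)
  both <- rbind(ref_reads, snp_reads)
  attr(both, "L") <- 30L
  sam <- tempfile(fileext = ".sam")
  make_sam_fixture(both, ref$genome, sam)
  cls <- audit_alignments(sam, "se", drop_ref_tag = TRUE)
  expect_equal(nrow(cls), nrow(snp_reads))
  expect_true(all(grepl("^SNP:", cls$tag)))
})
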