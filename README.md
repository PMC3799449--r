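# mapblack

Mappability blacklists for variant-call filtering.

Short-read aligners sometimes place a read *uniquely* at the wrong genomic
location — most often when the read's true origin spans a splice junction
(RNA-seq) or lies in one member of a paralogous gene pair. At the reported
location some read bases disagree with the reference, and over many reads
those disagreements pile up into what looks exactly like a single-nucleotide
variant. `mapblack` identifies these artifact positions ahead of time:

1. **Simulate** exhaustive reads from the reference itself — every
   transcript position starts one read of length *L*, so a transcript of
   length *T* yields *T − L + 1* reads and every internal base is covered by
   exactly *L* reads. By construction every read matches the reference
   perfectly. Single-end, paired-end (fixed outer insert) and unspliced
   exome-target modes; optional per-base sequencing-error injection
   (default rate 10⁻⁴) and known-SNP injection (one alternate allele per
   read; multi-SNP reads duplicated, SNP-free reads dropped).
2. **Align** the reads with *your* aligner and settings (external to this
   package). Each read's true origin is encoded in its name, so any SAM/BAM
   can be audited.
3. **Audit** every read against its encoded truth: `unmapped`,
   `multimapped`, `uniquely_correct` (single hit within 5 bp of the truth)
   or `uniquely_mismapped`, with junction-spanning and paralog attribution
   for the mismapped ones. Pairs with an unmapped mate or a template length
   over 1 Mb count as unmapped; a pair is correct only if both mates are.
4. **Blacklist**: build a CIGAR-aware pileup from the uniquely mapped
   reads and record every single-nucleotide difference (SND) — a position
   covered by at least one non-reference base. Because the input reads were
   error-free by construction, every SND is a mapping artifact. A stricter
   preset (depth ≥ 30, alt reads ≥ 10, VAF ≥ 0.1, one-sided binomial tail
   ≤ 10⁻²⁰) flags the positions likely to be *called* as variants.
5. **Filter** candidate variant calls from real data against the blacklist
   (position + allele by default), after replicate intersection and
   database pre-filtering, and quantify blacklist enrichment of novel calls
   with a binomial upper tail P(X ≥ x), X ~ B(n, p).

A deterministic toy-fixture generator (multi-exon genes, diverged paralog
pairs, truth-perturbed SAM files) makes the whole pipeline testable with no
external aligner; it is first-class, tested code.

## Worked example

A miniature of the whole causal chain: junction-spanning reads of one gene
are planted onto its diverged paralog, audited, turned into a blacklist,
and a variant call at a blacklisted position is filtered out.

```r
library(mapblack)

ref    <- make_toy_reference(fixture_spec(seed = 7))   # 2 chroms, paralog pair
reads  <- simulate_se(ref$transcripts, ref$genome, sim_params(L = 50))
nrow(reads)
#> [1] 1528

a <- ref$transcripts[[ref$paralogs$gene_a[1]]]
b <- ref$transcripts[[ref$paralogs$gene_b[1]]]
offset <- min(b$blocks) - min(a$blocks)
junction_reads_of_a <- function(nms) vapply(nms, function(n) {
  o <- decode_truth(n)$origins[[1]]
  o$chrom == a$chrom && nrow(o$blocks) >= 2 &&
    o$blocks[1, 1] >= min(a$blocks) && o$blocks[1, 1] < max(a$blocks)
}, logical(1))

sam <- tempfile(fileext = ".sam")
make_sam_fixture(reads, ref$genome, sam, perturbations = list(
  perturbation(junction_reads_of_a, "shift", k = offset)))

cls <- audit_alignments(sam, "se", transcripts = ref$transcripts,
                        paralogs = ref$paralogs)
s <- summarize_classifications(cls)
setNames(s$counts, s$categories)
#>           unmapped        multimapped   uniquely_correct uniquely_mismapped
#>                  0                  0               1430                 98
c(s$junction_fraction, s$paralog_fraction)
#> [1] 1 1
```

All 98 mismapped reads span a junction at their truth and landed in the
paralog — the characteristic error mode this package exists to catch. The
mismatches they deposit become the blacklist:

```r
pile <- build_pileup(read_alignments(sam), ref$genome)
snds <- annotate_exonic(call_snds(pile), ref$transcripts)
head(snds, 3)
#>   chrom pos ref alt alt_count depth in_exon db_flags
#> 1  chr1 774   T   G         4    39    TRUE
#> 2  chr1 983   A   T        36    86    TRUE
#> 3  chr1 989   A   T        30    80    TRUE

variants <- data.frame(chrom = "chr1", pos = snds$pos[1] + 1L,
                       ref = snds$ref[1], alt = snds$alt[1],
                       depth = 60L, alt_count = 31L, sample = "u87")
rep <- filter_blacklist(variants, snds)
c(rep$n_blacklisted, rep$n_retained)
#> [1] 1 0

enrichment_test(92, 129, 37540 / 73418700)
#> [1] 4.512063e-271
```

Each SND row is a genomic position (0-based in memory, 1-based in the TSV
written by `write_blacklist()`), the reference base, the most frequent
non-reference allele observed there, and its supporting counts. The
enrichment call shows the binomial tail for 92 of 129 novel variants
falling on blacklisted positions when the blacklisted fraction of exon
space is 37 540 / 73 418 700 — overwhelming evidence that such a set is
dominated by mapping artifacts.

See `vignettes/mappability-blacklists.Rmd` for the model, the parameter
conventions (insert size, tolerance, thresholds), and what the toy fixtures
do and do not emulate.

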