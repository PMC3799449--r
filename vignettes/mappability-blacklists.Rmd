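---
title: "Mappability blacklists: from simulated reads to filtered variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mappability blacklists: from simulated reads to filtered variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapblack)
```

## The problem

Short-read aligners make systematic errors. A read whose true origin spans a
splice junction, or lies in one member of a paralogous gene pair, may be
reported *uniquely* at the wrong place — and, because the reported location
differs from the read's origin, some of its bases will disagree with the
reference there. Piled up over many reads, those disagreements look exactly
like single-nucleotide variants. Such mapping artifacts contaminate variant
calls from RNA-seq (where spliced alignment is hardest) and, to a lesser
degree, whole-exome sequencing.

The remedy implemented here is simulation-based: generate reads *from the
reference itself*, so that by construction every base of every read matches
the genome; align them with the user's own aligner and settings; and record
every position where the aligned reads nonetheless mismatch the reference.
Any such "single nucleotide difference" (SND) is an artifact of mismapping,
not biology. The set of SNDs — positions plus the observed non-reference
allele — is a *blacklist* specific to the aligner, read length and reference
used, and candidate variant calls from real data can be screened against it.

## The simulation model

Reads are generated exhaustively and deterministically, not sampled:

* **Single-end mode.** Every position of every transcript is the start of
  one read of length $L$; a transcript of length $T \ge L$ yields exactly
  $T - L + 1$ reads, and every internal transcript base is covered by
  exactly $L$ reads. Transcripts shorter than $L$ yield none. The supported
  study lengths are the common short-read settings (36–200 bp); $L$ is a
  free parameter.
* **Paired-end mode.** Fragments of a fixed *outer* insert length are tiled
  the same way; mate 1 is the first $L$ bases, mate 2 the reverse
  complement of the last $L$. We interpret "insert size" as the outer
  fragment length: with the common $2 \times 100$/insert-200 configuration
  this gives abutting mates, whereas the inner-distance reading would be
  degenerate at $2 \times 200$.
* **Exome (WES) mode.** The same machinery over single-block target
  intervals — no junctions exist, which is precisely the contrast of
  interest with RNA-seq.

Transcripts are modeled as ordered genomic exon blocks with strand
(0-based, half-open internally; BED12 on disk). Negative-strand transcripts
are reverse-complemented, so transcript offset 0 is always the 5' end.
`project_to_genome()` maps any transcript window to its genomic blocks; a
read "spans a junction" iff its projected origin has at least two blocks.
Each read's origin is encoded in its name
(`BO|chrom|strand|starts|sizes|tag|mate`), so any SAM produced by any
aligner can be audited against the truth with no side tables.

Uniform, exhaustive coverage is deliberately unrealistic: the goal is to
enumerate every possible mapping error of a given aligner configuration,
which random coverage-matched simulation cannot do.

### Error and SNP injection

Two perturbed read sets extend the reference-only analysis:

* **Sequencing errors.** Each base is substituted independently with
  probability $10^{-4}$ (the default), uniformly to one of the three other
  bases. Internally this is sampled as a per-read binomial count of
  substituted positions followed by distinct uniform offsets —
  distributionally identical to per-base Bernoulli trials but vectorizable.
  A log of (read, offset, old, new) records every edit, and affected reads
  are re-tagged `ERR`.
* **Known SNPs.** For every exhaustive read and every cataloged SNP falling
  inside the read's origin, one copy of the read is emitted with that SNP's
  alternate allele substituted (complemented on minus-strand transcripts).
  Reads covering several SNPs are duplicated, one copy per SNP, so each
  emitted read carries exactly one non-reference base; reads covering no
  SNP are dropped. At internal transcript positions each SNP is therefore
  covered by exactly $L$ alt-carrying reads. SNP rows that are not
  biallelic SNVs, or whose stated reference allele disagrees with the
  genome, are rejected with counts. The intended protocol co-aligns the
  SNP-injected reads with the reference-only reads (so junctions are
  discoverable at full coverage) and drops the `REF`-tagged reads after
  alignment; `audit_alignments(drop_ref_tag = TRUE)` implements the
  post-filter.

Base qualities are written as constant Q40: every downstream threshold sets
minimum quality to zero, so qualities are inert by design.

## The audit

Every read (or pair) gets exactly one category:

* **unmapped** — no mapped record; for pairs, also a missing or unmapped
  mate, or an absolute template length above 1 Mb (a safeguard against
  absurd "proper" pairs).
* **multimapped** — more than one reported location, via secondary records
  or a hit-count (`NH`) tag above 1. Supplementary records are ignored for
  counting.
* **uniquely_correct** — a single location on the truth chromosome whose
  leftmost aligned base is within 5 bp of the truth's leftmost base.
* **uniquely_mismapped** — a single location anywhere else (including other
  chromosomes).

The 5 bp tolerance avoids penalizing reads whose junction lies within a few
bases of a read end, where aligners legitimately slip the boundary; the
comparison is leftmost-to-leftmost on the same chromosome, which is cheap
and matches that motivation. For pairs, the conjunction rule applies: a
pair is correct only if *both* mates are within tolerance (whether a
half-correct pair should count as mismapped is genuinely underdetermined;
we chose the conjunction and state it here rather than hiding it).
Mismapped reads are additionally annotated with whether their truth spans a
junction and whether the reported location falls in an exon of a known
paralog of the source gene (the paralog table is treated as symmetric).

## SNDs, variants and the blacklist

The pileup is computed directly from the uniquely mapped records,
CIGAR-aware (`M/=/X` consume both reference and query, `I/S` query only,
`D/N` reference only, so skipped introns contribute no counts). Records
whose CIGAR length disagrees with the sequence are rejected with a warning.

Two calling presets mirror standard usage:

| preset | min depth | min alt reads | min VAF | p cutoff |
|---|---|---|---|---|
| SND | 1 | 1 | 0 | — |
| variant | 30 | 10 | 0.1 | 1e-20 |

An SND is any column with at least one non-reference, non-N base; the
recorded alternate allele is the most frequent non-reference base, with
ties broken lexicographically (A < C < G < T) — a documented convention,
since multiple alternates at one position are rare in this setting and a
single-alt row keeps the blacklist dialect compact. The variant preset adds
a one-sided binomial significance test: a column is called when
$P(X \ge \text{alt} \mid n = \text{depth}, p = e) \le 10^{-20}$ with a
configurable sequencing-error rate $e$ (default 0.001). The upstream tool
this parameterization follows delegates its significance model to an
external caller whose internals are unspecified; an explicit, reproducible
binomial tail with the same thresholds is preferable to emulating
unspecified internals. By construction every variant call is also an SND,
and raising any threshold can only remove calls — both properties are
tested.

Blacklist rows are written as TSV (`chrom`, 1-based `pos`, `ref`, `alt`,
`alt_count`, `depth`, `in_exon`, `db_flags`); reading a written blacklist
reproduces the in-memory object exactly. SNDs can be flagged against any
number of database position sets (e.g. dbSNP, COSMIC) and against the exon
union of the annotation.

## Filtering candidate variants

The end-use pipeline mirrors common practice for cell-line replicates:
drop excluded chromosomes (chrM by default), keep calls present in every
replicate (keyed on chrom/pos/alt — the intersection is over *called
variants*, not over supporting evidence), remove non-exonic positions and
positions known to databases, then screen the surviving novel calls against
one or more blacklists. Matching is on position *and* allele by default
(`position_allele`); position-only matching is one flag away and both
counts appear in every report, because published applications of this
scheme do not always state which was used.

Enrichment of novel calls for blacklist positions is measured by a binomial
upper tail: with $n$ novel variants of which $x$ sit at blacklisted
positions, and $p$ the blacklisted fraction of exon positions,
`enrichment_test(x, n, p)` returns $P(X \ge x)$, $X \sim B(n, p)$. With the
reference counts $x = 92$, $n = 129$, $p = 37540/73418700$ the tail is
around $10^{-270}$, far below the $10^{-15}$ reporting threshold; a
`log10` form is provided for values that underflow doubles.

## The toy-fixture generator

No external aligner runs in the test suite; instead `make_toy_reference()`
builds the two structures that attract mismapping — multi-exon genes
(junction reads) and paralogous gene pairs (a second locus overwritten with
a copy of the first, mutated at a configurable per-base divergence) — and
`make_sam_fixture()` writes reads aligned exactly at their encoded truth
(splice gaps as `N` CIGAR operations, minus-strand reads
reverse-complemented with the reverse flag), then applies engineered
perturbations: drop (unmapped), duplicate (multimapped), relocate or shift
(mismapped). The fixture SAM is deliberately unsorted so downstream stages
cannot assume order. Everything is a pure function of the fixture seed, and
the generator restores the caller's RNG state.

The defaults (two chromosomes of 10 kb, four genes of three 80 bp exons
with 150 bp introns, one paralog pair at 5% divergence, ten exonic SNPs)
are chosen so that junction reads exist for every gene, paralog pairs are
similar enough to be confusable yet carry divergent bases that become SNDs,
and every stage has non-trivial input in well under a second.

What the fixtures do *not* emulate: real aligner decision making, indels,
quality-score structure, coverage heterogeneity, or genome-scale repeat
content. Passing tests therefore demonstrate that the bookkeeping —
projection, truth encoding, classification, pileup, thresholds, filtering —
is exact, and that the causal chain (mismapped junction reads at a paralog
→ piled-up non-reference allele → false variant → blacklisted and
filtered) behaves as designed in miniature. They do not certify any
particular aligner's error profile; that is exactly why the blacklist must
be regenerated per aligner and read length.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; SAM, VCF and
  the blacklist TSV convert at the boundary. Mixed conventions inside the
  arithmetic are the classic source of off-by-one errors here.
* BED12 is the canonical transcript input; single-block BED records load
  as WES targets through the same type.
* `N` bases are simulated verbatim and never excluded — how an aligner
  treats them is the aligner's concern. `N` never becomes an SND alternate
  allele.
* Reads are generated per transcript; identical sequences arising from
  overlapping transcripts are distinct reads, matching the per-transcript
  construction.
* Determinism: the SE/PE generators are pure functions of their inputs;
  error injection and the fixture generator are pure functions of an
  explicit seed and restore the caller's RNG state.
* Degenerate inputs: empty FASTA, duplicate chromosome names, inconsistent
  BED block arithmetic, ref-mismatched SNP rows, CIGAR/sequence length
  disagreements and malformed blacklist rows all fail loudly (or are
  rejected with counts) rather than propagating.

## Problem sizes used in the checks

The package's own verification uses toy references of 2 × 10 kb with 6–8
multi-exon genes (thousands of exhaustive reads per run), an
error-injection calibration of one million 75 bp reads at rate $10^{-4}$
(the measured fraction of error-carrying reads is compared with the
analytic $1 - (1 - 10^{-4})^{75} \approx 0.75\%$ within four Monte-Carlo
standard deviations), and a miniature end-to-end study in which the reads
of one paralog are planted onto its diverged copy and the resulting
blacklist is verified base-for-base against the engineered divergence.
These sizes make every stage's expected outcome exactly enumerable; the
full-scale analysis (a real genome, tens of millions of reads, external
aligners, database downloads) uses the same code paths through the
command-line front-end.

## Known limitations

* The audit's positional check is leftmost-based; an alignment with the
  correct leftmost base but a wrong block structure counts as correct. A
  strict block-overlap mode would be stricter than the published tolerance
  and is not the default.
* Indels are out of scope throughout: the simulator injects substitutions
  only, and indel rows in variant inputs are skipped with counts.
* The blacklist stores one alternate allele per position.
* PE truth names carry both mates' origins in one shared stem; tools that
  rewrite read names will break truth decoding (as they would any
  truth-encoding scheme).
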