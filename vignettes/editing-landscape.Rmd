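---
title: "Models and design choices in editscape"
author: "editscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in editscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what is being
modeled, which rules are applied where, why the open design choices were
made the way they were, and what the synthetic-data tests do and do not
demonstrate about real data.

## The signal and its confounders

A-to-I editing by ADAR enzymes converts adenosine to inosine in
double-stranded RNA; reverse transcription and sequencing read inosine as
guanosine. Against a reference genome, editing therefore looks like an
A→G mismatch in reads from plus-strand transcripts and a T→C mismatch
(forward-reference representation) from minus-strand transcripts. The
dominant substrate is the inverted Alu repeat pair, so genuine sites
cluster in Alu elements of introns and 3'UTRs and favor U as the 5' and G
as the 3' neighbor of the edited adenosine.

Everything else that produces an RNA/genome mismatch is a confounder:
germline and somatic DNA variants, sequencing errors (quality-dependent),
misalignment near read ends, and strand-specific library artifacts. The
detection model is therefore not a probabilistic caller but a cascade of
exclusions, each tied to one confounder, followed by an optional learned
score.

## Detection cascade

A `PileupTally` records, per covered position, raw and quality-filtered
base counts plus every mismatching observation with its base quality,
mapping quality, distance to the nearer **raw** read end (soft clips
count toward the ends) and read strand. The cascade then requires, per
candidate (position, alternate base):

1. **Support** — at least `minAltReads = 2` alternate observations with
   base quality ≥ 20 and mapping quality ≥ 30, and filtered coverage ≥
   `minCoverage = 10`. The quality cutoffs deliberately reuse the
   package-wide read filters so site-level and gene-level numbers are
   computed from the same read population.
2. **Matched DNA** — the position must be absent from the sample's DNA
   variant table. This is the only filter with zero tolerance: a VCF
   position can never be called as editing. When no table is supplied the
   filter is skipped with a warning (and `requireDna = TRUE` turns that
   into an error).
3. **Read-end distance** — at least one alternate observation ≥ 5 bp from
   the raw read ends; mismatches confined to read termini are classic
   misalignment artifacts.
4. **Strand bias** — a two-sided Fisher's exact test on the 2×2 table of
   (reference reads, alternate reads) × (forward, reverse), rejected when
   p < `biasAlpha = 0.01`. An earlier formulation — binomial test of the
   alternate-strand count against the reference-read strand proportion —
   treats that proportion as known; at high editing frequency there are
   few reference reads, the proportion estimate is noise, and ~5% of
   genuine sites get rejected. The Fisher form makes the identical
   comparison exact and keeps power against true one-strand artifacts.
   Because this is a per-site *filter*, not an inference, no multiplicity
   correction is applied.
5. **Simple repeats** — membership is always recorded as a feature;
   exclusion is optional (`excludeSimpleRepeats`), off by default.

Gene assignment uses all overlapping genes but designates the
longest-span gene as canonical; positions inside genes on both strands
have ambiguous A-to-I polarity and are excluded from A-to-I summaries
(status `NA`).

### The confidence score

A logistic regression over 12 features (support, coverage, frequency,
mean base/mapping quality, minimum end distance, strand-bias p, simple
repeat, Alu, A-to-I flag, 5'-U and 3'-G context) is retrainable on any
labeled candidate set; in this package the labels come from the
simulator's truth tables. The published 28-feature model this mechanism
mirrors is not reproduced — its weights are not public — so the
classifier is a documented, re-trainable stand-in with the same role:
an associated confidence in [0,1] and a threshold (default 0.9).

Training needs negative examples. The default cascade removes nearly all
error-derived candidates (that is its job), so training candidates are
generated with a relaxed cascade (`minAltReads = 1`, no strand-bias
gate); the default-cascade output is what gets scored. Features are
standardized before fitting; the held-out AUC comes from a stratified
50/50 split.

## Editing indices

**AEI.** Sum of quality-filtered G-mismatch observations at
transcribed-strand adenosines inside Alu intervals, divided by the total
filtered coverage of those adenosines. The denominator includes
adenosines with no mismatch at all — the index is activity-weighted, not
a mean of per-site frequencies. Adenosines are taken on the strand of the
Alu BED record; unstranded records fall back to forward A→G plus reverse
T→C, summed. A read-truncation flag (`cutReadLength`, default off)
supports the practice of cutting reads to 100 bp before AEI computation
to remove read-length bias; whether truncation should precede the other
analyses is left to the user, hence a flag rather than a global setting.

**Region index.** Same ratio restricted to one interval; the shipped
`MAVS_3UTR` preset is an hg19 interval (chr20:3848102-3855844) and is
only meaningful against hg19-aligned input — assemblies are treated as
opaque user inputs, and mixing them is the user's responsibility.

**Gene-level editing.** The fraction of reads covering at least one of a
gene's cataloged sites that carry the edited base at one or more of them,
with read filters base quality > 20 (strict), mapping quality > 30
(strict) and site ≥ 7 bp from the raw read ends (2 bp from the
5-bp-trimmed read). A read editing two sites counts once; the definition
is read-level, not site-level. The site list fed in must already obey the
cohort rules (A-to-G, ≥ 2 samples, non-intergenic) — that restriction
lives in the catalog stage, not here.

## Cohort stage

**Recurrence catalog.** A site is tumor-enriched when it is A-to-I,
genic, detected in strictly more than `minFraction = 0.10` of tumor
samples, detected in zero controls, and seen in at least two samples.
The recurrence denominator is the full tumor cohort: samples without
coverage still count, matching the per-cohort phrasing of the rule. A
covered-samples denominator is available (`coveredMatrix`) for users who
prefer conditioning on assayability.

**Landscapes and exclusivity.** Gene × sample edited status (≥ 1 retained
site with frequency > 0) and mutated status (≥ 1 genic SNV in the
sample's VCF — indels and structural variants are out of scope) are
compared per gene with a two-sided Fisher's exact test; odds ratio < 1
indicates mutual exclusivity. Degenerate margins (all-true/all-false
rows) are flagged and returned with p = 1 rather than tested.

**Differential editing.** Pooled mode gates on ≥ 10 filtered reads per
pool and ≥ 1 edited read in either pool; replicate mode gates on ≥ 50
reads in *every* replicate of both groups and wild-type pooled frequency
≥ 0.2. Gated positions get a two-sided Fisher's exact test on
(edited, unedited) counts and Benjamini–Hochberg adjustment (the only
multiplicity procedure used in the package, applied within each analysis
family). Under the null the discrete Fisher p-values are super-uniform,
so the realized false-positive fraction sits well below the nominal FDR —
the calibration tests assert the bound, not equality.

**Hyper-editing clusters.** Single-linkage merging of consecutive sites
with inter-site gap ≤ 50 bp. The default gap is the smallest round value
that reproduces the six-run cluster structure of a MAVS-like synthetic
3'UTR fixture (runs of sites spaced ≤ 40 bp inside an ~7.7 kb region,
separated by several hundred unedited bases); it is exposed as `maxGap`.

## Expression signatures

Scores are the mean across signature genes of per-gene z-scores of
log2(TPM+1) across samples — a deliberately simple, versioned
construction chosen because the original score definitions are delegated
to external publications and are not restated here; the formula is fixed
so results are comparable across runs, and zero-variance genes are
dropped with their count reported. Consequences worth knowing: scores
average zero across the cohort by construction, and they are relative to
the analyzed cohort, not absolute. The shipped GMT
(`signatures_synthetic.gmt`) contains *synthetic placeholder* gene ids
matching the simulator's gene naming, for testing only; real ISG/NF-κB/
exhaustion lists are user-supplied.

High/low splits assign the top half of samples to "high"; with an odd
count the median sample goes to "low", and boundary ties break by input
order. Group comparisons use the Mann-Whitney U test (exact for small
tie-free samples, normal approximation with tie correction otherwise,
following the `stats::wilcox.test` switch below 50 per group);
correlations are Pearson with two-sided p.

## The simulator: what it emulates, and what it does not

`simulateCohort()` generates: a uniform-random genome with genes tiled in
fixed-size units (2–4 exons, terminal-exon 3'UTRs, ~25% of the gene);
Alu elements as 300 bp slots covering `aluDensity` of each gene on the
gene's strand; editing sites sampled from transcribed-strand adenosines
with 90% in Alu, 90% A-to-I (the rest C-to-U), and 5'/3' neighbors
weighted U = 0.5 / G = 0.5 against 0.15–0.2 for the alternatives —
matching the observed Alu enrichment and neighbor preference of ADAR
targets. Per-site baseline frequencies are Beta(2,3); per-sample activity
multipliers are Gamma with CV 0.3 around means of 1.2 (tumor) and 0.4
(control). The 3× tumor/control ratio is an assumption — no quantitative
ratio is published for the motivating cohorts — chosen so controls retain
clearly nonzero editing, as control B cells do; it and the 50% shared-site
fraction (which gives recurrence filters true positives and true
negatives) are configurable. Reads are fixed-length, ungapped, drawn
uniformly over gene spans in proportion to TPM × length; germline
variants hit 100% of overlapping reads, somatic variants a configured
fraction (default 0.4); sequencing errors are phred-faithful draws on a
two-point quality mixture (phred 40/13) whose low-quality fraction is set
from the requested mean error rate, so quality filters have something
real to remove. DNA variants are never planted on editing-site positions:
collision would make the zero-leakage property untestable rather than
false.

Not emulated: splice-junction reads and isoforms, fragment-length
structure, indels, batch effects, mappability variation, and
hyper-edited reads so dense they fail alignment — the last is a known
cause of underestimating editing in real RNA-seq, so recall measured
here is recall *given alignment*. Passing tests on this simulator
demonstrate correctness of the rules and estimators, not performance on
real libraries.

## Numerical and degenerate-input conventions

- Internal coordinates are 1-based inclusive everywhere; BED's 0-based
  half-open convention is converted at the boundary, and malformed BED
  records (start ≥ end on disk) are rejected with a warning.
- N reference or read bases never count as mismatches; contig-edge motif
  neighbors are recorded as N and excluded from frequency tables.
- Zero denominators return NA with a reason (AEI without adenosine
  coverage, genes with no covering read) rather than 0.
- Empty gate results from differential editing carry the per-gate
  attrition so silent data loss is visible.
- The pipeline manifest contains no timestamps; two runs from one seed
  are byte-identical, which is what the determinism tests assert.

## Problem sizes used in the tests

The test suite exercises cohorts of 10 tumor + 4 control samples on a
2 × 50 kb genome with 1,000 planted sites (the leakage property), five
single-sample replicates on 30 kb genomes with 400 sites each (recall and
precision), uniform-editing genomes with ≥ 10⁵ adenosine observations
(AEI recovery at g = 0.01/0.05/0.10 within ±0.01), and 10-seed
differential-editing panels of ~80 null positions at 100× with one
planted 0.20-vs-0.02 site at 200×. These sizes were chosen as the
smallest at which the binomial/multinomial sampling error is comfortably
inside the asserted tolerances.

## Known limitations

- The classifier is only as good as its labels; on real data a user must
  supply a trusted positive/negative set (e.g. known-site overlaps) or
  rely on the rule cascade alone.
- Gene-level editing and the catalog treat multi-mapped gene overlaps by
  canonical-gene assignment; allele-specific or isoform-specific editing
  is out of scope.
- The AEI here is the aggregate index; no per-element decomposition or
  confidence interval is computed beyond the raw numerator/denominator.
- C-to-U (APOBEC) events are recorded in the mismatch spectrum but not
  called or scored as editing.
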