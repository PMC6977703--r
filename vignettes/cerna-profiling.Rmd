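---
title: "Ordered-condition expression profiling and ceRNA inference: methods"
author: "ceRNAprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered-condition expression profiling and ceRNA inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAprofiler)
```

# The problem and the data model

The package analyses bulk expression over an *ordered* condition axis. The
motivating design is the four-group rat model of Parkinson's disease (PD)
and levodopa-induced dyskinesia (LID): sham-operated controls, 6-OHDA-
lesioned PD animals, and lesioned animals after chronic L-DOPA with (LID)
or without (NLID) dyskinesia. The ordering Sham → PD → NLID → LID encodes
disease progression, and the biological question is which genes — in
particular which long noncoding RNAs — move monotonically along it.

Expression lives in a `ConditionExperiment`, a `SummarizedExperiment`
whose columns carry a condition label and whose metadata fixes the
condition order. Values are non-negative (FPKM by default; raw counts can
be flagged). Transcript structure lives in a `TranscriptSet` (GRanges
anchors, GRangesList exons, optional spliced sequences), 1-based inclusive
throughout; any interval exported in a BED-like 0-based half-open dialect
is converted at the boundary.

# Model-profile clustering

## Candidate shapes

Over `T` ordered conditions, candidate profiles are integer vectors
starting at 0 whose successive differences lie in `[-c, +c]`. Excluding
the flat profile, there are `(2c+1)^(T-1) - 1` shapes. We fix `c = 1` as
the default unit step: it is the unique value giving the classical
26-profile set for four conditions, and a single condition-to-condition
transition of more than one doubling unit is better captured by the
log2-ratio magnitude than by the shape library. The flat profile is
excluded from the candidate set — a flat gene is not a dynamic pattern,
and keeping it would absorb low-variance genes that the zero-variance
guard already reports explicitly. Profile ids (`P01`, `P02`, ...) follow
the lexicographic order of the shape vectors and are stable across runs.

```{r}
profiles <- enumerateProfiles(nConditions = 4, maxStep = 1,
                              excludeFlat = TRUE)
profiles
matchProfile(profiles, c(0, -1, -1, -2))
```

## Series transform and assignment

Replicates are collapsed to condition means before any transform — the
shape library describes one trajectory per gene over group labels, not
per-replicate variation. Each gene's series is
`x_t = log2((mean_t + eps) / (mean_1 + eps))` with pseudocount
`eps = 1` (FPKM units) by default, so the first element is exactly 0 and
zero expression stays finite. Assignment maximises Pearson correlation
between the series and each shape; ties break to the smallest profile id
(deterministic, and exact ties are measure-zero on continuous data).
Pearson similarity makes assignment invariant to positive affine scaling
of a series, so the method clusters *shape*, not amplitude. Genes with a
zero-variance series are returned unassigned with reason
`zero_variance`; `minSimilarity` (default 0) can additionally withhold
weak matches (`below_threshold`).

## Permutation significance

The null asks: how many genes would land on each profile if the condition
order carried no information? Every gene's series is permuted over
conditions, re-referenced so the permuted first element is 0, and
re-assigned. For `T = 4` the exhaustive null uses all `4! = 24`
permutations. The identity permutation is included in the null average by
default: this is conservative (it pulls the expected count toward the
observed one) and keeps the null an average over the full symmetric
group; `includeIdentity = FALSE` is available. The per-profile p-value is
the upper binomial tail `P(X >= observed)` with `X ~ Bin(n, expected/n)`
over the `n` profiled genes. A sampled null (`permutations = <draws>`,
minimum 10) exists for larger `T` where `T!` is impractical.

# Differential-expression screen

Fold change is computed from condition means with pseudocount 1 on the
FPKM scale — standard practice to stabilise ratios near zero. The default
thresholds are fold change ≥ 2 (as `|log2FC| >= 1`, two-sided; one-sided
`up`/`down` modes exist because the direction convention for
down-regulation is a user decision) and BH-adjusted `q <= 0.05`. The
p-value source is pluggable:

* `moderated` (default): limma's moderated t on `log2(x + 1)`. At two or
  three replicates per group, per-gene variance estimates are extremely
  noisy; empirical-Bayes moderation is the standard remedy and is what a
  practitioner would use where a negative-binomial count model is not
  being fit.
* `welch_t`: a plain Welch t on `log2(x + 1)`, kept as a dependency-free
  reference. With constant groups it degenerates to p = 1 (equal means)
  or p = 0 (separated means).
* a supplied named vector, for p-values computed by an external count
  model (e.g. a negative-binomial exact test); the thresholding logic is
  identical in all three modes.

Term enrichment is a one-sided over-representation hypergeometric tail on
a user-supplied term–gene table (the sidedness is our choice; raw
p-values with an `alpha = 0.05` flag, no cross-term correction, since the
selection convention for pathway reporting is raw `P < 0.05`).

# lncRNA candidate filter

Six rules, each reported separately: spliced length ≥ 200 nt, exon count
≥ 2, longest ORF ≤ 300 nt, CPC score < 0, CNCI score < 0, no significant
Pfam similarity. All thresholds are inclusive as printed. The ORF scanner
is built in: three sense-strand frames, ORF = ATG…stop inclusive of the
stop codon, `N` never matches a codon, and the reported length is the
maximum (0 if none). Sense-strand-only is deliberate — transcripts are
stranded spliced sequences and an antisense ORF belongs to a different
transcript — with `sixFrame = TRUE` available. CPC/CNCI/Pfam scoring
engines are consumed as inputs (a TSV of externally computed scores), not
re-implemented. Merging with a known catalogue de-duplicates by id with
known annotation taking precedence (warning on collision).

# ceRNA network inference

Three steps. (1) Pearson correlation of every lncRNA × mRNA pair across
*all* samples of all groups — the "overall correlation distribution" is
read as this full pool. (2) Retain pairs at or above the nearest-rank
99th percentile of the pool: the threshold is the
`ceiling(p/100 * n)`-th order statistic, chosen over interpolating
quantile definitions because it is deterministic, interpolation-free and
always an observed value. Signed `r` (not `|r|`) is used, matching the
printed `>= 0.99` convention for the co-expression network. (3) Expand
retained pairs over the miRNA set and keep triplets in which *both*
members carry ≥ 1 perfect 6mer seed site of the shared miRNA — an exact
reverse complement of miRNA positions 2–7 (the TargetScan 6mer
convention; start and length are configurable since seed nomenclature
varies). G:U wobble does not count as a match under the "perfect"
wording; wobble-aware matching is available in the trans-target scorer.
Zero-variance genes are dropped from the pool with a warning. Output
ordering is canonical, so results are invariant to input ordering.

The miRNA set is a required input: the package takes mature miRNA
sequences as FASTA and makes no claim about their provenance, since no
miRNA assay is part of the supported experimental design.

# Target prediction

*Cis*: a gene is a target when it lies on the same chromosome with a
span-to-span gap ≤ 10 kb (default window), symmetric up/downstream and
strand-agnostic. The gap convention is fixed once:
`later.start − earlier.end − 1` on 1-based inclusive spans, 0 on overlap;
the window is measured from transcript-span ends (not TSS). *Trans*: a
two-stage screen-then-score design — candidates sharing an exact
reverse-complement 12-mer with the lncRNA survive stage 1; stage 2 scores
the best ungapped antisense alignment by counting paired positions. The
match-count score is a deliberately simplified surrogate for thermodynamic
duplex energy: it preserves the screen-then-score architecture and its
stage-1 filter never removes a candidate whose best perfect duplex is at
least the screen k-mer length, but it does not model stacking energies,
loops or gapped duplexes.

# qPCR quantification

Technical replicates are averaged on the Ct scale (arithmetic mean, the
standard convention). `dCt = Ct(target) − Ct(reference)` per sample;
`ddCt` subtracts the arithmetic-mean `dCt` of the calibrator condition
(Sham by default — the untreated reference is the natural calibrator);
`rq = 2^−ddCt`. By construction the calibrator condition has geometric
mean rq of 1, and rq is invariant to adding a constant to every Ct of
both genes. No amplification-efficiency correction is applied. Pearson
correlation against behavioral scores uses the standard two-sided
t-distribution p-value and refuses degenerate (zero-variance) input.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with recorded ground truth:

* **Expression**: planted genes take replicate values
  `base * 2^(shape_t + e)`, `e ~ N(0, noiseSd)` i.i.d. per replicate.
  Noise is lognormal (normal on the log2 scale) so planted shapes are
  unbiased after the log2-ratio transform. Background genes are flat with
  the same noise and lognormally spread baselines.
* **Sequences**: planted triplets get the exact seed site inserted at a
  recorded offset in both members; every sequence is screened by
  rejection sampling (bounded at 1000 retries, then an error) to be free
  of all non-planted seed sites, so negatives are clean by construction.
* **Annotation**: cis pairs placed at controlled gaps inside/beyond the
  window, with pair blocks separated by five windows so no accidental
  cross-pair hits exist.
* **Novel transcripts**: candidates passing all six filter rules plus
  rejects violating exactly one rule each, cycling through the rules.

The demo instance (`demoConfig`) fixes the study scale used throughout
the test suite: 4 conditions × 3 replicates; 50 genes planted on
`(0, −1, −1, −2)` at base 10 FPKM with log2 noise sd 0.2 among 1000 flat
genes; 5 planted triplets among 25 lncRNAs × 25 mRNAs (planted pairs
exactly proportional, i.e. noise-free correlation); 5 cis pairs inside
and 5 beyond the window. Three replicates is a realistic floor for bulk
RNA-seq group sizes; the 25×25 pair pool makes the top-1% correlation
tail large enough (ceiling(625/100) ≈ 7 pairs) to hold all planted pairs.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: count-based mean–variance relationships (noise
is homoscedastic on the log scale), correlated replicates or batch
effects, realistic genome geometry and transcript structure beyond
two-exon toys, partially complementary miRNA sites, or miRNA expression.
Recovery results on synthetic data certify the algorithmic chain, not
biological sensitivity.

# Numerical and engineering choices

* All generators and the pipeline are pure functions of (configuration,
  seed); two runs with the same config are byte-identical, which the test
  suite checks at the md5 level.
* Stage order default is screen-then-profile (mirrors the narrative in
  which dynamic profiling is applied to differentially expressed genes);
  `profileOn = "all"` profiles every gene instead, and an empty screen
  result falls back to the full gene set rather than aborting.
* Expression TSVs are written with 17 significant digits so write→read is
  bit-exact; network files are sorted lexicographically before writing.
* Degenerate inputs are handled explicitly rather than silently: negative
  expression values, duplicate gene ids, exons outside spans,
  sequence/spliced-length mismatches, ambiguous seed bases, zero-variance
  correlation inputs and missing reference Ct measurements all raise
  errors naming the offending record.
* Oracle tests pit every operation against an independent brute-force
  implementation (explicit loops and closed-form tails) across ≥ 20
  random seeds; the brute-force code shares nothing with the package
  implementations.

# Known limitations

The screen's built-in p-value sources assume roughly log-normal
expression; count-model inference should be supplied externally. The
permutation null permutes condition labels per gene independently and so
ignores gene–gene correlation; its binomial tail is a convenient
approximation rather than an exact exchangeability test. The trans-target
score is not an energy model. Cis targeting ignores strand and promoter
architecture. The profile library is exhaustive only for small `T` and
`c`; for long series a sampled null is required. None of the methods
model within-condition covariates (sex, batch, litter).
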