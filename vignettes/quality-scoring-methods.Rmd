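---
title: "Methods: quality feature sets, model tuning, and evaluation protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality feature sets, model tuning, and evaluation protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngsqc)
```

# Overview

`ngsqc` scores the quality of NGS data files in two stages. First, four
feature sets are extracted per file: RAW (eleven Pass/Warning/Fail
report flags from read-level statistics), MAP (aligner mapping-rate
percentages), LOC (fractions of sampled mapped reads over nine genomic
region categories) and TSS (binned read density around transcription
start sites). Second, classifiers are tuned over these features to emit
`P_low`, the probability that the file is of low quality, where the
training labels encode a released (high-quality) versus revoked
(low-quality) curation decision. This vignette documents the modelling
choices, defaults and their rationale, what the synthetic-data
generators do and do not emulate, and the package's numerical
conventions.

# RAW: the eleven report flags

The RAW set consists of the Pass/Warning/Fail summary flags of the
standard read-level QC report, excluding its "Basic Statistics" header
module. Report tool versions differ on the exact module list (some drop
the k-mer module); the set frozen here (`RAW_MODULES`) includes both
"Per tile sequence quality" and "Kmer Content", which is an assumption
this package documents rather than hides. Flags are computed from
`summarize_reads()` statistics with the reference tool's documented
default thresholds, e.g. per-base quality fails when any position's
lower quartile drops below 5 or any median below 20, overrepresentation
warns when any sequence exceeds 0.1% of reads and fails above 1%, and
duplication warns above 20% non-unique reads and fails above 50%
(estimated, as in the reference procedure, from the first 100,000
distinct sequences truncated to 50 bp).

Two conventions worth spelling out:

* **Inclusive adapter limits.** Rate-style thresholds are documented by
  the reference tool with strict inequalities and we follow that,
  except for adapter content where the limit itself counts as flagged
  (cumulative adapter fraction ≥ 5% warns, ≥ 10% fails). A file whose
  contaminated-read fraction sits exactly at the limit is therefore
  flagged, which keeps the flag an exact function of the contamination
  fraction.
* **Absent evidence passes.** The per-tile module returns Pass when
  read identifiers carry no tile field: the absence of evidence must
  not penalize quality.
* **K-mer positional bias** is tested per k-mer with a binomial
  upper-tail test on the most loaded position bin, Bonferroni-adjusted
  across bins and tested k-mers (warn p < 0.01, fail p < 1e-5). The
  Bonferroni guard is a package choice: without it, pristine random
  reads of realistic depth would false-flag by multiple testing.
* The per-read GC histogram is compared against a normal distribution
  fitted to the data's own mean and sd, so a uniform compositional
  shift does not trigger the GC flag; skewed or bimodal distributions
  do.

For paired-end samples RAW features are computed per mate file and one
mate's flags are dropped before modelling; the drop is deterministic
(mate 1 kept) with an optional seed to randomize, because a
reproducible default beats an unseeded coin flip.

# MAP: mapping-rate features

MAP features come either from the short-read aligner's summary log
(`parse_alignment_log()`) or are recomputed from SAM/BAM records
(`compute_map_stats()`) with identical field semantics. Single-end
files carry four features (unmapped / uniquely mapped / multi-mapped /
overall rate). For paired-end files the eight features are frozen as
the aligner's own paired summary lines — concordant 0/1/multi,
discordant unique, residual mates 0/1/multi, overall rate — with the
log's own denominators (pairs, concordant-zero pairs, residual mates
respectively). A read is multi-mapped when its alignment-count tag
exceeds 1 or secondary alignments share its name.

# Gene models, LOC and TSS

`parse_gtf()` keeps one representative transcript per gene — the
longest — so "first exon" and "first intron" have a single consistent,
strand-aware definition. Intervals are handled as `GRanges`; all
coordinates are 1-based inclusive throughout, which is the GTF and
Bioconductor convention (the package does not introduce a second,
0-based internal convention: one convention, documented everywhere,
beats two with translations at the boundary).

The region index assigns every genomic position exactly one of nine
categories with the fixed priority promoter > 5'UTR > 3'UTR > first
exon > other exon > first intron > other intron > downstream > distal
intergenic. UTRs outrank exon categories so an exonic position inside
an annotated UTR is reported as UTR. Window sizes default to
`promoter_halfwidth = 3000` bp and `downstream_length = 3000` bp —
the defaults of the annotation tooling this feature set mirrors — and
are configurable and recorded in the index.

LOC features are the fractions of sampled read anchors per category;
the distal-intergenic catch-all guarantees they sum to exactly 1. TSS
features count (anchor, TSS) pairs in ten 1 kb bins tiling TSS ± 5 kb,
oriented by transcription direction (bin `TSS-4500` covers offsets
[-5000, -4000)); an anchor near several TSSs contributes once per TSS.
Bins are divided by the total number of sampled anchors rather than
left as raw counts: raw counts would scale with the number of available
reads whenever a file has fewer than the one-million sampling target,
making files incomparable. The anchor is the midpoint of the aligned
interval (configurable to the 5' end); midpoints are symmetric and
robust to read length. For proper pairs the fragment spanned by both
mates is anchored once.

# One-feature baseline

Each feature alone is scored by using its values directly as
probabilities of low quality. Because some features rise and some fall
with quality, the ROC is computed under both the default and the
inverted labels and the maximum area is reported
(`one_feature_auroc()`), so the baseline always lies in [0.5, 1]. The
underlying `auroc()` is the Mann–Whitney concordance with half credit
for ties — ties are unavoidable once categorical flags are encoded.
Flags enter this construction through the ordinal map Pass → 0,
Warning → 0.5, Fail → 1 ("probability of low quality"); the numeric
coding is an explicit package assumption since any strictly monotone
coding gives the same auROC.

# Model lab

Feature tables one-hot encode the RAW flags (11 × 3 columns, each group
summing to 1): chi-squared selection needs non-negative input, and
distance- and tree-based learners treat indicator columns sensibly.
Single- and paired-end MAP features live in a union schema; the absent
layout's columns are zero-filled and a binary `MAP_is_paired` indicator
marks the layout, so one generic model can train across layouts.

The tuning grid crosses feature-selection settings (none, chi-squared,
RFE, stability selection; k ∈ {25, 50, 75, 100}%) with ten classifier
families. Backends and their parameterizations:

* random forest: `ranger`, 500 or 1000 trees, `mtry = sqrt(p)`,
  unlimited depth. The canonical reference setting (1000 trees, sqrt
  features, default depth) is in the default grid. Split criterion is
  Gini impurity; Gini and entropy splitting yield practically
  indistinguishable forests, so the grid does not duplicate settings
  across criteria.
* gradient boosting: `xgboost` configured as classical gradient
  boosting (no L1/L2 penalty, full subsampling). The regularized
  extreme-gradient-boosting variant is registered as a separate family
  but excluded from the shipped default grid, mirroring the released
  form of this methodology.
* AdaBoost: in-package discrete SAMME over depth-limited `rpart`
  learners (no maintained AdaBoost package fits the registry's fit /
  predict-probability contract); probabilities via a logistic link on
  the normalized margin.
* multilayer perceptron: `nnet`, one hidden layer (size and decay in
  the grid). Deeper architectures are out of scope by design.
* logistic regression: ridge-penalized (`glmnet`, small fixed lambda),
  which matches the common default of L2-regularized logistic
  regression and is robust to the collinearity of one-hot blocks. The
  same ridge model ranks features inside RFE.
* naive Bayes (Gaussian, `e1071`), k-NN (`class`, odd k only so votes
  cannot tie), SVM (`e1071`, probability outputs), decision tree
  (`rpart`, Gini or information splitting).

Cross-validation is stratified 10-fold (every fold's class ratio within
one sample of the global ratio); feature selection is fitted on the
training folds only — the leakage test in the suite verifies that 1000
pure-noise columns cannot lift the cross-validated auROC of a null
table above 0.65. Models are ranked by mean CV auROC with ties broken
by lower Brier loss, then fewer retained features, then the
lexicographic spec label, making the ranking fully deterministic.
Stability selection runs 100 stratified half-subsamples of the
chi-squared ranking and retains the most frequently selected columns
(ties by mean score); all of its parameters live in the grid
configuration file (`inst/extdata/*.json`).

Scaling-sensitive families (logistic, MLP, k-NN, SVM) standardize
features inside `fit` using training statistics only. All stochastic
steps take an explicit seed and restore the caller's RNG state.

# Evaluation protocols

* **Within-experiment leave-out**: for every experiment that contains
  both low- and high-quality files, the model is retrained without that
  experiment and its members are scored; the per-experiment summary is
  the mean P_low difference between low- and high-quality files (the
  mean rather than the median, configurable; with typical group sizes
  of 4 the two nearly coincide). Training-set membership is recorded on
  the model so the no-peeking property is assertable.
* **Cross-group generalization**: outer stratified 5-fold per group;
  an inner 10-fold grid search picks the spec on each outer-training
  split; the model is evaluated on the held-out fold of its own group
  and the corresponding fold of the other group.
* **Quality-flag validation**: five metrics (median base quality,
  uniquely mapped %, PBC, FRiP, union DHS overlap) convert to bad flags
  when strictly below the recommended thresholds {25, 60, 80, 1, 70} —
  strict, exactly as the guidelines print them ("bad if < 25").
  Samples need at least 4 annotated metrics; the label rule is high
  quality iff more than 3 good flags. The validation statistic is the
  Pearson correlation between P_low and the bad-flag count.
* **Outlier screening**: expression matrices are log2(TPM + 1)
  transformed (pseudo-count 1, configurable, since "log2 transformed"
  alone is undefined at zero), standardized per gene, and projected on
  the first two principal components; group separation is the Dunn
  index (minimum between-cluster distance over maximum within-cluster
  diameter, with the degenerate zero-diameter case mapped to +Inf for
  distinct clusters). The two samples with highest P_low per group are
  removed, the projection and standardization are recomputed on the
  remaining samples, and the index difference is reported.

# The synthetic-data generators

The generators produce every input the pipeline consumes and define the
study conditions for the test suite:

* `make_genome()` packs genes (2–6 exons, UTRs, both strands) with at
  least 10 kb spacing on random chromosomes; output is byte-identical
  for a fixed seed.
* `simulate_fastq()` draws base qualities per position from a normal
  around `base_quality_mean − decay × position` (sd 2, clipped to
  [2, 40]); adapter contamination replaces the read suffix with a fixed
  12-mer in an exact `ceiling(rate × n_reads)` count of reads, so the
  contaminated fraction is a deterministic function of the knob rather
  than a binomial draw; duplication copies reads from a small template
  pool; `gc_bias` mixes in a GC-rich read population (bimodal
  contamination — a pure mean shift would not, and should not, trigger
  the GC flag); N calls are injected per base.
* `simulate_alignments()` draws mapping outcomes from exact counts of
  the profile fractions, places mapped reads by an
  exonic/promoter/uniform mixture, and writes a SAM file together with
  an aligner-style log computed from the same counts, so the log path
  and the record path agree by construction. Residual paired-end mates
  are never both unique — such a pair would be discordant by
  definition.
* `simulate_feature_table()` plants a standardized mean shift of
  `effect_size` on the informative numeric columns (baseline mean 50,
  sd 10, clipped at 0 so chi-squared selection applies; the clip is
  negligible at these parameters). The implied Bayes-optimal auROC,
  `pnorm(sqrt(n_informative) × effect_size / sqrt(2))`, is returned
  with the table and anchors the parameter-recovery tests. Labels
  alternate so consecutive experiment groups mix both classes.

What the generators do **not** emulate: realistic sequencing error
models (no indels or substitution calibration), instrument-specific
quality profiles, correlated features across sets, class imbalance, or
batch structure. Passing tests on these fixtures therefore demonstrate
the correctness of the statistics, the selection/tuning machinery, and
the protocols — not real-data performance of any particular trained
model, which depends entirely on the training corpus supplied by the
user.

# Problem sizes and numerical conventions

The test and acceptance runs use deliberately modest sizes chosen to
exercise every code path at stable statistical power: read counts of
1,000–10,000 (10,000 where a flag threshold must be resolved at 0.1%
precision), 2,000–10,000 alignments, genomes of 2 × 150–400 kb with
5–20 genes, and feature tables of 200–400 samples. The Bayes-recovery
experiment uses n = 400 with the reduced grid (ten specifications);
the top cross-validated auROC is required to land within
[A* − 0.07, A* + 0.03] of the closed-form optimum — asymmetric because
cross-validation estimates generalization and can only exceed the
Bayes bound by sampling noise. The label-permuted null over a reduced
grid must land in [0.35, 0.65]: wider than a single model's null
spread because the grid reports the maximum over specifications.

Other conventions: probabilities are clamped to [0, 1] after backend
prediction; undefined precision (no positive calls) is reported as NA
/ JSON null rather than 0; model ranking ties are broken
deterministically; every fingerprintable object (training matrices)
carries an MD5 fingerprint for provenance assertions; seeds derived
internally stay below 2^31.

# Known limitations

* The exact hyperparameter grids of the original large-scale study are
  not reproduced; the shipped default grid is a documented assumption
  (a JSON config users can replace) and is intentionally much smaller
  than an exhaustive search.
* The random-forest backend offers Gini but not entropy splitting; see
  above.
* The MLP family has a single hidden layer.
* Headline numbers from corpus-scale training (thousands of curated
  files) are out of reach of a synthetic-fixture package by
  construction; the acceptance script reports what the package itself
  computes under its stated study conditions.
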