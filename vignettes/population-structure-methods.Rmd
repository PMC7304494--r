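---
title: "Models and methods behind popstructr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popstructr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popstructr)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the test suite demonstrates. It states no
empirical number that the tests or the acceptance script do not themselves
compute.

## Data model

A `cohort` couples an integer genotype matrix (samples × variants, values
0/1/2 counting alt alleles, `NA` for missing) with a sample table (id,
population, subpopulation/birthplace, panel tag) and a variant table
(chrom, 1-based pos, id, single-nucleotide ref/alt). Coordinates follow
the VCF convention throughout. Missing genotypes are always an explicit
`NA`, never a sentinel value. Sex chromosomes are carried through I/O;
distance, PCA, admixture, FST and AMOVA default to autosomes only
(`autosomes_only = FALSE` restores the full set, mirroring merged array
datasets that retain a handful of sex-chromosome SNPs).

When two cohorts are merged, variants are intersected on (chrom, pos) and
alleles harmonized: exact (ref, alt) matches pass through, swapped pairs
are recoded `g → 2 − g`, and any other combination — including
strand-ambiguous A/T and C/G mismatches — is dropped with a logged count.
Guessing strand flips silently corrupts downstream frequencies, so we
never do it.

## The synthetic-cohort generator

The generator exists so that every stage has inputs with known truth.

* **Ancestral divergence** follows the Balding–Nichols model: a
  common-pool frequency *p* is drawn uniformly on `base_freq_range`
  (default 0.05–0.95), and each of K populations receives an independent
  Beta(p(1−F)/F, (1−p)(1−F)/F) draw. The expected per-population variance
  is F·p(1−p), so `fst_param` is the target FST of downstream recovery
  tests. Frequencies are clamped to [1e-6, 1−1e-6] to keep the admixture
  likelihood finite.
* **Cohorts**: genotypes are Binomial(2, Σₖ q·f) given each sample's
  ancestry vector q — exactly the likelihood the supervised EM maximizes.
  Three designs: discrete one-hot clusters, i.i.d. Dirichlet(α) admixture,
  and a linear gradient of q along the sample index between two vertex
  populations, emulating a continuous admixture continuum. Missingness is
  i.i.d. at a configurable rate.
* **Reference panels** for the Z-screen jitter each panel around the study
  consensus with Gaussian SD σ and shift named loci of the study column by
  δ, so an injected locus has expected Z ≈ δ/σ. By default the study
  column is the exact consensus, which makes the injected-Z arithmetic
  exact; `study_jitter_sd = jitter_sd` instead draws the study column from
  the same noise process, under which the null Z is standard normal up to
  the sample-SD correction — that switch is what the null-calibration test
  uses.

Every generator is a pure function of its parameters and one integer
seed. What the generator does **not** emulate: linkage disequilibrium
(loci are independent; LD-pruning tests instead use explicitly duplicated
or correlated columns), genotyping batch effects, allele-frequency
ascertainment bias of arrays, and relatedness. Tests passing on these
simulations therefore certify the estimators' contracts, not robustness
to array artifacts.

## QC filters

Defaults transcribe common array practice: missingness > 1%, minor allele
frequency < 1%, Hardy–Weinberg exact p < 0.001, LD pruning with windows of
1000 variants, step 10, r² > 0.4.

The HWE test is the conditional exact test: all heterozygote counts
compatible with the observed allele counts are enumerated, each weighted
by its probability under random mating, and the p-value is the summed
probability of configurations no more likely than the observed one
(plain tail; a `midp` flag halves the observed configuration's weight).
Probabilities are built by a ratio recurrence from the modal heterozygote
count, which is numerically stable at n in the thousands; the test suite
checks the implementation against a direct log-gamma enumeration oracle
for all totals ≤ 200. One behavior worth knowing: applied to a pooled,
structured cohort the test removes far more than the nominal rate because
the Wahlund effect depresses heterozygosity — that is the statistic
working as designed, not an error. Whether to filter within subcohorts or
the pooled cohort is the caller's choice; the filter operates on whatever
cohort it is handed.

LD pruning is variant-count-windowed (not kb-windowed), matching the
quoted parameter triple. Within a window, pairs are scanned greedily in
position order; the member of an offending pair with the lower MAF is
removed, ties broken by removing the later position. These tie-breaks are
stated because the classic tool leaves them undocumented and the tests
need determinism. Pairwise r² is the squared Pearson correlation of
dosage vectors over pairwise-complete samples; a constant vector is
treated as r² = 0 with a warning. Passes repeat until no window changes,
which guarantees the post-condition (no within-window kept pair above the
threshold) that the suite asserts directly.

## Distances, PCA, admixture

1−IBS uses the shared-allele fraction `(2 − |gₓ − g_y|)/2` per locus,
averaged over pairwise non-missing loci. Het–het pairs count as fully
shared — the natural convention on unphased biallelic dosages, stated
explicitly because allele-level IBS conventions differ. The matrix is
computed by indicator-matrix products, so cohorts of a few thousand
samples are fast; a pair with zero overlapping loci is an error naming
the pair, not a silent NA.

PCA standardizes each locus to `(g − 2p)/sqrt(2p(1−p))` with p estimated
from the cohort itself, imputes missing entries to 0 (the column mean),
and eigen-decomposes the sample covariance. Coordinates are eigenvectors
scaled by the square root of their eigenvalues; each component's sign is
fixed by making its largest-magnitude loading positive, so results are
reproducible across platforms. Monomorphic loci are a hard error
directing the user to QC rather than a silently dropped column.

Supervised admixture fixes the panel frequency matrix F (estimated from
labeled reference samples, clamped off 0/1) and maximizes each sample's
binomial likelihood over the ancestry simplex by EM. The problem is
per-sample independent and convex enough in practice that the uniform
start with a log-likelihood convergence test (`tol = 1e-6`, cap 1000
iterations, both configurable) is sufficient; the EM update is monotone,
which the tests assert on random instances against an independent replay.
Missing genotypes are dropped from the likelihood rather than imputed —
likelihood purity over convenience. Unsupervised estimation (learning F
and choosing K by cross-validation) is deliberately out of scope: the
analysis chain needs q given reference panels, which is the testable
subproblem.

## Trees

UPGMA is average-linkage agglomeration (`stats::hclust`), with merge
heights recorded as the linkage distances themselves — the convention of
the common plotting stacks — and verified against a naive O(n³)
re-implementation on random matrices. Neighbor joining is the classic
Saitou–Nei algorithm (`ape::nj`) with negative branch lengths clamped to
zero; on additive matrices the recovered tree reproduces the input
distances exactly, which is the defining guarantee the tests check.
Newick export goes through `ape`, which sanitizes label characters that
the format cannot carry; round-trip tests pin that behavior down.

## Stratification statistics

Heterogeneity, separation and compactness are defined in the README. Two
design decisions deserve a note:

* **Compactness is separation ÷ heterogeneity.** Published descriptions
  of this family of statistics sometimes invert the phrase; the ratio
  used here is the one under which "well-clustered" populations score
  above 1 and weakly stratified ones score near 1, and it is the
  orientation consistent with the reference tables this package's
  acceptance checks recompute.
* **Summary means are means of per-replicate ratios**, not ratios of mean
  numerator and denominator. For low-variance replicate distributions the
  two agree to several decimals; the distinction matters only at the
  ~1e-5 level but is stated so the output is well-defined.

Down-sampling uses `min(n_per_pop, population size)` members per
replicate without replacement; populations at or below the cap are used
in full, so their heterogeneity is constant across replicates (their
separation still varies through the counterparts' resampling). The
per-population compactness replicate vectors are compared to the focal
population's by a two-sided Welch t-test — Welch because replicate
variances differ across populations; the focal-vs-itself row is t = 0,
p = 1 by construction. When both replicate vectors are constant
(everything exhaustive), equal means give t = 0, p = 1 and unequal means
give ±Inf, 0 — degenerate but well-defined. The exclusion list (for an
unbiased focal separation, e.g. omitting a reference population known to
overlap the focal one) removes those populations from every counterpart
set and from the report; the report's parameters record it.

Problem sizes in the tests were chosen to make the statistical contracts
sharp at desk scale: compactness calibration uses 100–150 samples with
1500 loci, where the null band [0.98, 1.02] and the clustered threshold
1.2 hold with margin.

## FST, AMOVA, Slatkin

The Weir–Cockerham (1984) locus estimator is implemented from the
variance components a (among populations), b (among individuals within
populations) and c (within individuals), vectorized over loci; the suite
checks it against an independently transcribed copy of the formulas on
1000 random count configurations at 1e-12. Two summaries are reported:
the mean of per-locus θ over loci with a defined denominator (the "mean
FST" of the widely used command-line tool — the headline number), and
the ratio of sums Σa/Σ(a+b+c), which is the statistically preferred
weighting and the one that recovers the Balding–Nichols parameter in
simulation. Loci with zero denominator are excluded from the mean and
counted.

AMOVA partitions allele-level variance into among-population,
among-individual-within-population and within-individual strata. Per
locus, each non-missing diploid individual contributes two allele copies;
sums of squares and degrees of freedom accumulate over loci, and the
variance components solve the nested mean-square equations with
size-weighted coefficients (each individual contributes exactly two
copies, so the individual-level coefficient is 2; the population-level
coefficient is the usual (S₁ − S₂/S₁)/(r−1) accumulated df-weighted over
loci). Because df are summed over loci, a multi-locus table's df are
per-locus design df times the locus count — derived from the actual
data rather than copied from any fixed design. Negative components, which
moment estimators produce near zero structure, are truncated at zero for
percentage reporting while raw values are retained in the table. The
fixation index is the among-population share of the total; Slatkin's
linearized distance is FST/(1−FST).

## The allele-frequency divergence screen

Reference columns are joined to the study frequencies on the full
(chrom, pos, ref, alt) key — position alone is not identity. The score is
`Z = (p_study − mean(p_ref)) / sd(p_ref)` with the sample SD over the
reference columns; this "cross-panel spread" reading yields one Z per
locus, as the summary tables require, and needs at least three reference
columns. A per-population binomial-SE Z would be the alternative reading;
it is noted here and not implemented because it produces one score per
panel rather than per locus. Loci whose reference SD falls below
`sd_floor = 1e-6` (monomorphic reference panels) are flagged
uninformative and excluded rather than divided by ~0. The default
threshold |Z| > 4 corresponds to a two-sided normal p of 6.3×10⁻⁵; no
further multiple-testing correction is applied, deliberately. Flag
classes (low / null / high / uninformative) partition the loci;
cross-tabulation against effect-category annotations puts unannotated
loci in "Others", and chromosome densities are half-open bins
[start, start + bin).

The screen's VCF export is sites-only VCF 4.2 with `AF_STUDY`,
`AF_<panel>`, `ZSCORE` and `ZFLAG` INFO fields at 6 significant digits,
and a reader that round-trips it.

## Plots

Every plot function builds a plain-data "scene" first — pie-glyph polygon
vertices with exact arc fractions, ordered long-format bars, ordered
heatmap cells — and attaches it to the returned ggplot as an attribute.
Tests assert on the scene, never on pixels, so the suite is robust to
rendering-backend differences. Pie glyphs are drawn in data coordinates
with a constant radius (default 2% of the PC1 span); overlap is allowed,
no repulsion layout. Colors are assigned stably by sorted population name
unless overridden. The pipeline writes figures as PDF, the one vector
device available everywhere R runs.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → QC → frequencies → distances → trees →
PCA → admixture → diversity → FST → AMOVA → Z-screen → plots, writing
TSV/newick/VCF/PDF artifacts and a JSON manifest of parameters, seed and
MD5 hashes of the data artifacts (PDFs embed timestamps and are listed
but not hashed). The default toy study is 500 samples in 3 populations ×
2000 loci with the standard QC and diversity settings — sized so the
whole chain, including the 100×100 resampling, runs in a couple of
minutes on one CPU; identical seeds give identical manifests. The
subcommand surface of a shell tool is deliberately not provided: the
exported functions and this pipeline driver are the interface of an
analysis package.

## Known limitations

* No relatedness or sample-level QC (call rate per sample, heterozygosity
  outliers) — the analysis chain assumes unrelated, QC'd samples.
* The admixture module is supervised-only by design.
* AMOVA implements the three-level partition; additional grouping levels
  (groups of populations) are a noted extension, not included.
* IBS distances do not satisfy the triangle inequality in general, and no
  such property is asserted.
* The synthetic generator's independence of loci means LD-sensitive
  behavior (e.g. pruning on realistic haplotype structure) is exercised
  only through constructed correlated columns.
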