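---
title: "Methods: aging statistics for two-strain egg-chamber RNA-seq"
author: "ovage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging statistics for two-strain egg-chamber RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovage)
```

This vignette is the package's own account of its statistical model and the
design choices behind it: what each test assumes, which tunable parameters
matter, what the synthetic-data generator does and does not emulate, and the
numerical details that affect reproducibility.

## The design and the expression scale

The target design is bulk mRNA-seq of *Drosophila* stage-14 egg chambers
from two inbred strains, each sampled at a young and an old age, with 2–4
biological replicates per strain × age cell (unbalanced replicate counts are
expected; the default simulated design uses 4 + 4 and 3 + 3). Stage-14 egg
chambers — the oocyte plus its follicular sheath, the last stage before
ovulation — minimize cell-type heterogeneity, so expression changes can be
read as aging of a defined tissue rather than shifts in tissue composition.

Expression is summarized as RPKM (reads per kilobase of transcript per
million mapped reads):

$$\mathrm{RPKM}_{ij} = \frac{c_{ij}}{(L_i/10^3)\,(N_j/10^6)}$$

with $c_{ij}$ the read count of feature $i$ in sample $j$, $L_i$ the
annotated transcript length (not the genomic span; the GFF3 reader prefers a
`transcript_length` attribute and falls back to the span), and $N_j$ the
column total over *all* features in the matrix, TE families and
mitochondrial features included.

The aging signature of a feature in a strain is

$$r_{is} = \log_2 \frac{\overline{\mathrm{RPKM}}^{old}_{is} + \delta}
                      {\overline{\mathrm{RPKM}}^{young}_{is} + \delta}$$

where replicate means are taken on the RPKM scale *within* each strain × age
cell before the ratio (per-replicate ratios are not even defined when
replicate counts differ between ages), and the pseudo-RPKM offset $\delta$
(default 0.5, configurable) keeps the ratio finite at zero expression and
damps the variance of low-expression features. Direction is the sign of
$r_{is}$, with $|r_{is}| < 10^{-9}$ called "flat" purely as an exact-tie
guard. A linear fold `mean_old/mean_young` without the offset is reported
alongside, labelled as such, because published fold-difference tables are
conventionally offset-free; it is `NA` when the young mean is zero.

## Differential expression

Counts are modelled per feature as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$ and a log-linear mean,

$$\log \mu = \beta_0 + \beta_{strain} + \beta_{age}
  \,(+\, \beta_{strain \times age}) + \log s_j,$$

with median-of-ratios size factors $s_j$ as offsets. The age test is a Wald
test on $\beta_{age}$ in the reduced (no-interaction) model — age while
controlling for strain; the interaction test is a Wald test on the
interaction coefficient in the full model. Per-strain log2 age effects come
from the full model. p-values are BH-adjusted with NAs (non-convergent fits)
excluded from the number of tests. Features with zero counts in every sample
are dropped before testing.

Dispersions are estimated by the method of moments on normalized counts
within strain × age cells, pooled, then shrunk halfway (weight configurable)
toward a fitted mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ with
coefficients clamped non-negative, floored at $10^{-8}$. This is a
deliberately transparent stand-in for the shrinkage machinery of the
standard NB DE tools: no shrinkage priors on fold changes, no outlier
replacement, no independent filtering. The package does not attempt to
reproduce any specific tool's gene lists; its contract is calibration —
near-uniform null p-values, type-I error at the nominal level, and unbiased
recovery of injected effects — which the test suite checks by simulation.
Wald (rather than likelihood-ratio) tests were chosen because the design has
a single primary contrast and Wald standard errors come free from the fit.

One identifiability note: a log-fold change shared by *all* features is
absorbed by the size factors and is estimated as zero by construction.
Effects are only identified relative to the bulk of unchanged features, as
in any global-scaling normalization.

## The expression-matched permutation test

The package's centerpiece is the set-level test for a coordinated aging
shift, built to respect the strong dependence of ratio variance on
expression level.

1. Rank all features by overall mean expression — the mean of the four
   strain × age cell means, pooling ages so the age contrast cannot leak
   into the null. Focal-set members are excluded from the candidate pool so
   the null cannot be contaminated by the very signal under test.
2. Match every focal gene to its `k_up = 10` nearest-ranked non-focal genes
   above and `k_down = 10` below (the "20 most similarly expressed genes").
   At the extremes of the ranking the deficit is filled from the other side,
   so every focal gene keeps 20 matches.
3. The observed statistic is the per-strain mean of the focal genes' log2
   aging ratios — the mean log-ratio reading of "average fold increase"; the
   log scale symmetrizes up- and down-shifts. A linear-scale variant is not
   the default.
4. Each of `n_perm` (default 10,000) replicates draws, independently per
   focal gene, one uniform match; a control may serve several focal genes in
   one replicate. A replicate is an exceedance when its per-strain means
   reach the observed means in **both strains simultaneously**. A
   without-duplicates mode exists but is non-default; sampling with
   replacement is the simplest reading of "random samples of gene sets".
5. The reported p is the add-one estimator $(x+1)/(B+1)$, which is never
   exactly zero; the raw proportion $x/B$ is returned alongside, since
   published permutation p-values are often the raw proportion.

**A calibration caveat that users should understand.** The joint
both-strains exceedance rule is faithful to how such tests are described and
run, but the number it produces is not a uniformly distributed p-value when
the two strains' aging ratios are independent under the null. In that case
the per-strain exceedance proportions are two nearly independent uniforms
and the joint proportion behaves like their product, so
$P(p < 0.05) \approx 0.05(1 - \ln 0.05) \approx 0.20$. The package therefore
also provides `criterion = "min"`, which compares the scalar
minimum-over-strains mean against its own permutation distribution; this is
a valid, calibrated p (the test suite verifies calibration of the default
rule's components and the enumeration equivalence of both rules on small
instances). The joint rule remains the default because it is the published
procedure; treat its p as a descriptive exceedance proportion, or use
`"min"` when frequentist calibration matters. When the two strains'
ratios are strongly positively correlated — as they are for genuinely
shared aging responses — the two rules converge.

Exactness is guarded by a brute-force oracle: for instances small enough to
enumerate every assignment of matches, the Monte-Carlo estimate must sit
within three binomial standard errors of the exhaustive answer.

## Directional and positional tests

*Sign tests.* For a directional set (eggshell/chorion, mitochondrial, ETC),
flat members are excluded and the two-sided exact binomial p at $p_0 = 1/2$
is twice the smaller tail, capped at 1. The upper tail is computed via the
$p_0 = 1/2$ symmetry `pbinom(n-k, n, 1/2)` rather than `1 - pbinom(k-1, …)`;
the naive form loses about six significant digits to floating-point
cancellation once p drops below $10^{-10}$, which is exactly the regime
where strong chorion effects live.

*Yates chi-squared.* DE-by-compartment 2×2 tables use
$\chi^2 = \sum (\max(|O-E| - 0.5,\, 0))^2/E$ on one degree of freedom,
upper-tail p. The continuity correction is truncated at zero so a perfectly
proportional table scores exactly 0. Margins must be positive; a table with
no significant genes is refused rather than scored.

*Compartment membership.* A gene is "in" a chromatin domain if its body
overlaps any domain interval by at least one base, after converting BED's
0-based half-open intervals to the 1-based inclusive convention (so a domain
abutting a gene end-to-start does not count). An upstream promoter-window
mode exists but is off by default, since domain residence of the gene body
is the usual reading of "intersection". Intercalary versus pericentric
labels are taken from the domain file's name column, never inferred from
coordinates.

*Compartment shift.* The test for a genome-wide derepression of
heterochromatic genes is a Welch two-sample t-test of aging ratios,
in-compartment versus rest, per strain. Welch rather than pooled-variance
because the two groups differ in size by an order of magnitude and there is
no reason to assume equal variances.

*Top-decile enrichment.* Tested features are ranked by adjusted age p (ties
by raw p, then stable input order); the top $\lceil 0.10\,n \rceil$ are
crossed with set membership and tested by the same Yates machinery.

## TE family statistics

TE expression is quantified per family (an aggregate count per family, as
produced by mapping against a repeat-masked genome plus family consensus
library; producing those counts is upstream of this package). The global
derepression test is a paired t-test of per-family young versus old mean
expression within a strain, on the log2(RPKM + 0.5) scale — the log
stabilizes the heavy-tailed family expression distribution; a linear-scale
mode exists. The all-tied degenerate case is reported as t = 0, p = 1.
Family-level age and strain-by-age tests are literally the gene machinery on
relabelled rows — the test suite asserts bit-identical p-values — so there
is no TE-specific statistical code path to audit separately.

## Stage verification

Each sample's log2(RPKM + 0.5) over the eggshell marker panel is correlated
with each reference stage profile on the same scale; the sample is assigned
the argmax stage. Ties break toward the earlier stage with a warning, and a
winning correlation below 0.3 flags the call as low-confidence rather than
silently assigning a stage.

## The synthetic-data generator

`simulate_counts()` draws counts feature-wise from
$\mathrm{NB}(\mu = L_j\, q_i\, 2^{\eta_{is} + a_{is}\cdot \mathrm{old}},\,
\alpha)$:

* $q_i$: relative abundances, log-normal (`baseline_log_mean = 3`,
  `baseline_log_sd = 1.5` on the natural-log scale); mitochondrial features
  are scaled ×50 (they dominate real egg-chamber libraries) and TE families
  ×0.5.
* $L_j$: log-normal library sizes, mean 5 × 10⁶ reads, CV 0.2 — a
  replicate-pool variability typical of pooled-dissection designs. No
  published depth was available to copy, so these are free parameters chosen
  once.
* $\eta_{is}$: per-gene strain offsets, N(0, 0.2) in log2, so strains differ
  without any age signal.
* $a_{is}$: injected log2 age effects from the effect table. The defaults
  encode the study conditions: a 31-gene focal ("pirna") set at +0.4 in both
  strains; a 15-feature mitochondrial set at −0.8; a 40-gene ETC set at
  −0.5; a 49-gene eggshell set at −1.0 / −0.3 (strain-asymmetric); one TE
  family up (+1.5), four down (−1.2), and a pair with opposite-sign ±0.8
  strain-by-age effects. Genes in no set have age effect exactly 0.
* $\alpha$: one genome-wide dispersion, default 0.05 — a typical
  biological-replicate value for inbred-line bulk RNA-seq; Var = mu +
  alpha·mu². A single alpha is the simplest calibratable choice and is what
  the dispersion-estimation tests recover.
* Geometry: five major chromosome arms (each with a 2 Mb pericentric block
  and five dispersed 200 kb intercalary blocks), a fully heterochromatic
  1.35 Mb dot chromosome, a mitochondrial contig, and a TE contig.
  A configured fraction of genes (default 1695/14289) is placed inside
  domains — dot-chromosome genes first, the rest split 1:2 between
  pericentric and intercalary blocks — and all other genes inside the
  euchromatic gaps, so the emitted BED domains and the truth table agree by
  construction. Transcript lengths are log-normal around 2 kb, floored at
  200 bp so RPKM is always defined.
* `paper_marginal_config()` pins the annotation marginals to 14,289 genes,
  1,695 heterochromatic, 84 on the dot chromosome.

The seed fully determines every output, down to the bytes of the written
files. The generator emulates the *statistical* structure the tests assume —
NB sampling noise, library-size variation, unbalanced replicates, set-wise
coordinated shifts, compartment geometry — and deliberately not: read-level
artifacts, GC or length biases, transcript isoforms, correlated gene-gene
expression within pathways beyond the injected mean shifts, TE insertion
polymorphism between strains, or per-gene biological aging variation outside
the declared sets. Passing tests therefore certify the statistics under
clean NB assumptions, not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* GLM fits use `glm.fit` with an NB family at fixed per-feature dispersion
  (maximum 50 IRLS iterations); non-convergent or rank-deficient fits yield
  NA p-values, are flagged, and leave the FDR denominator.
* All-zero features are dropped; constant-count features get the dispersion
  floor rather than an error.
* The permutation test's exceedance comparison uses plain `>=`, so exact
  ties (e.g. the all-identical-ratios degenerate case) count as exceedances
  and give p = 1.
* `sign_test` requires `n_total >= 1`; `yates_chi2` refuses zero margins;
  `cross_strain_correlation` refuses zero-variance inputs and needs at least
  3 features; `te_global_test` needs at least 3 families.
* Matching ties in overall expression resolve by counting equal-expression
  candidates as ranked above the focal gene, with stable order within ties.

## Problem sizes in the test suite

The suite calibrates on simulations sized to make each check sharp but
quick: 2,000-gene datasets for DE calibration and permutation-test studies
(200 null datasets for the uniformity study, 50 for power, 2,000
permutations each), 5,000 genes for the generator's effect-recovery check,
the full 14,289-gene paper-marginal preset once for the end-to-end
structural run, and exhaustive enumeration up to 4 focal genes × 3 matches.
These sizes are the package's chosen trade-off between Monte-Carlo error
and turnaround.

## Known limitations

* The default joint-exceedance permutation p is a descriptive proportion,
  not a calibrated p-value, under strain-independent nulls (see above);
  `criterion = "min"` is the calibrated alternative.
* The NB stage is intentionally plain: no fold-change shrinkage, no outlier
  handling, single-alpha default in the generator. Gene lists will differ
  from heavier DE tools on the margins even when both are calibrated.
* Between-sample normalization is per-million scaling (RPKM) plus
  median-of-ratios size factors in the count models; no TMM/quantile
  variants.
* Gene sets are user-supplied GMT files; the package ships no canonical
  piRNA-pathway list, since set membership is a curation decision.
* TE analysis is family-level only; locus-level insertion genotyping and
  small-RNA (piRNA pool) analysis are out of scope.
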