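---
title: "Autozygosity burden from runs of homozygosity: models and methods"
author: "RohBurden package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity burden from runs of homozygosity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RohBurden)
```

## The scientific problem

When both copies of a chromosomal segment descend from a single ancestral
segment, every variant in it is homozygous: the segment is *autozygous*.
Dense SNP arrays reveal such segments as long runs of homozygosity (ROH).
The fraction of the autosome covered by ROHs, written Froh, estimates the
genomic inbreeding coefficient F — the probability that the two alleles at
a locus are identical by descent. If disease-risk alleles are biased
toward recessivity (directional dominance), autozygosity should raise
disease risk, and a case/control cohort should show a positive
relationship between Froh and affection status. This package implements
that entire chain for multi-site case/control SNP cohorts: quality
control, LD pruning, ROH detection, Froh and its decompositions, burden
regression models, regional ROH mapping with permutation thresholds, and
a synthetic-cohort generator with planted autozygosity so that every step
is testable without access to consortium genotypes.

## ROH detection

A run of homozygosity is a maximal stretch of consecutive homozygous
calls. The caller (`callRohs`) applies three rules, all configurable via
`rohParams()`:

* **Consecutiveness** — at least `min_snps` homozygous SNPs in a row
  (default 65), with *no* heterozygote calls allowed; a heterozygote
  always breaks a run. By default a missing call breaks a run too; since
  the intended substrate is best-guess imputed calls with no missingness,
  this default is inert there, and `allowed_missing > 0` makes missing
  calls transparent for raw-data use.
* **Density** — a run is kept only if its span per SNP is at most
  `min_density_bp_per_snp` (default 200 kb per SNP). The test is applied
  to the whole run rather than a sliding sub-window: the rule's purpose
  is to stop runs from crossing SNP deserts such as centromeres, and the
  whole-run ratio is the simplest rule that is fully testable against an
  independent enumerator.
* **Gap** — a run is split wherever adjacent homozygous SNPs are more
  than `max_gap_bp` apart (default 500 kb).

At 65 SNPs and roughly one SNP per 30 kb, the shortest callable ROH spans
about 2 Mb, long enough that chance runs of homozygosity are vanishingly
rare (the per-SNP homozygosity is ~0.64 under the default frequency
spectrum, so a 65-SNP chance run has probability ~1e-13 per start).

Lengths are spans: `length_bp = bp_end - bp_start`, the convention used
throughout, so a 27,700,000 bp ROH contributes exactly 0.01 to Froh under
the default denominator.

`joinMiscallSplit` re-joins two adjacent ROHs separated by at most one
heterozygous call and at most 500 kb. A single heterozygote in the middle
of several megabases of homozygosity is far more plausibly a genotyping
miscall than two independent autozygous segments abutting by chance. The
joined records feed only tract-length (generation-depth) analyses; Froh
is always computed from the unjoined calls, since the bridged span was
still observed homozygous on both sides and the joining would perturb the
burden denominator logic.

## Froh and its decompositions

`computeFroh` divides the summed ROH length by the SNP-mappable autosomal
distance, 2.77e9 bases. ROHs shorter than 5 Mb feed `froh_short`, those
of at least 5 Mb feed `froh_long` (a tract of exactly 5 Mb is "long");
the two always sum to `froh` exactly, as do the common/uncommon
components when allelic-match labels are supplied.

The 5 Mb boundary is motivated by Haldane's recombination model: a tract
inherited intact from a common ancestor g generations back has
exponentially distributed length with mean 1/(2g) Morgans, so at the
1 cM/Mb rule of thumb a 5 Mb expected length corresponds to g = 10 —
short ROHs reflect distant inbreeding, long ROHs recent inbreeding.
`haldaneMeanLength` and `inferGenerations` implement the model and its
maximum-likelihood inversion (the exponential MLE is the reciprocal of
twice the mean observed length).

`matchRohs` labels pooled ROHs *common* or *uncommon*. ROHs are grouped
by single-linkage over pairs with at least 50% reciprocal span overlap;
within a group two ROHs match when their homozygous-genotype identity
over the group consensus region reaches 0.95; an ROH with at most 16
matches is uncommon. The 16-match boundary is the median match count in
the motivating application; the 50% overlap and 0.95 identity values are
this package's defaults for parameters that the original external tooling
did not document — they are exposed as arguments, and the planted-family
test shows the classifier separates haplotype families of size 5 and 30
cleanly at these settings.

`classifyPossibleDeletion` guards against hemizygosity: a deletion on one
chromosome makes the surviving allele look homozygous. An ROH whose
length falls strictly below 500 kb after subtracting its overlap with
known deletion calls is flagged as a possible deletion. Since deletions
have median length ~10 kb while callable ROHs start near 2 Mb, the flag
rate is expected (and observed, in the simulation tests) to be well under
1%.

## Burden models

The central model is a mixed-effects logistic regression of case status
on Froh with a dataset-level random intercept
(`fitMixedLogistic`, Laplace-approximate ML via lme4):

$$\mathrm{logit}\,P(y_i = 1) = \alpha + a_{d(i)} + \beta\,F_{roh,i}
  + \gamma^\top c_i,\qquad a_d \sim N(0, \sigma_d^2).$$

The random intercept absorbs between-site differences in base rate and
genotyping platform. Covariates \(c_i\) (principal components of the
genotype matrix, per-sample missingness, excess heterozygosity) control
population stratification and call-quality artifacts; `buildCovariates`
computes them from the post-QC calls. Confidence intervals are Wald
intervals on the log-odds scale, hence symmetric in beta and asymmetric
after exponentiation.

A slope beta converts to interpretable effect sizes as
`exp(0.01 * beta)` — the odds multiplier per 0.01 of Froh — and
`exp(beta * F)` for the expected autozygosity of specific matings
(F = 0.0625 for cousin-cousin, 0.015625 for second-cousin offspring).

Supporting analyses: per-dataset logistic fits (`perDatasetFits`) with an
exact one-sided binomial sign test on the direction of the odds ratios
(`signTest`, ties excluded); a threshold sweep re-calling ROHs over a
grid of `min_snps` values (`thresholdSweep`); a sensitivity suite
(`sensitivitySuite`) that refits after dropping samples above Froh
cutoffs 0.125, 0.0625, 0.03125, 0.005 and the cohort mean, adds a
quadratic Froh term as a linearity check, and fits the short/long and
common/uncommon components separately; and a 2-df likelihood-ratio
heterogeneity test comparing random-slope to random-intercept models
(`heterogeneityTest`) — the motivating analysis reports a heterogeneity
statistic without naming its test, and a slope-variance LRT is the
natural choice consistent with its shape.

Nagelkerke's pseudo R² is reported against the covariate-only null, so
it measures the contribution of Froh itself.

## ROH mapping

`rohMapping` tiles the autosome into 500 kb bins anchored at position 1
per chromosome (the final partial bin is retained), scores each sample
for any-overlap ROH carriage per bin, and runs one logistic regression
per bin of case status on carriage plus covariates. Dataset enters as a
fixed indicator here — with a single binary predictor per bin, the cheap
fixed-effect adjustment is preferable to thousands of mixed-model fits,
and the permutation calibration makes the choice immaterial for
inference. Bins carried by no one or everyone are skipped, in both the
real scan and the permutations.

Significance thresholds come from permutation: case/control labels are
shuffled *within* dataset (preserving per-site case counts), the scan is
re-run, and the minimum p across bins is retained. Over `n_perm = 1000`
permutations the 50th smallest minimum is the genome-wide threshold and
the 100th the suggestive threshold — order statistics that control
family-wise error at ~5% and ~10% regardless of the p-values'
distribution, which matters because carriage is sparse and the per-bin
p-values are discrete. `frohExcluding` recomputes Froh with hit regions
excised, to ask how much of the overall burden signal any region carries.

## The synthetic cohort generator

`simulateCohort` emulates the data-generating process the analyses
assume, with every parameter in `simConfig()`:

* **Panel** — SNPs sit on a regular grid of mean spacing 30 kb with
  ±20% uniform jitter, emulating the near-uniform density of an
  LD-pruned panel (~1 SNP per 30 kb). The jittered grid, rather than
  exponential waiting times, guarantees that a 2.5 Mb tract always
  contains enough SNPs to be callable — the property the recovery
  analyses quantify. Allele frequencies are uniform on 0.05–0.5 and the
  genetic map is 1 cM/Mb unless overridden.
* **Haplotypes** — a first-order Markov chain: each allele copies its
  left neighbour with probability `ld_rho` (default 0.3, residual LD of
  a pruned panel) and is otherwise drawn fresh from its frequency.
* **Autozygosity** — per sample, a target fraction f is drawn from a
  mixture of a point mass (85% at 0.0005) and an exponential tail (15%
  with mean 0.006). Tracts are then planted by a Poisson process: count
  ~ Poisson(f x L x 2g) with lengths Exponential(mean 1/(2g) Morgans)
  (g = 6 by default), placed uniformly, truncated at chromosome ends and
  merged. The Poisson-process design, rather than explicit pedigree
  simulation, gives exact control of the target fraction while keeping
  the exponential length law that the generation-depth analyses assume;
  the per-person tract-count law is a modelling choice, not an estimate.
  The mixture is calibrated so the marginal Froh distribution has mean
  ~0.0015 and SD ~0.004 and is strongly right-skewed, matching the
  descriptive statistics of large European-ancestry case/control
  cohorts.
* **Noise** — each truly homozygous call flips to a heterozygote with
  probability `het_miscall_rate` (default 0.001); miscalls at already
  heterozygous sites are irrelevant to ROHs, which is why the error is
  applied only at homozygous sites. `missing_rate` defaults to 0,
  emulating best-guess imputed calls. Hemizygous deletions (Poisson
  ~100 per sample, log-normal lengths with median ~10 kb) force
  heterozygotes within their span to a random homozygote.
* **Disease** — P(case) = logistic(alpha0 + a_d + beta_froh x F_true)
  with site intercepts a_d ~ N(0, sigma_dataset²). Defaults: 17
  datasets of 1,285 samples (n = 21,845), alpha0 = -0.28 (43% cases),
  sigma_dataset = 0.3 (moderate between-site heterogeneity),
  beta_froh = 16.1.

`simulateFrohLevel` bypasses genotypes and draws Froh directly from the
same tract model — the workhorse for parameter-recovery and type-I-error
studies at full cohort scale. `metadata()` of a simulated cohort carries
the full truth (per-sample tracts, realized autozygous fraction, dataset
intercepts, deletion regions) for recovery tests.

What the generator deliberately does *not* model: coalescent ancestry
and realistic recombination maps, population structure between or within
datasets, batch/plate artifacts, and imputation error structure. Passing
tests therefore demonstrate that the pipeline's logic is correct under
its own assumptions — unbiased slope recovery, calibrated size, exact
caller semantics — not that real cohorts are free of the confounding
these features create; on real data the covariate controls, not the
simulator, carry that burden.

## Quality control

`sampleQC` removes samples with call missingness > 0.02, genome-wide
heterozygosity more than 6 SD above the cohort mean, and one member
(the higher-missingness one) of any pair with relatedness > 0.2. The
relatedness statistic is the off-diagonal of the standardized genotype
relationship matrix — a moment estimator of genome-wide IBD sharing that
agrees with pi-hat at the 0.2 decision boundary for the relationship
classes the filter targets. `snpQC` applies the Hardy-Weinberg 1-df
chi-square filter at p < 1e-6 (computed in controls only, the standard
GWAS practice, since case genotypes can deviate through association),
SNP missingness > 0.02, case/control missingness difference > 0.02,
frequency difference to an optional reference panel > 0.15, and the
MAF >= 0.05 floor.

`ldPrune` slides a 50-SNP window (step 5) and, while any SNP in the
window can be predicted from the other retained window SNPs with
multiple R² > 0.90 (OLS on standardized, mean-imputed calls), removes
the offending SNP at the largest map position. Removing the later SNP of
a redundant pair keeps the first-seen marker, and the loop guarantees on
exit that no retained SNP is predictable above threshold from its
retained window-mates — the property the tests verify by direct
recomputation. The exact traversal is not scientifically load-bearing;
determinism is.

Both filters are idempotent. An optional PCA ancestry-outlier filter is
exposed but off by default: ancestry curation of real cohorts is a
dataset-construction step, not something a simulator-backed test can
meaningfully constrain.

## Numerical choices and degenerate inputs

* Missing genotype calls use `NA`; all statistics treat them explicitly
  (mean imputation only inside PCA/LD computations).
* Logistic fits are IRLS (`glm`); quasi-separation and constant
  predictors yield flagged, non-converged `BurdenFit`s rather than
  silent garbage. The mixed model uses the Laplace approximation with
  the bobyqa optimizer; derivative-based convergence checks are
  disabled in favour of the optimizer's own status because the
  finite-difference Hessian is unreliable at Froh's small scale
  (slopes of order 10 on a predictor of order 0.001).
* Wald inference throughout; CIs are beta ± 1.96 se.
* In the per-bin scan, a Wald SE above 100 (carriage too sparse to
  inform) marks the bin as skipped instead of reporting a meaningless
  p-value; skipped bins are skipped identically in permutations.
* Ties in the sign test (odds ratio exactly 1) are dropped from n.
* Region arithmetic is in the span metric (end - start), matching the
  ROH length convention; BED input/output converts between 0-based
  half-open and the internal 1-based inclusive convention at the
  boundary, and deletions are merged before overlap subtraction.

## Problem sizes used in the validation suite

The parameter-recovery study runs 100 replicates at the full default
scale (17 datasets, n = 21,845) at the Froh level. The type-I study uses
400 replicates of 10 datasets x 300 samples — size calibration of a
Wald test does not require the full cohort, and this size keeps the
study's runtime proportionate. The permutation-calibration study uses
50 null studies of 600 samples x 50 bins with 200 permutations at
genome-wide rank 10 (expected family-wise error 10/201). Genotype-level
recovery and deletion-classifier studies use 120–1,700 samples on 3–5
chromosomes of 1-1.5e8 bp. These sizes are the package's validation
design; all are overridable through the same public interfaces.

## Known limitations

* The Froh denominator (2.77e9) and the autosome lengths are fixed
  constants of the human SNP-mappable genome; analyses of simulated
  mini-genomes should pass the simulated genome length instead (the
  pipeline does this automatically for simulated cohorts).
* `matchRohs` is quadratic in the size of an overlap group; adequate for
  cohort-scale ROH counts, not for biobank scale.
* The caller's `allowed_het` is fixed at 0 by design — the tolerant
  variants used on raw array data interact with density rules in ways
  the whole-run density test does not capture; raw-data emulation should
  instead raise `het_miscall_rate` and use `joinMiscallSplit`.
* Permutation thresholds shuffle labels only; covariates stay attached
  to samples, so confounding between covariates and carriage is
  preserved under the null, which is the intended exchangeability.
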