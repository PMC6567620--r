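---
title: "Methods: spike-calibrated microbiome, metabolite, and longevity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-calibrated microbiome, metabolite, and longevity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muribloom)
```

muribloom implements a multi-stage analysis of 16S rRNA gene surveys from
acarbose-treated mice sampled at three study sites, where each fecal sample
was spiked with a fixed aliquot of *Sphingopyxis alaskensis* cells before DNA
extraction. This vignette is the package's own account of the statistical
procedures, the choices that were genuinely open, and what the synthetic
cohort generator does and does not emulate.

## Spike-adjusted absolute abundance

Relative abundances confound a bloom of one taxon with an apparent decline of
every other. The spike-in standard provides a per-sample yardstick: with
$R$ the relative abundance of a taxon among endemic reads, $E$ the endemic
read total, $S$ the spike read total, $v$ the spike volume (uL) and $w$ the
sample wet weight (g), the spike-adjusted abundance is

$$ A \;=\; R \cdot \frac{E \, v}{S \, w} $$

in uL-spike-equivalents per gram. No attempt is made to convert to literal
16S copies per gram; only the relative yardstick is calibrated. Summed over
taxa the statistic equals $E v / (S w)$, which the tests use as an exact
identity. A sample with zero spike reads has an undefined statistic; such
samples are reported as missing and excluded from density analyses rather
than imputed, because any pseudo-count in the denominator would bias density
ratios. (Whether such samples occurred in the original study is unknown; the
drop rule is this package's policy.)

Family-level abundance is the sum over member OTUs, so totals are conserved
and the unit (relative or spike-equivalent) propagates unchanged.

## Diversity

* **Chao1** uses the bias-corrected estimator
  $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$, finite even without doubletons;
  it equals the observed richness when at most one singleton is present.
* **Simpson's evenness** is the inverse Simpson index divided by observed
  richness, $E = (1/\sum p_i^2)/S_{obs} \in (0, 1]$. The source toolchain
  (mothur's `simpsoneven`) uses this form; since the defining publication
  leaves the formula unstated, the reported control/treated medians cannot
  discriminate among conventions without the raw data, and this convention
  is fixed here once.
* **Rarefaction** subsamples each sample once, without replacement, to the
  cohort-minimum endemic read count, with a seeded single realization (no
  averaging over realizations). Diversity statistics are then computed on the
  rarefied profile.
* **Partitioned diversity** removes a designated OTU set *first* and then
  rarefies to the minimum remaining total. The order is the point: it
  equalizes the retained read totals across samples, so a dominance shift in
  the excluded taxa cannot masquerade as a diversity change in the remainder.

## Community structure

Bray-Curtis dissimilarity ($\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$) feeds
three procedures implemented from their definitions:

* **PCoA**: eigendecomposition of the double-centered Gower matrix of squared
  dissimilarities; negative eigenvalues are reported, not corrected; percent
  variance is relative to the sum of positive eigenvalues.
* **PERMANOVA** with sequential (Type I) sums of squares via projection
  operators on the Gower matrix. Term order is user-controlled because
  order-robustness of the conclusions is itself of scientific interest in an
  unbalanced design. Significance comes from free permutation of the sample
  rows, with no strata: only one mouse per cage was sampled, so cages do not
  form exchangeability blocks.
* **PERMDISP**: distances to *group centroids* in the full PCoA embedding
  (squared imaginary-axis distances subtracted, clipped at zero), then a
  one-way ANOVA F on the distances with label permutation. Centroids, not the
  spatial medians that `vegan::betadisper` defaults to, are used for analytic
  tractability; the test cross-checks distances against `betadisper(type =
  "centroid")`.

Permutation p-values follow the $(1 + b)/(1 + m)$ convention, so the observed
statistic is a member of its own null set and p is never zero. When a
complete permutation set is supplied explicitly (exact enumeration), p is the
plain exceedance fraction instead — the identity permutation is already in
the set, and adding one would double-count it. Default $m = 999$; the number
of permutations in the original analysis is not reported, so this is a
package choice.

## Differential abundance

Per-OTU testing follows a two-stage design. Every OTU detected in at least
two samples is fit with a negative-binomial log-linear model of counts on
`site + sex + treatment + sex:treatment` with log size-factor offsets
(median-of-ratios size factors over OTUs positive in all samples, with a
positive-count fallback). The per-OTU dispersion is a method-of-moments
estimate floored at $10^{-8}$; the empirical-Bayes dispersion shrinkage of
dedicated differential-abundance packages is deliberately *not* reproduced —
the scientific content here is the design and filtering procedure, not the
shrinkage machinery — so per-OTU power at low counts is somewhat lower than
DESeq2's. Wald z statistics give two-sided p-values.

FDR correction then applies Benjamini-Hochberg *only* to OTUs passing two
filters computed from abundance, never from p-values: mean relative abundance
at least 0.01% and detection in at least 5% of samples (cohort-wide; the
per-site alternative is not used). Rare OTUs keep their raw p but receive no
q, reducing the number of tests without biasing the FDR. Mann-Whitney U
tests (exact by enumeration when the combined sample size is at most 12 and
tie-free, otherwise tie-corrected normal approximation) serve the univariate
group comparisons.

## Metabolite quantification

HPLC standard curves are weighted least squares of peak area on
concentration with weights $1/c^2$, fitted without an intercept for every
compound except propionate. Without an intercept the weighted slope reduces
exactly to $\mathrm{mean}(a_i / c_i)$, which the tests exploit as a closed
form. Concentrations convert to umol per g wet feces through the extraction
volume — either proportional (1:10 weight:volume) or the fixed-volume
protocol variant — with areas below the intercept clamped to zero and
flagged. Zeros are replaced by half the minimum detected concentration of
that compound before natural-log transforms (the log base cancels in every
test statistic). Total SCFA is defined exactly as acetate + butyrate +
propionate.

Two interaction analyses run on log concentrations: the treatment-by-site
F-test from an ANOVA including `site + sex + treatment + treatment:site`,
and a Gaussian likelihood-ratio test, $n \log(RSS_0 / RSS_1) \sim \chi^2_1$,
for the sex-by-treatment term with all other two-way interactions retained
in both models. The 1-df LRT runs slightly liberal at small n (it lacks the
F-test's denominator correction); the null-calibration tests allow for this.

## Taxon-metabolite association

Family-level Spearman correlations (Student-t approximation,
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$) are computed within strata so that
between-site or between-treatment offsets cannot manufacture correlation.

The OTU-level LASSO predicts log metabolite concentration, adjusted for
site, sex and treatment by OLS residualization, from the spike-adjusted
abundances of OTUs passing the same 5%-incidence and 0.01%-mean filters.
Predictors are standardized before penalization — penalizing raw
uL-equivalents-per-gram scales would make the penalty meaningless across
OTUs — and coefficients are reported on that standardized scale. Abundances
are not log-transformed by default (the source analysis specifies the log
transform only for the response); `lasso_cv()` accepts any design matrix, so
callers can pass transformed abundances if desired. The penalty is chosen to
maximize pooled out-of-bag $R^2 = 1 - SSE_{oob}/SST$ over a randomized
10-fold assignment on a 100-point log-spaced grid from $\lambda_{max}$ down
to $10^{-4}\lambda_{max}$, and the final model is refit on all data at the
chosen penalty.

A model is **validated** when the Spearman correlation between observed
responses and out-of-bag predictions is *positive* with $p < 0.05$. The sign
requirement is a deliberate design choice: when the selected penalty yields
an (almost) all-zero model, each held-out prediction is the training-fold
mean of the response, which is mechanically anti-correlated with the held-out
values; a two-sided gate validates that artifact often under a pure-noise
null, while the positive-sign gate holds the type-I error at or below the
nominal 5% (verified over 200 null replicates in the test suite).

## Survival analysis

Lifespans are related to fecal SCFA concentrations by Cox proportional
hazards with *delayed entry*: a mouse enters the risk set only at its fecal
sampling age, since mice dying before sampling are structurally unobservable.
All sampled mice were dead at analysis, so there is no right-censoring. Ties
are handled with the Efron correction (day-resolution lifespans make ties
certain; Efron is the survival-package default the original analysis used).
Sampling age acts only through delayed entry, never as a covariate. SCFA
concentrations are log-transformed, centered and scaled to unit SD over the
analysis cohort (after exclusions), so `exp(coefficient)` is a standardized
hazard ratio per SD. The null model carries treatment, sex, site and all
their two- and three-way interactions; each SCFA is tested singly over that
null, and the three jointly, with a 3-df likelihood-ratio comparison.
Monotone likelihoods (perfect separation) are detected and raised as errors,
not returned. Kaplan-Meier group medians use the step-function convention
(smallest time with survivor function at or below one half), and percent
changes in medians are reported rounded to whole percent, as longevity gains
are conventionally quoted.

## The synthetic cohort generator

No sequence data are deposited for the motivating study, so the generator is
a first-class module that emulates the *statistical structure* the analysis
assumes, with planted-effect and null modes.

* **Design**: 3 sites x 2 sexes x 2 treatments x 12 mice (144 samples), one
  mouse per cage, sampling ages uniform on 762-973 days.
* **Community**: log-normal per-OTU baseline densities with site offsets
  (the skewed abundance distributions the non-parametric tests assume; no
  generative model is given by the source, so log-normal is a package
  choice). The focal taxa have fixed, not drawn, baselines calibrated to the
  published community profile: the bloom OTU near 8% of control sequences
  and near 29% under treatment, five dominant families in realistic
  proportions, spike reads a few percent of each sample. Under treatment the
  site's bloom OTU density is multiplied by 4.3 and the other
  *Muribaculaceae* by 0.5 — the planted folds downstream stages must
  recover. `OTU_4` exists only at UT; `OTU_1` blooms at TJL and UM.
* **Sequencing**: one multinomial draw per sample over endemic copies x
  weight and spike copies x volume, at a depth uniform on 70-130% of the
  target. No FASTQ-level artifacts (chimeras, PCR bias) are simulated;
  generation starts at OTU counts.
* **Metabolites**: log concentration = baseline + direct treatment effects
  (glucose up, succinate down) + per-OTU coefficients on *within-site*
  standardized log1p density + a latent factor shared by acetate and
  butyrate + Gaussian noise. Within-site standardization makes the planted
  couplings hold inside every site (as reported for the real data), and a
  site-restricted taxon's coupling is zeroed off-site so that latent noise
  invisible to sequencing cannot dilute the planted signal. Coefficients and
  noise SD are calibrated so planted family-metabolite rank correlations
  fall in the reported 0.36-0.8 range.
* **Survival**: Weibull proportional hazards (shape 6, scale 920 days) with
  sex-specific treatment effects and the published standardized hazard
  ratios (0.674 propionate, 0.586 butyrate, 1.576 acetate) as per-SD
  log-hazard coefficients. Left truncation uses inverse-transform sampling
  on the conditional survivor function given survival to sampling age,
  avoiding unbounded rejection loops.
* **Sex effects** on the community are off by default (reported to be small,
  and keeping them out keeps null mode exactly null). A cage-level random
  effect is exposed but defaults to zero: no cage variance component is
  reported to calibrate it against.
* One seed drives a single RNG stream from which each stage's sub-seed is
  derived, so cohorts are bit-reproducible.

What passing tests on these cohorts shows — and does not show: the pipeline
recovers planted folds, couplings and hazards under log-normal abundance,
multinomial sequencing, log-linear couplings and proportional hazards. Real
data can violate all of these (overdispersed sequencing beyond multinomial,
non-monotone taxon-metabolite relations, non-proportional hazards), and the
tests say nothing about robustness to such violations.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 144 mice (the study
design) for single-cohort checks; 12-24 replicate cohorts for fold-recovery
averages; 2004 mice for joint hazard-ratio recovery; 500 replicates for the
Cox coverage study; and 200 replicates for each null-calibration study, with
binomial tolerance bands of three standard deviations around the nominal
level — sizes chosen to make Monte-Carlo noise small relative to the
quantities being checked. Newton-Raphson convergence, tie handling and
rank-deficiency are delegated to `survival::coxph` (Efron, 50 iterations)
with explicit divergence detection; LASSO solutions come from glmnet at
convergence threshold $10^{-10}$ and are verified against the KKT conditions
in the tests; permutation statistics compare with a $10^{-12}$ slack so ties
in F are counted as exceedances.

## Known limitations

* The NB Wald stage has no dispersion shrinkage, no outlier handling, and no
  log-fold-change shrinkage; its per-OTU estimates at low counts are noisy.
* PERMANOVA offers no strata/blocks and no pairwise post-hoc tests;
  constrained ordination is out of scope.
* The LASSO reports a single penalty's support; it performs no stability
  selection, and support membership of weakly coupled taxa varies across
  cohorts at n = 144.
* Standard-curve handling assumes curves are assigned per run externally;
  no within-package batch assignment is performed.
* Right-censoring, time-varying covariates and frailty terms are not
  supported in the survival module.
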