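---
title: "Factor-analytic mixed models for multi-environment trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-analytic mixed models for multi-environment trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfa)
```

## The problem

Regional plant-breeding trials evaluate a changing set of genotypes across
many year-by-location *environments*. Such series are structurally
unbalanced: new hybrids enter every year, inferior ones are dropped, and an
environment can be lost altogether (drought, failed harvest). The questions
a breeder asks of these data — which hybrids are best on average, how
heritable is the trait, how stable is each hybrid across environments, do
two traits share genetic control — all require a model for the covariance
of genotype effects *across* environments, estimated from plot-level
records.

`metfa` implements that analysis for trait panels such as grain carotenoid
concentrations (lutein, zeaxanthin, beta-cryptoxanthin, alpha-carotene,
beta-carotene, and derived provitamin A) together with agronomic traits
(grain yield, flowering, plant and ear height).

## The model

The combined analysis fits, by restricted maximum likelihood (REML),

$$y = X\tau + Z_g u_g + Z_\eta u_\eta + e,$$

where $y$ stacks the plot records of one trait, $\tau$ holds fixed
environment means, $u_g$ the genotype-within-environment effects, $u_\eta$
the replicate- and incomplete-block-within-environment design effects with
diagonal covariance $G_\eta$, and $e$ the residuals with one variance per
environment (heterogeneous $R$). The genetic covariance across the $p$
environments for each of the $m$ genotypes takes the factor-analytic form

$$u_g = (\Lambda \otimes I_m) f + \delta, \qquad
  \mathrm{var}(u_g) = (\Lambda\Lambda' + \Psi) \otimes I_m,$$

with $\Lambda$ a $p \times k$ loading matrix ($k \le 3$), $f$ the $m\times k$
genotype scores with unit variance, and $\Psi$ diagonal specific (lack-of-fit)
variances. An FA($k$) model is a latent multiple regression of a genotype's
environment effects on $k$ environment covariates: the loadings are the
covariates, the scores are per-genotype slopes. The share of
genotype-by-environment variance the factors explain is
$\%\mathrm{VAF} = 100\,\mathrm{tr}(\Lambda\Lambda') /
\mathrm{tr}(\Lambda\Lambda'+\Psi)$.

A separate all-random *variance-component* model (environment, hybrid,
replicate-in-environment, hybrid-by-environment, heterogeneous residuals)
supplies the covariance tables, the drop-one REML likelihood-ratio tests,
and the inputs to Cullis heritability. The trial literature states the
combined model once with environment means fixed (the displayed formula)
and once with all effects random; the package resolves this by using the
fixed-means form for the FA fit (`fit_fa()`) and the all-random form for
the component tests (`fit_vc()`), which is also the split the reported
tables require.

## Estimation

Both fits run on the mixed-model equations, in two phases.

**Monotone EM warm start.** The coefficient matrix is partitioned so the
genotype-structured block is block-diagonal by genotype
($\Sigma^{-1}$ plus a diagonal of weighted counts); each E-step costs one
small Cholesky per genotype plus one Cholesky of the Schur complement of
the fixed + design block. M-steps are closed form, except FA($k$), which
takes an inner factor-analysis EM started from the current parameters (a
conditional-maximization step, so the restricted likelihood never
decreases).

**Quasi-Newton polish.** EM alone crawls along the near-flat ridges of the
FA likelihood: in our development runs it stalled with the leading factor's
variance visibly under-estimated while the log-likelihood moved by less
than $10^{-3}$ per hundred iterations. The polish phase therefore runs
L-BFGS-B on unconstrained parameters — free lower-triangle loadings
(the upper triangle of the leading $k \times k$ block is fixed at zero for
identifiability), log variances, and a log-Cholesky factor for the
unstructured bivariate case — using analytic REML gradients assembled from
E-step byproducts: for any genetic-covariance parameter $\theta$,

$$\frac{\partial \ell_R}{\partial \theta} = \frac{m}{2}\,
  \mathrm{tr}\!\left(\frac{\partial \Sigma}{\partial \theta}\,
  \Sigma^{-1}(S - \Sigma)\Sigma^{-1}\right),$$

where $S$ is the conditional second-moment matrix
$\tfrac1m\sum_i(\hat u_i \hat u_i' + \mathrm{PEV}_i)$, with matching closed
forms for design and residual variances. The gradients were validated
against central finite differences (agreement to seven digits). Box
constraints mirror the EM variance floors so both phases share one feasible
region, which keeps the recorded likelihood trace monotone.

Defaults: 60 EM warm-start iterations, L-BFGS cap 600, relative
log-likelihood tolerance $10^{-8}$, max-norm parameter tolerance $10^{-6}$,
$\Psi$ floor $10^{-8}$, residual floor $10^{-10}$. A fit is flagged
converged when the optimizer meets its function-change/projected-gradient
tolerances or when a trial EM step moves neither the likelihood nor the
parameters beyond the tolerances. On flat ridges (weakly informed
cross-year covariance blocks) a fit can exhaust the cap with the usable
quantities (likelihood, $\Sigma$, BLUPs, scores) fully stable; such fits
return `converged = FALSE` and downstream functions warn but proceed.

## Stability, heritability, correlations, profiling

*Rotation and latent-regression stability* (`rotate()`): REML loadings are
only identified up to rotation; the principal-component solution
$\Lambda = UDV'$ gives rotated loadings $UD$ and co-rotated scores $V'f$,
ordered by non-increasing explained variance. Each loading column is
sign-fixed so its sum over environments is positive — a positive slope then
reads "responds positively to better environments". The near-zero slope
threshold defaults to $0.25\,\mathrm{sd}$ of the slopes within each factor;
the source analyses say only "close to zero", so the value is a convention
and a parameter. Note the sign convention is a convention only: when a
loading column sums to approximately zero (a contrast-like factor), its
sign is data-noise; recovery tests therefore align estimated to generating
factors by the sign of their loading correlation.

*Cullis heritability* (`cullis_h2()`):
$H^2 = 1 - \bar v_\Delta / (2\hat\sigma^2_g)$ with $\bar v_\Delta$ the mean
prediction-error variance of genotype-BLUP differences over all pairs. It
uses the variance-component model's genotype main effect — the tables that
report heritabilities accompany that model, not the FA fit. An FA-based
variant was considered and not implemented, as nothing downstream consumes
it.

*Genetic correlations* (`genetic_correlation()`): a bivariate REML fit with
an unstructured $2\times2$ genotype covariance, trait-by-environment fixed
cells, and independent residuals per trait per environment; estimates are
clipped to $[-1, 1]$ with a warning, and a BLUP-correlation fallback (tagged
in the output) covers non-convergence.

*Profiling* (`pca_scores()`, `ward_groups()`, `canonical_discriminant()`):
PCA on the correlation matrix of the five carotenoid genotype BLUPs; all
five component scores feed Ward clustering (`ward.D2` on Euclidean
distances) cut at three groups by default — the group count is a parameter,
as no tree-cutting rule is stated in the source analyses. Canonical
discriminant functions come from the between/within scatter generalized
eigen-problem, with coefficients scaled to unit pooled within-group
variance, shares reported as percentages of the eigenvalue total, and
structure correlations (Pearson, variable vs canonical score) identifying
the carotenoids driving each function. Within-group scatter is regularized
($10^{-8}\,\mathrm{tr}/q$ on the diagonal) only when singular, with a
warning. Ties in Ward merges are broken toward the lowest-index pair by the
`hclust` ordering.

## The synthetic generator

`met_truth()` fixes every generating parameter; `generate_met()` draws
plot records from exactly the model above. The default trial-scale truth
(`default_fa_truth()`) mimics the regional-trial structure the package
targets: 23 environments over 4 years, 64 genotypes with year turnover (10
tested in all four years, 9 in three, 12 in two, 33 once), alpha-lattice
style blocks of 6 within 2 replicates, FA(2) genetic covariance with
all-positive first-factor loadings, mean per-environment genetic variance
3.7 (the provitamin-A scale, $(\mu g/g)^2$), a factor-explained share of
90%, heterogeneous residual variances of roughly 0.55–1.5, and replicate
and block variances of 0.37 and 0.30. These values reproduce the reported
analysis regime (heritability near 0.9, FA(2) explaining about 90% of the
interaction). Replicate count is a parameter: the source trials used three
replicates agronomically but sampled carotenoids from the first two, so
no single value is canonical.

A single root seed derives fixed substreams per random term (scores,
specific effects, replicates, blocks, residuals, missingness) so adding a
trait never perturbs earlier draws; `generate_multitrait()` correlates
corresponding factor-score columns across traits with a target genetic
correlation matrix while everything else stays independent, preserving
each trait's marginal structure. An optional missing-completely-at-random
plot deletion (default 0) emulates plot loss; no plot-level mechanism is
reported for the real trials, so nothing more elaborate is warranted.

What the generator does *not* emulate: spatial field trend (the analysis
model has none), genotype-by-management interaction, measurement rounding,
or the selection process that decides which hybrids are dropped between
years (turnover is a fixed design, not outcome-dependent). Passing
recovery tests therefore demonstrate estimator correctness under the
stated model, not robustness to field artefacts outside it.

## Verification strategy and problem sizes

Every stage is checked against an independent oracle on small instances:
dense restricted-likelihood evaluation and brute-force maximization (grid
plus Nelder-Mead) for the REML engine; dense mixed-model-equation solves
for BLUPs and prediction-error variances; exhaustive-search Ward merges;
dense generalized-eigen decompositions for the discriminant analysis;
hand arithmetic for the carotenoid formulas. Parameter recovery runs at
the full trial scale (10 generated trials of 64 genotypes by 23
environments), genetic-correlation recovery at 200 genotypes, and the
REMLRT calibration on 1000 small simulated trials (8 genotypes, 2
environments) — sizes chosen to give stable Monte-Carlo answers from a
test suite one can run routinely.

Two findings from that verification are worth recording. First, at 64
genotypes with realistic turnover, the sampling floor of the genetic
covariance matrix is large: even an oracle given the *true* simulated
genotype-effect vectors through the turnover observation mask misses
$\Lambda\Lambda' + \Psi$ by about 21% in aggregate relative terms (about
16% with no turnover), so headline covariance-recovery figures at this
scale measure information limits as much as estimator quality; the
trace ratio (%VAF) and the score signs, by contrast, are recovered well
(within ±4 points and above 94% agreement in our runs). Second, the
chi-square(1) reference for the drop-one REMLRT is conservative at the
variance boundary; the package reports it as the default because the
source analyses do, and offers the 50:50 mixture reference as an option.

## Known limitations

- FA orders above 3 are not supported; the source analyses never exceed
  FA(3), and the auto-selection rule (smallest $k$ with %VAF $\ge$ 85) is
  a convention, not a stated criterion.
- The bivariate genetic-correlation model omits a genotype-by-environment
  term; with heterogeneous residuals per trait-environment cell this is
  absorbed in practice, but correlations of strongly interacting traits
  are main-effect correlations.
- No spatial adjustment, outlier screening, or pedigree information —
  none appear in the analyses this package implements.
- Wall-clock: a full-scale FA(2) fit takes on the order of 15 seconds on
  one core; the EM phase dominates for variance-component models and the
  L-BFGS phase for FA fits.
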