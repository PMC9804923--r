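---
title: "Multilevel phylogenetic meta-analysis of developmental thermal plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel phylogenetic meta-analysis of developmental thermal plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darrmeta)
```

## The question and the effect size

Ectotherms raised at warmer embryonic or juvenile temperatures sometimes
tolerate heat better as a result — developmental plasticity of heat
tolerance. The evidence is scattered across hundreds of experiments that
each reared animals at two or more developmental temperatures and assayed
heat tolerance (CTmax under ramped heating, LT50 under fixed exposure, or a
static knockdown-time assay). `darrmeta` implements the full chain needed to
synthesize such experiments.

The effect size is the developmental acclimation response ratio,

$$dARR = \frac{HT_{T_2} - HT_{T_1}}{T_2 - T_1},$$

the change in heat tolerance (°C) per degree of developmental warming. A
dARR of 1 is perfect compensation; 0 is no plasticity; negative values mean
warmer development *reduces* tolerance. Because it divides by the
temperature difference, dARR is comparable across designs with different
treatment spacings.

Its sampling variance follows from the group summaries. For independent
groups,

$$s^2(dARR) = \frac{1}{(T_2-T_1)^2}\left(\frac{sd_1^2}{n_1} +
\frac{sd_2^2}{n_2}\right) \quad\text{or}\quad
\frac{se_1^2 + se_2^2}{(T_2-T_1)^2},$$

and when the *same* cohort of animals is measured at both temperatures the
errors correlate and

$$s^2(dARR) = \frac{sd_1^2 + sd_2^2 - 2r\,sd_1 sd_2}{(n_1+n_2)(T_2-T_1)^2},$$

with the analogous se form. The repeat-measurement correlation $r$ is
unknowable from published summaries; `r = 0.5` is the conventional
conservative choice and is exposed as a parameter. When one group reports
sd and n and the other only se, the sd-based group is converted
(`se = sd/sqrt(n)`) and the se form used — for independent *and* for
cohort-paired comparisons — because dropping the pair would discard data the
formulas can accommodate.

Designs with more than two developmental temperatures are expanded into
*stepwise* comparisons of adjacent temperatures (20–22, 22–25, 25–27 °C),
so a $k$-temperature design yields $k-1$ effects and every interior group
participates in two of them. That re-use is recorded effect-by-effect (which
two group rows built each effect) so the induced sampling covariance can be
reconstructed exactly.

### Missing dispersion and static assays

Rows with a missing sd but known n and mean get an imputed
`sd = cv * |mean|`, where `cv` is the arithmetic mean of sd/mean ratios over
all complete rows. The pool is per heat-tolerance metric by default because
dynamic (CTmax) and static (LT50) assays disperse on different scales;
treating the ratio as constant across studies, and pooling it as an
unweighted mean, are assumptions, flagged here. Standard errors cannot be back-imputed without n and are left alone;
rows with no usable dispersion go to a rejects table with machine-readable
reasons, never silently.

Static assays report time to knockdown at several constant test
temperatures. Knockdown time declines log-linearly with temperature (the
thermal death time curve), so the package fits OLS of $\log_{10}$(time in
hours) on test temperature and inverts to the temperature tolerable for
exactly one hour, $T^\* = -a/b$, a CTmax proxy. Base 10 and hours are
choices (any base shifts both coefficients consistently; the 1-h criterion
is then the root of the fitted line). The uncertainty of $T^\*$ has no
established convention; we attach the delta-method SE from the OLS
coefficient covariance, $\nabla = (-1/b,\; a/b^2)$, and treat the result as
an se-only group row. Estimates outside the tested temperature range warn,
since extrapolated TDT inversions are less reliable.

## Nonindependence

Three structures are modelled explicitly.

* **Phylogeny.** A user-supplied (or simulated) species tree is made
  strictly bifurcating by seeded random polytomy resolution, given Grafen
  branch lengths — node height $(d-1)/(n-1)$ raised to a power $\rho$
  (default 1), tips at 0, root at 1 — and converted to a correlation matrix
  $A$ with $A_{ij}$ the shared root-to-MRCA path length. Species in the
  data but absent from the tree are a hard error: grafting is a curation
  decision that belongs to the input tree, not the pipeline.
* **Shared treatments.** Effects that re-use a treatment group get sampling
  covariance $r_{shared}\sqrt{v_i v_j}$ (default $r_{shared} = 0.5$); the
  functional form is the standard shared-control convention. In a
  four-temperature chain, effects 1–2 and 2–3 correlate, as do 2–3 and 3–4,
  but 1–2 and 3–4 do not — the covariance follows actual group overlap, not
  a block stamp.
* **Shared cohorts.** Handled in the variance formula itself (above).

## The model

Effect sizes $y$ with design matrix $X$ are modelled with marginal
covariance

$$\Sigma(\theta) = \sigma^2_{phylo}\, Z A Z^\top + \sigma^2_{species}\, Z
Z^\top + D_{obs}(\theta) + V,$$

where $Z$ maps effects to species, $V$ is the known sampling VCV and
$D_{obs}$ is diagonal: a single observation-level variance, or one per level
of a categorical moderator — the heteroscedastic, zero-covariance residual
structure used for the moderator models. Variance components are estimated
by REML; fixed effects by GLS at the optimum; inference uses t
distributions with $df = k - p$ and the convention that a 95% CI excluding
zero is "significant". REML AICs (penalty = number of variance parameters)
compare residual structures at a fixed $X$.

Numerical choices: components are optimized on the log scale (Brent for one
component, Nelder–Mead otherwise) from three deterministic starts, relative
tolerance 1e-8; components below 1e-8 times the response variance are
reported as exactly 0; if a proposed $\Sigma$ loses positive definiteness to
rounding, eigenvalues are clipped at 1e-10 *for the factorization only*.
The structured solver is tested against an independent dense-likelihood
optimizer (textbook determinant/solve formulation) to 1e-6 on 20–30-effect
instances.

Derived quantities:

* **Heterogeneity.** $I^2_c = \sigma^2_c / (\sum_c \sigma^2_c + \bar s^2)$
  per component, with the multilevel "typical" sampling variance
  $\bar s^2 = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/v_i$.
  Components share a denominator, so they sum exactly to the total; this
  $\bar s^2$ is the standard multilevel convention.
* **Prediction intervals.** $\hat\beta \pm t_{df}\sqrt{SE^2 + \sum
  \sigma^2}$. Under per-level residual variances the observation component
  enters as the effect-count-weighted mean of level variances (there is no
  single established convention); per-level intervals using each level's
  own variance are also returned.
* **Post-stratified marginal means.** For cell-means moderator fits, the
  equal-weight average $c^\top\hat\beta$, $c_l = 1/L$, with
  $SE = \sqrt{c^\top \widehat{Cov}(\hat\beta)\, c}$ — the correction used
  when one stratum (aquatic species) dominates the data. General contrasts
  use the same machinery.

## Publication bias and sensitivity

All refits go through the same REML path as the main model; there are no
shortcut estimators. The suite covers: meta-regression of dARR on its SE
(Egger-style; the variance moderator is also offered), on mean-centered
publication year (time-lag/decline effect), a published-vs-thesis
cell-means comparison with contrast, leave-one-study-out and
leave-one-species-out refits (the shared-treatment VCV is rebuilt per
subset), subset refits (initial/persistent timing, excluding imputed
variances, excluding risk-of-bias-flagged rows, and dARR cutoffs such as
$\ge -0.15$), and funnel data export (per-effect residual vs sampling SE).
Year centering uses the grand mean over effects so the intercept stays
interpretable. Risk-of-bias is honored as a boolean input column; the
editorial criteria behind it are outside the package.

## The synthetic world

`sim_truth()` fixes a generative world whose defaults mirror the reported
one: overall dARR $\beta_0 = 0.19$; variance components
$\sigma^2_{phylo} = 0.027$, $\sigma^2_{species} = 0.010$, $\sigma^2_{obs} =
0.066$, back-solved from the published heterogeneity split (26.1 / 10.0 /
63.4 percent of a 99.5% total) and prediction-interval width; a −0.15
terrestrial habitat offset (aquatic 0.209 vs terrestrial 0.060); 85.7%
aquatic effects; 20% persistent-timing studies; 10% missing sds; 5% se-only
rows; 5% TDT studies; 10% shared cohorts; 2–4 developmental temperatures
2–5 °C apart starting from 15–25 °C; group sizes 5–30; individual sds
0.5–2 °C. Group summaries are drawn from the exact sampling laws —
means $\sim N(\mu, sd^2/n)$ and sds $\sim sd\sqrt{\chi^2_{n-1}/(n-1)}$ — so
derived sampling variances are correctly calibrated, which the test suite
checks as a moment identity. Publication bias is induced, when needed, by
significance censoring (non-significant effects survive with a set
probability) rather than an SE-linked mean shift.

What the generator does **not** emulate: real taxonomic imbalance beyond
per-species study counts, digitization error, correlated moderators,
non-normal individual data, or any dependence of reporting on effect
direction. A green test on this world therefore establishes that the
*machinery* is correct and calibrated under the stated model — not that the
model is adequate for any particular real dataset.

For calibration experiments specifically (CI coverage and bias of
$\hat\beta_0$), the world sets the habitat offset and year slope to zero:
with a nonzero offset the intercept-only estimand is the habitat-weighted
mean, not $\beta_0$, and "coverage of $\beta_0$" would be ill-posed. Cohort
pairing is simulated with independent group means; the Eq-style paired
variance is therefore conservative bookkeeping on the analysis side, as in
real use where the true repeat-measurement correlation is unknown.

## Known limitations

* **Small-sample undercoverage of the fixed-effect CI.** The acceptance
  suite's calibration experiment (intercept-only fits on k ≈ 200 effects
  from 40 species) measures ~0.86 empirical coverage for the nominal 95%
  interval, with essentially zero bias and mean SE matching the empirical
  spread of $\hat\beta_0$ to within 1%. The misses concentrate in
  replicates where REML drives $\sigma^2_{phylo}$ (or $\sigma^2_{species}$)
  to zero — a weakly identified split at 40 species — collapsing the
  plug-in SE; we verified on such replicates that the optimum is the true
  restricted-likelihood optimum, not an optimizer failure. This is the
  documented behaviour of plug-in t-based Wald intervals in phylogenetic
  multilevel models with $df = k - p$; Kenward–Roger-type corrections,
  cluster-based df rules, and profile-likelihood intervals would mitigate
  it but are out of scope here.
* The TDT-derived SE is a delta-method approximation from few points; its
  downstream influence is limited because observation-level heterogeneity
  dominates sampling variance.
* AIC comparisons are REML-based and valid only across identical
  fixed-effect designs; the functions enforce this rather than warn.
* No robust (cluster-sandwich) variance estimators, no selection-model bias
  corrections, no Bayesian fitting.
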