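# darrmeta

Multilevel phylogenetic meta-analysis of developmental plasticity in
ectotherm heat tolerance.

Experiments that rear ectotherms at different embryonic or juvenile
temperatures and then assay heat tolerance (CTmax, LT50, or static
knockdown assays) ask whether early thermal environments program later heat
tolerance. Synthesizing them is awkward: treatments differ in spacing,
dispersion is inconsistently reported, multi-temperature designs re-use
control groups, repeated measures share cohorts, and species share
evolutionary history. `darrmeta` is for meta-analysts in thermal ecology
and ecophysiology who need that whole chain as tested, reusable code.

## What it computes

The effect size is the developmental acclimation response ratio

    dARR = (HT_T2 - HT_T1) / (T2 - T1),

the change in heat tolerance (°C) per degree of developmental warming, with
sampling variance derived from group summaries: for independent groups
`(sd1²/n1 + sd2²/n2)/(T2-T1)²` (or the se form), and for shared cohorts
`(sd1² + sd2² - 2r·sd1·sd2)/((n1+n2)(T2-T1)²)` with the conservative
`r = 0.5`. Multi-temperature designs expand into stepwise adjacent
comparisons whose shared treatment groups induce a sampling covariance
`0.5·sqrt(vi·vj)`, assembled into a variance-covariance matrix `V`. Missing
sds are imputed from the pooled within-metric sd/mean ratio; static
thermal-death-time series are inverted (OLS of log10 time on test
temperature) to the temperature tolerable for 1 h.

Effects `y` are then modelled by REML with marginal covariance

    Sigma = s2_phylo · Z A Z' + s2_species · Z Z' + D_obs + V,

where `A` is the Grafen-scaled phylogenetic correlation matrix from a
newick tree (seeded random polytomy resolution) and `D_obs` is a single or
per-moderator-level ("HCS, zero covariance") observation-level variance.
The package provides t-based inference (`df = k - p`), multilevel I²
decomposition, prediction intervals, equal-weight (post-stratified)
marginal means, contrasts, AIC comparison of variance structures, and a
publication-bias/sensitivity suite (Egger-style SE and variance
meta-regressions, time-lag regression, thesis-vs-published comparison,
leave-one-study/species-out, subset and dARR-cutoff refits, funnel data).
A synthetic-data generator with known truth makes every stage testable
end to end; the REML fitter is verified against an independent
dense-likelihood optimizer.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a 40-species world anchored to published estimates (true overall
dARR 0.19, heterogeneity split ~26/10/64); stages 2-4 run the full
analysis. From a fresh checkout:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_effect_sizes.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_bias_sensitivity.R
```

Stage 2 and 3 print (seed 1):

```
324 group rows -> 208 effects (0 rejected rows)
sd imputed for 28 rows (pooled CV: 0.0329, 0.0314)
160 effects sit in shared-treatment chains; 25 are paired cohorts

overall dARR = 0.122 [-0.186, 0.430], k = 208
95% PI = [-0.701, 0.946]
I2 total = 95.5% (phylo 45.5%, species 8.2%, residual 41.8%)
habitat cell means: habitataquatic = 0.151, habitatterrestrial = -0.045
equal-weight marginal mean = 0.053 [-0.249, 0.355]
```

Read: this replicate's overall estimate (0.122) is positive but its CI
crosses zero; heterogeneity dominates sampling error (I² 95.5%), with a
large phylogenetic share; weighting habitats equally pulls the mean down
because terrestrial species respond less. Stage 4 prints the bias suite —
e.g. excluding effects below -0.15 raises the estimate from 0.122 to 0.253,
the inflation that motivates keeping negative responses in.

Programmatic use mirrors the scripts:

```r
library(darrmeta)
sim  <- simulate_dataset(sim_truth(), seed = 1)
eff  <- build_effects(sim$groups)$effects
A    <- phylo_correlation(grafen_lengths(resolve_polytomies(sim$tree, 1)))
fit  <- darr_meta(eff, A = A, fixed = ~1)        # overall model
i2_decomposition(fit); prediction_interval(fit)
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package — simulate, build effect sizes with imputation,
assemble the phylogenetic and sampling covariance structures, fit the
intercept-only, habitat, and heteroscedastic models, and run the bias and
sensitivity suite — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.

## Layout

- `R/` — effect sizes, phylogeny/VCV construction, REML core, bias suite,
  synthetic-data generator, IO
- `analysis/` — the numbered workflow drivers (thin; all computation lives
  in `R/`)
- `tests/testthat/` — unit, property, and acceptance tests
- `vignettes/darr-meta-analysis.Rmd` — the methods vignette: model,
  assumptions, parameter choices, what the generator does and does not
  emulate, known limitations
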