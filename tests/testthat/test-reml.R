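test_that("REML recovers the closed-form equal-variance solution", {
  fit <- fit_reml(y = c(0, 1, 2), X = matrix(1, 3), V = diag(0.1, 3),
                  random = "obs")
  # total variance = sample variance of y; sigma2_obs = 1.0 - 0.1
  expect_equal(unname(fit$sigma2["obs"]), 0.9, tolerance = 1e-4)
  expect_equal(unname(fit$beta), 1, tolerance = 1e-8)
  expect_equal(unname(fit$se), sqrt(1 / 3), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$df, 2L)
})

test_that("structured REML matches an independent dense-likelihood optimizer", {
  for (s in c(31, 32)) {
    d <- make_small_dataset(seed = s)
    eff <- d$effects[seq_len(min(25, nrow(d$effects))), ]
    A <- d$A
    sp <- match_species_to_tips(eff$species, list(tip.label = rownames(A)))
    X <- matrix(1, nrow(eff))
    V <- build_sampling_vcv(eff, r_shared = 0.5)
    fit <- fit_reml(y = eff$darr, X = X, V = V, species = sp, A = A,
                    control = reml_control(reltol = 1e-12, maxit = 5000))

    # dense oracle: same parameter space, textbook matrix likelihood,
    # generic optimizer
    ZAZ <- A[sp, sp]
    ZZ <- outer(sp, sp, "==") * 1
    neg <- function(lpar) -dense_remll(exp(lpar), eff$darr, X, V, ZAZ, ZZ)
    best <- Inf
    for (st in list(log(c(0.05, 0.05, 0.05)), log(c(0.2, 0.01, 0.1)),
                    log(c(0.01, 0.2, 0.02)))) {
      o <- optim(st, neg, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))
      if (o$value < best) { best <- o$value; opt <- o }
    }
    ll_oracle <- -best
    expect_equal(fit$loglik, ll_oracle, tolerance = 1e-6)

    s2 <- exp(opt$par)
    Sigma <- V + s2[1] * ZAZ + s2[2] * ZZ + s2[3] * diag(nrow(eff))
    Si <- solve(Sigma)
    beta_oracle <- drop(solve(t(X) %*% Si %*% X, t(X) %*% Si %*% eff$darr))
    expect_equal(unname(fit$beta), beta_oracle, tolerance = 1e-5)
  }
})

test_that("with no random components the fit is the V-weighted GLS estimate", {
  d <- make_small_dataset(seed = 55)
  eff <- d$effects[1:15, ]
  V <- build_sampling_vcv(eff, r_shared = 0.5)
  X <- matrix(1, nrow(eff))
  fit <- fit_reml(y = eff$darr, X = X, V = V, random = character(0))
  Vi <- solve(V)
  beta_gls <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% eff$darr))
  expect_equal(unname(fit$beta), beta_gls, tolerance = 1e-10)
  expect_length(fit$sigma2, 0L)
})

test_that("t-based inference follows the k - p rule", {
  fit <- fit_reml(y = c(0, 1, 2), X = matrix(1, 3), V = diag(0.1, 3),
                  random = "obs")
  tab <- t_inference(fit)
  expect_equal(tab$df, 2L)
  expect_equal(tab$t, 1.732, tolerance = 1e-3)
  expect_equal(tab$ci_lb, tab$estimate - qt(0.975, 2) * tab$se,
               tolerance = 1e-12)

  # CI endpoints against the t-quantile for random df/se combinations
  set.seed(77)
  for (i in 1:10) {
    lv <- runif(1, 0.5, 0.99)
    tabl <- t_inference(fit, level = lv)
    q <- qt(1 - (1 - lv) / 2, df = fit$df)
    expect_equal(tabl$ci_ub - tabl$ci_lb, 2 * q * tabl$se, tolerance = 1e-8)
  }
})

test_that("prediction intervals widen the CI by total heterogeneity", {
  fit <- fit_reml(y = c(0, 1, 2), X = matrix(1, 3), V = diag(0.1, 3),
                  random = "obs")
  pi <- prediction_interval(fit)
  halfwidth <- qt(0.975, 2) * sqrt(fit$se^2 + fit$sigma2[["obs"]])
  expect_equal(unname(pi$pi_ub - pi$estimate), unname(halfwidth),
               tolerance = 1e-8)
  # numeric value of the toy case: 4.303 * sqrt(1.2333) ~ 4.779
  expect_equal(unname(pi$pi_ub - pi$estimate), 4.779, tolerance = 1e-2)

  # PI contains the CI always; equals it when heterogeneity is zero
  ci <- t_inference(fit)
  expect_lte(pi$pi_lb, ci$ci_lb)
  expect_gte(pi$pi_ub, ci$ci_ub)

  d <- make_small_dataset(seed = 60)
  g <- fit_reml(y = d$effects$darr[1:12], X = matrix(1, 12),
                V = build_sampling_vcv(d$effects[1:12, ]),
                random = character(0))
  pig <- prediction_interval(g)
  cig <- t_inference(g)
  expect_equal(pig$pi_lb, cig$ci_lb, tolerance = 1e-12)
  expect_equal(pig$pi_ub, cig$ci_ub, tolerance = 1e-12)
})

test_that("I2 components share a denominator and behave in limits", {
  fit <- fit_reml(y = c(0, 1, 2), X = matrix(1, 3), V = diag(0.1, 3),
                  random = "obs")
  i2 <- i2_decomposition(fit)
  expect_equal(i2$s2_typical, 0.1, tolerance = 1e-10)
  expect_equal(i2$i2_total, 90, tolerance = 1e-2)
  expect_equal(i2$i2_obs, i2$i2_total)

  # components sum exactly to the total on a full multilevel fit
  d <- make_small_dataset(seed = 70)
  full <- darr_meta(d$effects, A = d$A, fixed = ~1)
  i2f <- i2_decomposition(full)
  comps <- unlist(i2f[setdiff(grep("^i2_", names(i2f), value = TRUE),
                              "i2_total")])
  expect_equal(sum(comps), i2f$i2_total, tolerance = 1e-12)

  # sampling error -> 0 pushes I2 to 100%
  tiny <- fit_reml(y = c(0, 1, 2), X = matrix(1, 3), V = diag(1e-8, 3),
                   random = "obs")
  expect_gt(i2_decomposition(tiny)$i2_total, 99.9)

  # invariance under common rescaling of all variances
  c2 <- 4
  scaled <- fit_reml(y = c(0, 1, 2) * 2, X = matrix(1, 3),
                     V = diag(0.1 * c2, 3), random = "obs")
  expect_equal(i2_decomposition(scaled)$i2_total, i2$i2_total,
               tolerance = 1e-3)

  expect_error(i2_decomposition(fit, v = c(0.1, 0, 0.1)), "positive")
})

test_that("marginal means and contrasts do the stated linear algebra", {
  # toy arithmetic on the two-habitat configuration: levels 0.209 / 0.060
  # with diagonal covariance 0.01 / 0.04
  fake <- structure(list(
    beta = c(aquatic = 0.209, terrestrial = 0.060),
    vcov_beta = diag(c(0.01, 0.04)),
    se = sqrt(c(0.01, 0.04)), df = 100L, p = 2L, k = 102L,
    sigma2 = c(obs = 0), obs_level = NULL
  ), class = "darr_fit")
  mm <- marginal_means(fake)
  expect_equal(mm$estimate, 0.1345)
  expect_equal(mm$se, sqrt(0.0125), tolerance = 1e-10)

  ct <- contrast_estimate(fake, c(1, -1))
  expect_equal(ct$estimate, 0.149)
  expect_equal(ct$se, sqrt(0.05), tolerance = 1e-10)

  # e_i reproduces the coefficient's own inference
  ct1 <- contrast_estimate(fake, c(1, 0))
  expect_equal(ct1$estimate, 0.209)
  expect_equal(ct1$se, 0.1)
  # a level against itself is exactly zero with zero SE
  ct0 <- contrast_estimate(fake, c(0, 0))
  expect_equal(ct0$estimate, 0)
  expect_equal(ct0$se, 0)
  expect_error(contrast_estimate(fake, c(1, -1, 0)), "conformable")

  # equal weights with equal level estimates return the common value
  fake$beta[] <- c(0.1, 0.1)
  expect_equal(marginal_means(fake)$estimate, 0.1)

  # single-level model: the marginal mean is that level
  one <- structure(list(beta = c(lvl = 0.3), vcov_beta = matrix(0.02),
                        se = sqrt(0.02), df = 10L, p = 1L, k = 11L,
                        sigma2 = c(obs = 0), obs_level = NULL),
                   class = "darr_fit")
  expect_equal(marginal_means(one)$estimate, 0.3)
})

test_that("cell-means fit on real structure: marginal mean lies between cells", {
  d <- make_small_dataset(seed = 88,
                          truth = sim_truth(n_species = 10,
                                            prop_aquatic = 0.6,
                                            frac_tdt = 0, frac_missing_sd = 0,
                                            frac_se_only = 0))
  if (length(unique(d$effects$habitat)) == 2L) {
    fit <- darr_meta(d$effects, A = d$A, fixed = ~ 0 + habitat)
    mm <- marginal_means(fit)
    expect_gte(mm$estimate, min(fit$beta) - 1e-10)
    expect_lte(mm$estimate, max(fit$beta) + 1e-10)
    expect_equal(mm$estimate, mean(fit$beta), tolerance = 1e-10)
    # PI at least as wide as CI
    expect_lte(mm$pi_lb, mm$ci_lb)
  }
})

test_that("AIC comparison enforces identical fixed effects and nesting works", {
  d <- make_small_dataset(seed = 91)
  eff <- d$effects
  homo <- darr_meta(eff, A = d$A, fixed = ~1)
  het <- darr_meta(eff, A = d$A, fixed = ~1, residual_by = "timing")
  expect_error(aic_compare(homo = homo,
                           mod = darr_meta(eff, A = d$A, fixed = ~ 0 + timing)),
               "not comparable")
  if (length(unique(eff$timing)) == 2L) {
    tab <- aic_compare(homo = homo, het = het)
    expect_equal(nrow(tab), 2L)
    expect_equal(min(tab$delta_aic), 0)
    # the richer variance structure can only raise the restricted loglik
    expect_gte(het$loglik, homo$loglik - 1e-6)
    expect_equal(tab["homo", "q"], 3)
    expect_equal(tab["het", "q"], 4)
  }
  # identical models tie
  tab2 <- aic_compare(a = homo, b = homo)
  expect_equal(tab2$delta_aic, c(0, 0))
})

test_that("heteroscedastic fits prefer the true structure under strong inequality", {
  # strongly unequal level variances: the heteroscedastic model should win
  # the AIC comparison in nearly all replicates (scaled-down replicate count)
  wins <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    truth <- sim_truth(n_species = 12, studies_per_species = 1:2,
                       sigma2_obs = c(initial = 0.01, persistent = 0.36),
                       obs_level_by = "timing", frac_persistent = 0.5,
                       frac_tdt = 0, frac_missing_sd = 0, frac_se_only = 0)
    sim <- simulate_dataset(truth, seed = 4000 + s)
    eff <- build_effects(sim$groups)$effects
    if (length(unique(eff$timing)) < 2L) next
    homo <- darr_meta(eff, A = sim$A, fixed = ~1)
    het <- darr_meta(eff, A = sim$A, fixed = ~1, residual_by = "timing")
    if (het$aic < homo$aic) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("heteroscedastic fit with equal true level variances stays balanced", {
  # equal-variance truth at k ~ 300: per-level estimates should diverge by
  # less than 2x in >= 90% of replicates (replicate count scaled down)
  ok <- 0L; n_rep <- 12L
  for (s in seq_len(n_rep)) {
    truth <- sim_truth(n_species = 40, studies_per_species = 3:4,
                       p_temps = c(0.3, 0.4, 0.3),
                       sigma2_obs = c(initial = 0.08, persistent = 0.08),
                       obs_level_by = "timing", frac_persistent = 0.5,
                       frac_tdt = 0, frac_missing_sd = 0, frac_se_only = 0)
    sim <- simulate_dataset(truth, seed = 5000 + s)
    eff <- build_effects(sim$groups)$effects
    het <- darr_meta(eff, A = sim$A, fixed = ~1, residual_by = "timing")
    s2 <- het$sigma2[grep("^obs\\.", names(het$sigma2))]
    if (max(s2) / max(min(s2), 1e-8) < 2) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("rank-deficient designs and df exhaustion are refused", {
  d <- make_small_dataset(seed = 95)
  eff <- d$effects[1:10, ]
  expect_error(fit_reml(y = eff$darr[1:5], X = matrix(rep(1, 10), 5, 2),
                        V = diag(0.01, 5), random = "obs"),
               "rank deficient")
  expect_error(fit_reml(y = c(0, 1), X = diag(2), V = diag(0.1, 2),
                        random = "obs"),
               "more effects than")
})
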