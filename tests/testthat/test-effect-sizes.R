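test_that("dARR and its sampling variances reproduce the worked values", {
  g20 <- make_group(20, 38.0, sd = 1, n = 10)
  g25 <- make_group(25, 41.0, sd = 1, n = 10)
  expect_equal(compute_darr(g20, g25), 0.6)

  # no response across a 10-degree span
  expect_equal(compute_darr(make_group(18, 36.2), make_group(28, 36.2)), 0)

  # order of arguments is irrelevant: groups are sorted internally
  expect_equal(compute_darr(g25, g20), compute_darr(g20, g25))

  expect_equal(as.numeric(darr_variance_independent(g20, g25)), 0.008)
  expect_equal(
    as.numeric(darr_variance_independent(
      make_group(20, 38, se = 0.3), make_group(25, 41, se = 0.4))),
    0.010)

  c1 <- make_group(20, 38, sd = 1, n = 10, cohort_id = "c")
  c2 <- make_group(25, 41, sd = 1, n = 10, cohort_id = "c")
  expect_equal(as.numeric(darr_variance_shared_cohort(c1, c2, r = 0.5)),
               0.002)
  expect_equal(
    as.numeric(darr_variance_shared_cohort(
      make_group(20, 38, se = 0.3, cohort_id = "c"),
      make_group(25, 41, se = 0.3, cohort_id = "c"), r = 0.5)),
    0.0036)
})

test_that("sd- and se-based variances agree when se = sd/sqrt(n)", {
  set.seed(11)
  for (i in 1:20) {
    sd1 <- runif(1, 0.2, 3); sd2 <- runif(1, 0.2, 3)
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    t1 <- runif(1, 10, 20); t2 <- t1 + runif(1, 1, 10)
    v_sd <- darr_variance_independent(
      make_group(t1, 38, sd = sd1, n = n1), make_group(t2, 40, sd = sd2, n = n2))
    v_se <- darr_variance_independent(
      make_group(t1, 38, se = sd1 / sqrt(n1)),
      make_group(t2, 40, se = sd2 / sqrt(n2)))
    expect_equal(as.numeric(v_sd), as.numeric(v_se), tolerance = 1e-12)
  }
})

test_that("variance formulas behave as required over random inputs", {
  set.seed(42)
  for (i in 1:30) {
    sd1 <- runif(1, 0.1, 3); sd2 <- runif(1, 0.1, 3)
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    t1 <- runif(1, 5, 30); dt <- runif(1, 0.5, 12); t2 <- t1 + dt
    r <- runif(1, 0.05, 0.95)
    gi1 <- make_group(t1, 37, sd = sd1, n = n1)
    gi2 <- make_group(t2, 39, sd = sd2, n = n2)
    v <- as.numeric(darr_variance_independent(gi1, gi2))
    expect_gt(v, 0)
    # v scales as (delta T)^-2
    gi2b <- make_group(t1 + 2 * dt, 39, sd = sd2, n = n2)
    expect_equal(as.numeric(darr_variance_independent(gi1, gi2b)) * 4, v,
                 tolerance = 1e-12)
    # dARR invariant under jointly swapping the groups
    expect_equal(compute_darr(gi1, gi2), compute_darr(gi2, gi1))
    # paired correction is conservative: Eq 4 <= Eq 2 for same sd, n, r > 0
    gc1 <- make_group(t1, 37, sd = sd1, n = n1, cohort_id = "c")
    gc2 <- make_group(t2, 39, sd = sd2, n = n1, cohort_id = "c")
    v_ind <- as.numeric(darr_variance_independent(
      make_group(t1, 37, sd = sd1, n = n1),
      make_group(t2, 39, sd = sd2, n = n1)))
    v_coh <- as.numeric(darr_variance_shared_cohort(gc1, gc2, r = r))
    expect_lte(v_coh, v_ind + 1e-12)
  }
})

test_that("cohort variance limits: r = 0 gives the independent-error sum, r -> 1 kills it", {
  g1 <- make_group(20, 38, se = 0.3, cohort_id = "c")
  g2 <- make_group(25, 41, se = 0.3, cohort_id = "c")
  expect_equal(as.numeric(darr_variance_shared_cohort(g1, g2, r = 0)),
               (0.09 + 0.09) / 25)
  expect_lt(as.numeric(darr_variance_shared_cohort(g1, g2, r = 0.999)),
            1e-4)
  expect_error(darr_variance_shared_cohort(g1, g2, r = 1), "\\[0, 1\\)")
  expect_error(darr_variance_shared_cohort(g1, g2, r = -0.1), "\\[0, 1\\)")
})

test_that("degenerate and mismatched comparisons are rejected", {
  expect_error(compute_darr(make_group(20, 38), make_group(20.05, 38.2)),
               "degenerate")
  expect_error(compute_darr(make_group(20, 38, study_id = "a"),
                            make_group(25, 40, study_id = "b")),
               "study_id")
  expect_error(darr_variance_independent(make_group(20, 38),
                                         make_group(25, 40)),
               "unusable")
})

test_that("stepwise expansion emits adjacent comparisons with shared-group bookkeeping", {
  b3 <- make_block(c(20, 25, 27))
  e3 <- stepwise_effects(b3)
  expect_equal(nrow(e3), 2L)
  expect_equal(e3$t1, c(20, 25))
  expect_equal(e3$t2, c(25, 27))
  # the 25-degree group is shared: both effects carry the same non-NA id
  expect_false(anyNA(e3$shared_group_id))
  expect_equal(length(unique(e3$shared_group_id)), 1L)
  expect_true(e3$group_id_hi[1] == e3$group_id_lo[2])

  e2 <- stepwise_effects(make_block(c(18, 28)))
  expect_equal(nrow(e2), 1L)
  expect_true(is.na(e2$shared_group_id))

  e4 <- stepwise_effects(make_block(c(20, 22, 25, 27)))
  expect_equal(nrow(e4), 3L)
  ids <- c(e4$group_id_lo, e4$group_id_hi)
  counts <- table(ids)
  # middle groups (22, 25) each referenced exactly twice, extremes once
  expect_equal(sort(as.numeric(counts)), c(1, 1, 2, 2))

  expect_error(stepwise_effects(make_block(25)), "fewer than 2")
  expect_error(stepwise_effects(make_block(c(20, 20.05))), "duplicated")
})

test_that("stepwise effect count is always one less than the temperature count", {
  set.seed(5)
  for (i in 1:15) {
    kt <- sample(2:6, 1)
    temps <- sort(10 + cumsum(runif(kt, 0.5, 6)))
    eff <- stepwise_effects(make_block(temps))
    expect_equal(nrow(eff), kt - 1L)
    counts <- table(c(eff$group_id_lo, eff$group_id_hi))
    if (kt > 2) expect_equal(sum(counts == 2), kt - 2L)
    # variances routed through cohort formula when a cohort is declared
    eff_c <- stepwise_effects(make_block(temps, cohort_id = "coh1"))
    expect_true(all(eff_c$cohort_pairing))
    expect_true(all(eff_c$variance <= eff$variance + 1e-12))
  }
})

test_that("sd imputation pools the CV, respects se-only rows, and is idempotent", {
  rows <- data.frame(
    study_id = "s1", species = "x", metric = "ctmax",
    mean_ht = c(40, 50, 50, 50, 30),
    sd = c(0.05 * 40, 0.07 * 50, 0.06 * 50, NA, NA),
    se = c(NA, NA, NA, NA, 0.4),
    n = c(10, 10, 10, 12, NA), stringsAsFactors = FALSE
  )
  res <- impute_missing_sd(rows)
  expect_equal(res$summary$pooled_cv, 0.06)
  expect_equal(res$summary$k_complete, 3L)
  expect_equal(res$summary$imputed_row_ids, 4L)
  expect_equal(res$rows$sd[4], 3.0)
  expect_true(res$rows$sd_imputed[4])
  # se-only row untouched, still usable via the se formula
  expect_true(is.na(res$rows$sd[5]))
  expect_false(res$rows$unusable[5])

  # idempotence: a second pass changes nothing
  res2 <- impute_missing_sd(res$rows)
  expect_equal(res2$rows$sd, res$rows$sd)
  expect_equal(res2$summary$pooled_cv, res$summary$pooled_cv)
  expect_length(res2$summary$imputed_row_ids, 0L)

  # all-complete input is a no-op
  res3 <- impute_missing_sd(rows[1:3, ])
  expect_length(res3$summary$imputed_row_ids, 0L)
  expect_equal(res3$rows$sd, rows$sd[1:3])

  expect_error(impute_missing_sd(data.frame(mean_ht = 50, sd = NA, n = 10,
                                            metric = "ctmax")),
               "impossible")
})

test_that("imputation pools per metric by default", {
  rows <- data.frame(
    mean_ht = c(40, 40, 20, 20), sd = c(2, NA, 4, NA),
    se = NA_real_, n = 10,
    metric = c("ctmax", "ctmax", "lt50", "lt50"), stringsAsFactors = FALSE
  )
  res <- impute_missing_sd(rows)
  expect_equal(res$rows$sd[2], 0.05 * 40)  # ctmax cv = 2/40
  expect_equal(res$rows$sd[4], 0.20 * 20)  # lt50 cv = 4/20
  glob <- impute_missing_sd(rows, by_metric = FALSE)
  expect_equal(glob$rows$sd[2], mean(c(0.05, 0.2)) * 40)
})

test_that("TDT series invert to the 1-h tolerated temperature", {
  ser <- data.frame(test_temperature = c(40, 42, 44),
                    time_hours = c(10, 1, 0.1))
  out <- tdt_to_heat_tolerance(ser)
  expect_equal(out$mean_ht, 42.0, tolerance = 1e-10)
  expect_equal(out$metric, "tdt_derived")
  expect_false(out$extrapolated)

  # doubling all times shifts T* by +log10(2)/0.5, slope unchanged
  out2 <- tdt_to_heat_tolerance(transform(ser, time_hours = 2 * time_hours))
  expect_equal(out2$mean_ht - out$mean_ht, log10(2) / 0.5, tolerance = 1e-10)

  expect_error(tdt_to_heat_tolerance(
    data.frame(test_temperature = c(40, 42, 44), time_hours = c(0.1, 1, 10))),
    "implausible")
  expect_error(tdt_to_heat_tolerance(
    data.frame(test_temperature = c(40, 40, 40), time_hours = c(3, 2, 1))),
    "distinct")
  expect_error(tdt_to_heat_tolerance(
    data.frame(test_temperature = c(40, 42), time_hours = c(2, 1))),
    ">= 3 points")
})

test_that("TDT regression matches a brute-force normal-equations oracle", {
  set.seed(99)
  a_true <- 21; b_true <- -0.5
  temps <- seq(39, 44.5, length.out = 12)
  logt <- a_true + b_true * temps + rnorm(12, 0, 0.1)
  ser <- data.frame(test_temperature = temps, time_hours = 10^logt)
  out <- tdt_to_heat_tolerance(ser)

  # normal equations computed by hand
  Xm <- cbind(1, temps)
  coefs <- solve(t(Xm) %*% Xm, t(Xm) %*% logt)
  expect_equal(out$mean_ht, -coefs[1] / coefs[2], tolerance = 1e-10)
  # estimate close to the true 1-h temperature
  expect_lt(abs(out$mean_ht - (-a_true / b_true)), 2 * out$se + 0.2)
})

test_that("extrapolated TDT estimates warn", {
  ser <- data.frame(test_temperature = c(44, 45, 46),
                    time_hours = c(0.5, 0.25, 0.12))
  expect_warning(tdt_to_heat_tolerance(ser), "outside the tested range")
})

test_that("build_effects routes rejects with machine-readable reasons", {
  ok <- make_block(c(20, 25), study_id = "s1")
  lone <- make_block(22, study_id = "s2")
  bad <- make_block(c(20, 25), study_id = "s3")
  bad$sd <- NA_real_; bad$n <- NA_real_  # nothing to build a variance from
  groups <- rbind(ok, lone, bad)
  groups$.group_id <- seq_len(nrow(groups))
  res <- build_effects(groups, impute = FALSE)
  expect_equal(nrow(res$effects), 1L)
  expect_setequal(res$rejects$reason[res$rejects$.group_id %in% 3],
                  "single_temperature_block")
  expect_true(all(res$rejects$.group_id[res$rejects$reason ==
                                          "no_variance_information"] %in% 4:5))
})
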