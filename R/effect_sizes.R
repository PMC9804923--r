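#' Developmental acclimation response ratio (dARR) between two groups
#'
#' The dARR is the change in heat tolerance (in degrees C) per degree C change
#' in developmental temperature:
#' \deqn{dARR = (HT_2 - HT_1) / (T_2 - T_1)}
#' where the two groups are internally ordered so that `T2 > T1`. A dARR of
#' 0.6 means each degree of developmental warming raises heat tolerance by
#' 0.6 degrees C; a dARR of 1 would be perfect compensation.
#'
#' @param g1,g2 Group summaries: lists or one-row data frames with at least
#'   `temperature` and `mean_ht`, and matching `study_id`, `species` and
#'   `metric` when those fields are present.
#' @return The dARR value (numeric scalar).
#' @export
compute_darr <- function(g1, g2) {
  g1 <- as_group(g1)
  g2 <- as_group(g2)
  check_same_block(g1, g2)
  if (abs(g2$temperature - g1$temperature) < MIN_DELTA_T) {
    stop("degenerate comparison: developmental temperatures differ by < ",
         MIN_DELTA_T, " degrees C", call. = FALSE)
  }
  if (g2$temperature < g1$temperature) {
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  (g2$mean_ht - g1$mean_ht) / (g2$temperature - g1$temperature)
}

# temperatures closer than this are treated as duplicated digitizations
MIN_DELTA_T <- 0.1

as_group <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(nrow(g) == 1L)
    g <- as.list(g)
  }
  stopifnot(is.list(g), !is.null(g$temperature), !is.null(g$mean_ht))
  if (!is.finite(g$temperature) || !is.finite(g$mean_ht)) {
    stop("temperature and mean_ht must be finite", call. = FALSE)
  }
  g
}

check_same_block <- function(g1, g2) {
  for (f in c("study_id", "species", "metric")) {
    a <- g1[[f]]; b <- g2[[f]]
    if (!is.null(a) && !is.null(b) && !is.na(a) && !is.na(b) && a != b) {
      stop("cannot pair groups across different ", f,
           " ('", a, "' vs '", b, "')", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Sampling variance of dARR for independent groups
#'
#' Different animals in the two temperature treatments. With standard
#' deviations and sample sizes:
#' \deqn{s^2(dARR) = (T_2 - T_1)^{-2} (sd_1^2/n_1 + sd_2^2/n_2)}
#' With standard errors only:
#' \deqn{s^2(dARR) = (T_2 - T_1)^{-2} (se_1^2 + se_2^2)}
#' When one group reports sd and n and the other only se, the sd-based group
#' is converted to its standard error (`se = sd/sqrt(n)`) and the se form is
#' used, which keeps the pair rather than dropping it.
#'
#' @inheritParams compute_darr
#' @return Sampling variance (numeric scalar) with attribute `basis`, one of
#'   `"sd"`, `"se"`, `"imputed_sd"`.
#' @export
darr_variance_independent <- function(g1, g2) {
  g1 <- as_group(g1); g2 <- as_group(g2)
  dt2 <- (g2$temperature - g1$temperature)^2
  if (dt2 < MIN_DELTA_T^2) {
    stop("degenerate comparison: equal temperatures", call. = FALSE)
  }
  has_sd <- function(g) !is.null(g$sd) && !is.na(g$sd) &&
    !is.null(g$n) && !is.na(g$n)
  has_se <- function(g) !is.null(g$se) && !is.na(g$se)
  check_dispersion(g1); check_dispersion(g2)
  if (has_sd(g1) && has_sd(g2)) {
    v <- (g1$sd^2 / g1$n + g2$sd^2 / g2$n) / dt2
    basis <- if (isTRUE(g1$sd_imputed) || isTRUE(g2$sd_imputed)) "imputed_sd" else "sd"
  } else if (has_se(g1) || has_se(g2)) {
    se1 <- if (has_se(g1)) g1$se else if (has_sd(g1)) g1$sd / sqrt(g1$n) else NA_real_
    se2 <- if (has_se(g2)) g2$se else if (has_sd(g2)) g2$sd / sqrt(g2$n) else NA_real_
    if (is.na(se1) || is.na(se2)) {
      stop("unusable rows: need sd+n or se for both groups", call. = FALSE)
    }
    v <- (se1^2 + se2^2) / dt2
    basis <- if (isTRUE(g1$sd_imputed) || isTRUE(g2$sd_imputed)) "imputed_sd" else "se"
  } else {
    stop("unusable rows: need sd+n or se for both groups", call. = FALSE)
  }
  structure(v, basis = basis)
}

check_dispersion <- function(g) {
  if (!is.null(g$sd) && !is.na(g$sd) && g$sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.null(g$se) && !is.na(g$se) && g$se < 0) stop("se must be >= 0", call. = FALSE)
  if (!is.null(g$n) && !is.na(g$n) && g$n < 1) stop("n must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Sampling variance of dARR for a shared cohort
#'
#' The same animals measured at both developmental temperatures (repeated
#' measures). The within-cohort correlation `r` reduces the variance:
#' \deqn{s^2(dARR) = (T_2 - T_1)^{-2} (sd_1^2 + sd_2^2 - 2 r\, sd_1 sd_2)/(n_1 + n_2)}
#' or, with standard errors,
#' \deqn{s^2(dARR) = (T_2 - T_1)^{-2} (se_1^2 + se_2^2 - 2 r\, se_1 se_2).}
#' The default `r = 0.5` is a deliberately conservative guess at the
#' repeat-measurement correlation.
#'
#' @inheritParams compute_darr
#' @param r Within-cohort correlation, in `[0, 1)`. Default 0.5.
#' @return Sampling variance with attribute `basis` as in
#'   [darr_variance_independent()].
#' @export
darr_variance_shared_cohort <- function(g1, g2, r = 0.5) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r >= 1) {
    stop("r must be a single value in [0, 1)", call. = FALSE)
  }
  g1 <- as_group(g1); g2 <- as_group(g2)
  dt2 <- (g2$temperature - g1$temperature)^2
  if (dt2 < MIN_DELTA_T^2) {
    stop("degenerate comparison: equal temperatures", call. = FALSE)
  }
  has_sd <- function(g) !is.null(g$sd) && !is.na(g$sd) &&
    !is.null(g$n) && !is.na(g$n)
  has_se <- function(g) !is.null(g$se) && !is.na(g$se)
  check_dispersion(g1); check_dispersion(g2)
  imput <- isTRUE(g1$sd_imputed) || isTRUE(g2$sd_imputed)
  if (has_sd(g1) && has_sd(g2)) {
    v <- (g1$sd^2 + g2$sd^2 - 2 * r * g1$sd * g2$sd) / (g1$n + g2$n) / dt2
    basis <- if (imput) "imputed_sd" else "sd"
  } else if (has_se(g1) || has_se(g2)) {
    # mixed availability: convert sd,n to se and use the se form
    se1 <- if (has_se(g1)) g1$se else if (has_sd(g1)) g1$sd / sqrt(g1$n) else NA_real_
    se2 <- if (has_se(g2)) g2$se else if (has_sd(g2)) g2$sd / sqrt(g2$n) else NA_real_
    if (is.na(se1) || is.na(se2)) {
      stop("shared-cohort variance needs sd+n or se for both groups",
           call. = FALSE)
    }
    v <- (se1^2 + se2^2 - 2 * r * se1 * se2) / dt2
    basis <- if (imput) "imputed_sd" else "se"
  } else {
    stop("shared-cohort variance needs sd+n or se for both groups",
         call. = FALSE)
  }
  structure(v, basis = basis)
}

#' Stepwise dARR effect sizes from a multi-temperature design
#'
#' For one study/species/metric/timing block with k distinct developmental
#' temperatures, effects are computed for each adjacent pair after sorting
#' temperatures ascending (e.g. 20-22, 22-25, 25-27 degrees C), yielding k-1
#' effects. Interior temperature groups enter two comparisons; such effects
#' get a common non-NA `shared_group_id` so the shared-treatment sampling
#' covariance can be reconstructed later, and the constituent group ids are
#' carried in `group_id_lo` / `group_id_hi`.
#'
#' Variance is routed automatically: pairs with a common non-missing
#' `cohort_id` use the shared-cohort formulas with correlation `r_cohort`;
#' all other pairs are treated as independent.
#'
#' @param groups Data frame of group summaries for a single block (same
#'   study, species, metric, timing), one row per developmental temperature.
#'   Must carry a unique `.group_id` column (added by [read_groups()] /
#'   [build_effects()] if absent).
#' @param r_cohort Correlation for shared-cohort pairs (default 0.5).
#' @return Data frame, one row per effect, with `darr`, `variance`,
#'   `variance_basis`, `t1`, `t2`, `cohort_pairing`, `group_id_lo`,
#'   `group_id_hi`, `shared_group_id` plus carried metadata.
#' @export
stepwise_effects <- function(groups, r_cohort = 0.5) {
  stopifnot(is.data.frame(groups))
  if (is.null(groups$.group_id)) groups$.group_id <- seq_len(nrow(groups))
  if (nrow(groups) < 2L) {
    stop("no comparison possible: fewer than 2 distinct temperatures",
         call. = FALSE)
  }
  temps <- sort(groups$temperature)
  if (min(diff(temps)) < MIN_DELTA_T) {
    stop("duplicated developmental temperatures within a block (< ",
         MIN_DELTA_T, " degrees C apart)", call. = FALSE)
  }
  groups <- groups[order(groups$temperature), , drop = FALSE]
  k <- nrow(groups)
  block_id <- paste(groups$study_id[1], groups$species[1],
                    groups$metric[1], groups$timing[1], sep = "|")
  out <- vector("list", k - 1L)
  for (i in seq_len(k - 1L)) {
    g1 <- as.list(groups[i, , drop = FALSE])
    g2 <- as.list(groups[i + 1L, , drop = FALSE])
    paired <- !is.null(g1$cohort_id) && !is.na(g1$cohort_id) &&
      !is.na(g2$cohort_id) && g1$cohort_id == g2$cohort_id
    v <- if (paired) {
      darr_variance_shared_cohort(g1, g2, r = r_cohort)
    } else {
      darr_variance_independent(g1, g2)
    }
    eff <- data.frame(
      study_id = g1$study_id %||% NA_character_,
      species = g1$species %||% NA_character_,
      population_id = g1$population_id %||% NA_character_,
      metric = g1$metric %||% NA_character_,
      design = g1$design %||% NA_character_,
      timing = g1$timing %||% NA_character_,
      habitat = g1$habitat %||% NA_character_,
      taxon_group = g1$taxon_group %||% NA_character_,
      heating_rate = g1$heating_rate %||% NA_real_,
      year = g1$year %||% NA_real_,
      source_type = g1$source_type %||% NA_character_,
      risk_of_bias = g1$risk_of_bias %||% FALSE,
      t1 = g1$temperature,
      t2 = g2$temperature,
      darr = (g2$mean_ht - g1$mean_ht) / (g2$temperature - g1$temperature),
      variance = as.numeric(v),
      variance_basis = attr(v, "basis"),
      cohort_pairing = paired,
      group_id_lo = g1$.group_id,
      group_id_hi = g2$.group_id,
      stringsAsFactors = FALSE
    )
    out[[i]] <- eff
  }
  eff <- do.call(rbind, out)
  # any group appearing in >1 comparison marks the whole chain as shared
  eff$shared_group_id <- if (k > 2L) block_id else NA_character_
  stopifnot(all(eff$variance > 0), all(eff$t2 > eff$t1))
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

col_or <- function(df, name, default) {
  col <- df[[name]]
  if (is.null(col)) rep(default, nrow(df)) else {
    col[is.na(col)] <- default
    col
  }
}

#' Within-study imputation of missing standard deviations
#'
#' Assumes the coefficient of variation (sd / |mean|) is constant across
#' studies, pools it as the arithmetic mean of the ratios over all rows with
#' complete sd and mean, and fills `sd = cv * |mean_ht|` for rows that have a
#' missing sd but a known sample size and nonzero mean. Rows reporting only a
#' standard error are left untouched (an se cannot be back-imputed without
#' n); rows with neither sd+n nor se are flagged unusable. Pooling is per
#' heat-tolerance metric by default, since dynamic (CTmax) and static (LT50)
#' assays have different dispersion scales.
#'
#' @param rows Data frame of group summaries (columns `mean_ht`, `sd`, `se`,
#'   `n`, `metric`, optionally `sd_imputed`).
#' @param by_metric Pool the CV within each `metric` level (default) or
#'   globally.
#' @return List with `rows` (the data frame with imputed sds,
#'   `sd_imputed` flags, and an `unusable` logical column) and `summary`, an
#'   `imputation_summary` with the pooled CV(s), the number of complete rows,
#'   and the imputed row indices.
#' @export
impute_missing_sd <- function(rows, by_metric = TRUE) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (is.null(rows$sd_imputed)) rows$sd_imputed <- FALSE
  rows$sd_imputed[is.na(rows$sd_imputed)] <- FALSE
  if (is.null(rows$se)) rows$se <- NA_real_
  if (is.null(rows$n)) rows$n <- NA_real_
  complete <- !is.na(rows$sd) & !rows$sd_imputed &
    !is.na(rows$mean_ht) & rows$mean_ht != 0
  if (!any(complete)) {
    stop("imputation impossible: no rows with both sd and a nonzero mean",
         call. = FALSE)
  }
  key <- if (by_metric && !is.null(rows$metric)) as.character(rows$metric)
         else rep("all", nrow(rows))
  cv_tab <- tapply(rows$sd[complete] / abs(rows$mean_ht[complete]),
                   key[complete], mean)
  needs <- is.na(rows$sd) & !is.na(rows$n) & !is.na(rows$mean_ht) &
    rows$mean_ht != 0 & key %in% names(cv_tab)
  rows$sd[needs] <- cv_tab[key[needs]] * abs(rows$mean_ht[needs])
  rows$sd_imputed[needs] <- TRUE
  rows$unusable <- (is.na(rows$sd) | is.na(rows$n)) & is.na(rows$se)
  summary <- structure(list(
    pooled_cv = if (length(cv_tab) == 1L) unname(cv_tab[1L]) else cv_tab,
    k_complete = sum(complete),
    imputed_row_ids = which(needs)
  ), class = "imputation_summary")
  stopifnot(all(unlist(summary$pooled_cv) > 0), summary$k_complete >= 1L)
  list(rows = rows, summary = summary)
}

#' @export
print.imputation_summary <- function(x, ...) {
  cat("Within-study sd imputation\n")
  cat("  complete rows pooled:", x$k_complete, "\n")
  cat("  pooled cv:", paste(format(unlist(x$pooled_cv), digits = 4),
                            collapse = ", "), "\n")
  cat("  rows imputed:", length(x$imputed_row_ids), "\n")
  invisible(x)
}

#' Convert a thermal death time series to a 1-h heat tolerance estimate
#'
#' Static heat-knockdown assays report time to death at several constant test
#' temperatures. Time declines log-linearly with temperature (the thermal
#' death time curve), so an ordinary least-squares fit of log10(time, hours)
#' on test temperature can be inverted to the temperature tolerable for
#' exactly 1 hour, `T* = -intercept/slope`, a proxy for CTmax. A standard
#' error for `T*` is attached by the delta method from the OLS coefficient
#' covariance. Extrapolation beyond the tested temperature range is less
#' reliable and triggers a warning.
#'
#' @param series Data frame with columns `test_temperature` (degrees C) and
#'   `time_hours` (> 0); at least 3 points at >= 2 distinct temperatures.
#' @param meta Named list of group metadata carried onto the returned row
#'   (e.g. `study_id`, `species`, `temperature` = developmental temperature).
#' @return One-row data frame shaped like a group summary: `mean_ht` = T*,
#'   `se` = delta-method SE, `metric = "tdt_derived"`, plus `meta` fields and
#'   an `extrapolated` flag.
#' @export
tdt_to_heat_tolerance <- function(series, meta = list()) {
  stopifnot(is.data.frame(series),
            all(c("test_temperature", "time_hours") %in% names(series)))
  if (any(series$time_hours <= 0)) {
    stop("knockdown times must be positive", call. = FALSE)
  }
  if (length(unique(series$test_temperature)) < 2L) {
    stop("need >= 2 distinct test temperatures to fit a TDT line",
         call. = FALSE)
  }
  if (nrow(series) < 3L) stop("need >= 3 points", call. = FALSE)
  fit <- stats::lm(log10(time_hours) ~ test_temperature, data = series)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  if (!is.finite(b) || b >= 0) {
    stop("implausible thermal death time curve: slope must be negative",
         call. = FALSE)
  }
  t_star <- -a / b
  # delta method for T* = -a/b: gradient (-1/b, a/b^2)
  cv <- stats::vcov(fit)
  grad <- c(-1 / b, a / b^2)
  se_t <- sqrt(drop(t(grad) %*% cv %*% grad))
  extrap <- t_star < min(series$test_temperature) ||
    t_star > max(series$test_temperature)
  if (extrap) {
    warning("1-h tolerated temperature (", format(t_star, digits = 5),
            ") lies outside the tested range; extrapolated TDT estimates ",
            "are less accurate", call. = FALSE)
  }
  out <- data.frame(
    temperature = meta$temperature %||% NA_real_,
    mean_ht = t_star,
    sd = NA_real_,
    se = se_t,
    n = meta$n %||% NA_real_,
    metric = "tdt_derived",
    extrapolated = extrap,
    stringsAsFactors = FALSE
  )
  for (f in setdiff(names(meta), c("temperature", "n"))) out[[f]] <- meta[[f]]
  out
}

#' Build the full effect-size table from a group-level dataset
#'
#' The group rows are split into comparison blocks (study x species x
#' population x metric x timing), optionally after sd imputation, and each
#' block's stepwise effects are computed. Rows or blocks that cannot yield a
#' usable effect are collected in a rejects table with machine-readable
#' reasons rather than silently dropped.
#'
#' @param groups Data frame of group summaries (schema of [read_groups()]).
#' @param impute Run [impute_missing_sd()] first (default TRUE).
#' @param r_cohort Shared-cohort correlation (default 0.5).
#' @return List with `effects` (effect-size table), `rejects` (data frame of
#'   dropped rows/blocks with a `reason` column), and `imputation`
#'   (an `imputation_summary` or NULL).
#' @export
build_effects <- function(groups, impute = TRUE, r_cohort = 0.5) {
  stopifnot(is.data.frame(groups))
  if (is.null(groups$.group_id)) groups$.group_id <- seq_len(nrow(groups))
  imp <- NULL
  if (impute) {
    res <- impute_missing_sd(groups)
    groups <- res$rows
    imp <- res$summary
  } else {
    sd_col <- col_or(groups, "sd", NA_real_)
    n_col <- col_or(groups, "n", NA_real_)
    se_col <- col_or(groups, "se", NA_real_)
    groups$unusable <- (is.na(sd_col) | is.na(n_col)) & is.na(se_col)
  }
  rejects <- list()
  if (any(groups$unusable)) {
    rejects[[length(rejects) + 1L]] <- data.frame(
      .group_id = groups$.group_id[groups$unusable],
      reason = "no_variance_information", stringsAsFactors = FALSE)
    groups <- groups[!groups$unusable, , drop = FALSE]
  }
  key <- interaction(col_or(groups, "study_id", ""),
                     col_or(groups, "species", ""),
                     col_or(groups, "population_id", ""),
                     col_or(groups, "metric", ""),
                     col_or(groups, "timing", ""), drop = TRUE)
  effs <- list()
  for (blk in split(groups, key)) {
    if (length(unique(blk$temperature)) < 2L) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        .group_id = blk$.group_id,
        reason = "single_temperature_block", stringsAsFactors = FALSE)
      next
    }
    eff <- tryCatch(stepwise_effects(blk, r_cohort = r_cohort),
                    error = function(e) e)
    if (inherits(eff, "error")) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        .group_id = blk$.group_id,
        reason = paste0("block_error: ", conditionMessage(eff)),
        stringsAsFactors = FALSE)
    } else {
      effs[[length(effs) + 1L]] <- eff
    }
  }
  effects <- if (length(effs)) do.call(rbind, effs) else NULL
  if (!is.null(effects)) {
    rownames(effects) <- NULL
    effects$effect_id <- seq_len(nrow(effects))
  }
  list(
    effects = effects,
    rejects = if (length(rejects)) do.call(rbind, rejects) else
      data.frame(.group_id = integer(), reason = character()),
    imputation = imp
  )
}
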