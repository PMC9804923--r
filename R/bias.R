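#' Small-study (Egger-style) meta-regression
#'
#' Regresses dARR on its own standard error (default) or sampling variance
#' under the full multilevel random-effects structure. A slope whose 95% CI
#' excludes zero flags small-study asymmetry, the classic signature of
#' publication bias.
#'
#' @param effects Effect-size table.
#' @param A Phylogenetic correlation matrix (or NULL to drop the phylo
#'   component).
#' @param moderator `"se"` (default, Egger-style) or `"variance"`.
#' @param ... Passed to [darr_meta()].
#' @return A `darr_fit`; the second coefficient is the small-study slope.
#' @export
small_study_test <- function(effects, A = NULL, moderator = c("se", "variance"),
                             ...) {
  moderator <- match.arg(moderator)
  effects$.precision_mod <- if (moderator == "se") sqrt(effects$variance)
                            else effects$variance
  if (length(unique(effects$.precision_mod)) < 2L) {
    stop("small-study moderator is constant; regression is rank deficient",
         call. = FALSE)
  }
  fit <- darr_meta(effects, A = A, fixed = ~.precision_mod, ...)
  fit$moderator <- moderator
  fit
}

#' Time-lag (decline-effect) meta-regression
#'
#' Regresses dARR on mean-centered publication year; a negative slope
#' indicates early studies reported larger effects.
#'
#' @inheritParams small_study_test
#' @return A `darr_fit`; the second coefficient is the year slope (per
#'   year, at the grand-mean year).
#' @export
time_lag_test <- function(effects, A = NULL, ...) {
  stopifnot(!is.null(effects$year), !anyNA(effects$year))
  if (length(unique(effects$year)) < 2L) {
    stop("publication year is constant; regression is rank deficient",
         call. = FALSE)
  }
  effects$.year_c <- effects$year - mean(effects$year)
  fit <- darr_meta(effects, A = A, fixed = ~.year_c, ...)
  fit
}

#' Published vs thesis comparison
#'
#' Cell-means fit by source type with the published-minus-thesis contrast; a
#' difference suggests grey-literature effects diverge from the published
#' record.
#'
#' @inheritParams small_study_test
#' @return List with `fit` (cell-means `darr_fit`) and `contrast`
#'   (article minus thesis), or a skip marker (`NULL` fit with a `reason`)
#'   when only one source type is present.
#' @export
source_comparison <- function(effects, A = NULL, ...) {
  lv <- unique(as.character(effects$source_type))
  if (length(lv) < 2L) {
    return(list(fit = NULL, contrast = NULL,
                reason = paste0("only one source type present: ", lv)))
  }
  effects$source_type <- factor(effects$source_type)
  fit <- darr_meta(effects, A = A, fixed = ~ 0 + source_type, ...)
  cvec <- rep(0, fit$p)
  names(cvec) <- names(fit$beta)
  cvec[grep("article", names(cvec))] <- 1
  cvec[grep("thesis", names(cvec))] <- -1
  list(fit = fit, contrast = contrast_estimate(fit, cvec))
}

#' Leave-one-study-out / leave-one-species-out analysis
#'
#' Refits the intercept-only model once per excluded unit, rebuilding the
#' shared-treatment VCV from the retained effects each time. Non-convergent
#' refits are recorded, not fatal.
#'
#' @param effects Effect-size table.
#' @param A Phylogenetic correlation matrix.
#' @param unit `"study"` or `"species"`.
#' @param ... Passed to [darr_meta()].
#' @return Data frame of class `darr_loo`: one row per excluded unit with
#'   `beta0`, CI bounds and `k`; attribute `"range"` holds the min/max of
#'   `beta0`.
#' @export
leave_one_out <- function(effects, A = NULL, unit = c("study", "species"),
                          ...) {
  unit <- match.arg(unit)
  col <- if (unit == "study") "study_id" else "species"
  units <- unique(effects[[col]])
  if (length(units) < 3L) stop("need >= 3 ", unit, " units", call. = FALSE)
  rows <- lapply(units, function(u) {
    sub <- effects[effects[[col]] != u, , drop = FALSE]
    fit <- tryCatch(darr_meta(sub, A = A, fixed = ~1, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(excluded = u, k = nrow(sub), beta0 = NA_real_,
                 ci_lb = NA_real_, ci_ub = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(excluded = u, k = fit$k, beta0 = unname(fit$beta[1]),
                 ci_lb = unname(fit$ci_lb[1]), ci_ub = unname(fit$ci_ub[1]),
                 converged = fit$converged, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "range") <- range(out$beta0, na.rm = TRUE)
  attr(out, "unit") <- unit
  class(out) <- c("darr_loo", class(out))
  out
}

#' Define a sensitivity subset
#'
#' @param filter One of `"all"`, `"timing_initial"`, `"timing_persistent"`,
#'   `"exclude_imputed"`, `"exclude_risk_of_bias"`, `"cutoff"`.
#' @param cutoff Lower dARR bound for `filter = "cutoff"`: effects with
#'   `darr < cutoff` are dropped (the convention previous syntheses used,
#'   e.g. -0.15).
#' @param label Optional display label.
#' @return List of class `subset_spec`.
#' @export
subset_spec <- function(filter = c("all", "timing_initial",
                                   "timing_persistent", "exclude_imputed",
                                   "exclude_risk_of_bias", "cutoff"),
                        cutoff = NULL, label = NULL) {
  filter <- match.arg(filter)
  if (filter == "cutoff") stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  if (is.null(label)) {
    label <- if (filter == "cutoff") paste0("darr >= ", cutoff) else filter
  }
  structure(list(filter = filter, cutoff = cutoff, label = label),
            class = "subset_spec")
}

apply_subset <- function(effects, spec) {
  stopifnot(inherits(spec, "subset_spec"))
  keep <- switch(spec$filter,
    all = rep(TRUE, nrow(effects)),
    timing_initial = effects$timing == "initial",
    timing_persistent = effects$timing == "persistent",
    exclude_imputed = effects$variance_basis != "imputed_sd",
    exclude_risk_of_bias = !isTRUE_vec(effects$risk_of_bias),
    cutoff = effects$darr >= spec$cutoff
  )
  effects[keep & !is.na(keep), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Subset and cutoff sensitivity refits
#'
#' Refits the main model on each requested subset (initial/persistent
#' timing, excluding imputed variances or risk-of-bias rows, dARR cutoffs).
#' Subsets leaving fewer than `min_k` effects are skipped with a logged
#' reason rather than fitted.
#'
#' @param effects Effect-size table.
#' @param A Phylogenetic correlation matrix.
#' @param specs List of [subset_spec()] objects.
#' @param min_k Minimum effects for a refit (default 10).
#' @param ... Passed to [darr_meta()].
#' @return Data frame: one row per spec with `label`, `k`, `beta0`, CI and a
#'   `skipped` reason (NA when fitted).
#' @export
subset_refits <- function(effects, A = NULL, specs, min_k = 10L, ...) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  rows <- lapply(specs, function(sp) {
    sub <- apply_subset(effects, sp)
    if (nrow(sub) < min_k) {
      return(data.frame(label = sp$label, k = nrow(sub), beta0 = NA_real_,
                        ci_lb = NA_real_, ci_ub = NA_real_,
                        skipped = paste0("fewer than ", min_k, " effects"),
                        stringsAsFactors = FALSE))
    }
    fit <- darr_meta(sub, A = A, fixed = ~1, ...)
    data.frame(label = sp$label, k = fit$k, beta0 = unname(fit$beta[1]),
               ci_lb = unname(fit$ci_lb[1]), ci_ub = unname(fit$ci_ub[1]),
               skipped = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Funnel data export
#'
#' Per-effect model residuals (`y - X beta_hat`) against sampling standard
#' errors, the raw material of a funnel plot. Asymmetry (a residual-SE
#' relationship) suggests small-study effects.
#'
#' @param fit A converged `darr_fit`.
#' @return Data frame with `residual` and `se`, one row per effect.
#' @export
funnel_export <- function(fit) {
  stopifnot(inherits(fit, "darr_fit"))
  data.frame(residual = drop(fit$y - fit$X %*% fit$beta),
             se = unname(sqrt(diag(fit$V))))
}

#' Basic funnel plot
#'
#' Residuals on the x axis against precision (inverse SE convention:
#' smaller SE higher up), with a vertical zero line.
#'
#' @param fit A converged `darr_fit`.
#' @param file Optional path; when given, a PNG/SVG (by extension) is
#'   written instead of plotting to the current device.
#' @return The funnel data, invisibly.
#' @export
funnel_plot <- function(fit, file = NULL) {
  dat <- funnel_export(fit)
  draw <- function() {
    graphics::plot(dat$residual, 1 / dat$se, xlab = "residual dARR",
                   ylab = "precision (1/SE)", pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.6))
    graphics::abline(v = 0, lty = 2)
  }
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file)
    else grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(dat)
}
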