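#' Control parameters for the REML optimizer
#'
#' Variance components are parameterized on the log scale and the restricted
#' log-likelihood is maximized by Nelder-Mead from several fixed starting
#' points; components that converge onto the floor are reported as exactly 0.
#'
#' @param n_starts Number of deterministic multistarts (>= 1; default 3).
#' @param reltol Relative convergence tolerance (default 1e-8).
#' @param maxit Maximum iterations per start (default 2000).
#' @param floor Relative floor below which a variance component is snapped to
#'   zero at convergence (default 1e-8, relative to the response variance).
#' @return List of class `reml_control`.
#' @export
reml_control <- function(n_starts = 3L, reltol = 1e-8, maxit = 2000L,
                         floor = 1e-8) {
  stopifnot(n_starts >= 1L, reltol > 0, maxit > 0, floor >= 0)
  structure(list(n_starts = as.integer(n_starts), reltol = reltol,
                 maxit = as.integer(maxit), floor = floor),
            class = "reml_control")
}

# Restricted log-likelihood of the multilevel model at a given set of
# variance components. parts: list of k x k matrices, one per component
# (already expanded to effect level); d_idx: list mapping diagonal
# components to index vectors is handled by passing diagonal parts as
# vectors. Returns list(ll, beta, vcov_beta, XtWX).
remll_eval <- function(sigma2, y, X, V, parts) {
  k <- length(y)
  p <- ncol(X)
  Sigma <- V
  for (i in seq_along(parts)) {
    pt <- parts[[i]]
    if (is.matrix(pt)) {
      Sigma <- Sigma + sigma2[i] * pt
    } else {
      # diagonal component given as 0/1 indicator vector
      diag(Sigma) <- diag(Sigma) + sigma2[i] * pt
    }
  }
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    # numerical hiccup: clip eigenvalues for the factorization only
    eg <- eigen(Sigma, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-10 * max(eg$values))
    R <- chol(eg$vectors %*% (vals * t(eg$vectors)))
  }
  ldet <- 2 * sum(log(diag(R)))
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  XtWX <- crossprod(Xt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- drop(backsolve(ch, backsolve(ch, crossprod(Xt, yt),
                                       transpose = TRUE)))
  r <- drop(yt - Xt %*% beta)
  ll <- -0.5 * ((k - p) * log(2 * pi) + ldet +
                  2 * sum(log(diag(ch))) + sum(r^2))
  list(ll = ll, beta = beta, vcov_beta = chol2inv(ch))
}

#' Fit a multilevel meta-analytic model by REML
#'
#' The marginal covariance of the effect sizes is modelled as
#' \deqn{\Sigma = \sigma^2_{phylo} Z A Z' + \sigma^2_{species} Z Z' + D_{obs} + V}
#' where `Z` maps effects to species, `A` is the phylogenetic correlation
#' matrix, `D_obs` is a diagonal observation-level component (a single
#' variance, or one variance per level of `obs_level` — the heteroscedastic
#' "zero covariance" structure), and `V` is the known sampling
#' variance-covariance matrix. Variance components are estimated by
#' restricted maximum likelihood and fixed effects by generalized least
#' squares at the optimum. Inference uses t distributions with `df = k - p`.
#'
#' @param y Numeric response vector (effect sizes).
#' @param X Fixed-effect design matrix (k x p, full rank).
#' @param V Known k x k sampling variance-covariance matrix (or a vector of
#'   sampling variances, taken as a diagonal).
#' @param species Character/factor vector of length k mapping effects to
#'   species; required when `"phylo"` or `"species"` is in `random`.
#' @param A Phylogenetic correlation matrix with dimnames covering all
#'   species; required when `"phylo"` is in `random`.
#' @param random Random components to estimate, subset of
#'   `c("phylo", "species", "obs")`. Empty → plain GLS with weights from `V`.
#' @param obs_level Optional factor of length k; when given, the
#'   observation-level variance is estimated separately for each level.
#' @param control A [reml_control()] list.
#' @return Object of class `darr_fit`: fixed-effect estimates with t-based
#'   inference, variance components, restricted log-likelihood, AIC, and the
#'   ingredients needed for downstream heterogeneity / interval / contrast
#'   computations.
#' @export
fit_reml <- function(y, X, V, species = NULL, A = NULL,
                     random = c("phylo", "species", "obs"),
                     obs_level = NULL, control = reml_control()) {
  y <- as.numeric(y)
  k <- length(y)
  if (is.null(dim(X))) X <- matrix(X, nrow = k)
  stopifnot(nrow(X) == k)
  p <- ncol(X)
  if (k <= p) stop("need more effects than fixed coefficients", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("fixed-effect design is rank deficient; check moderator coding",
         call. = FALSE)
  }
  if (!is.matrix(V)) V <- diag(as.numeric(V), k, k)
  stopifnot(all(dim(V) == k))
  if (length(random)) {
    random <- match.arg(random, c("phylo", "species", "obs"),
                        several.ok = TRUE)
  }
  if (length(random) && any(c("phylo", "species") %in% random)) {
    stopifnot(!is.null(species), length(species) == k)
    species <- as.character(species)
  }

  parts <- list()
  labels <- character()
  if ("phylo" %in% random) {
    stopifnot(!is.null(A))
    missing <- setdiff(unique(species), rownames(A))
    if (length(missing)) {
      stop("species missing from the correlation matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    parts <- c(parts, list(A[species, species, drop = FALSE]))
    labels <- c(labels, "phylo")
  }
  if ("species" %in% random) {
    parts <- c(parts, list(outer(species, species, "==") * 1))
    labels <- c(labels, "species")
  }
  if ("obs" %in% random) {
    if (is.null(obs_level)) {
      parts <- c(parts, list(rep(1, k)))
      labels <- c(labels, "obs")
    } else {
      obs_level <- as.factor(obs_level)
      stopifnot(length(obs_level) == k)
      if (anyNA(obs_level)) {
        stop("every effect must map to exactly one residual-variance level",
             call. = FALSE)
      }
      for (lv in levels(obs_level)) {
        parts <- c(parts, list(as.numeric(obs_level == lv)))
        labels <- c(labels, paste0("obs.", lv))
      }
    }
  }

  n_par <- length(parts)
  if (n_par == 0L) {
    # degenerate limit: fixed-effect GLS with weights from V alone
    ev <- remll_eval(numeric(0), y, X, V, list())
    fit <- build_fit(ev, sigma2 = numeric(0), labels = character(0),
                     y = y, X = X, V = V, species = species,
                     obs_level = obs_level, converged = TRUE,
                     control = control)
    return(fit)
  }

  scale <- max(stats::var(y), mean(diag(V)), 1e-6)
  base <- rep(scale / (n_par + 1), n_par)
  starts <- list(log(base), log(base * 10), log(base / 10),
                 log(base * 100), log(base / 100))
  starts <- starts[seq_len(max(control$n_starts, 1L))]

  negll <- function(par) {
    s2 <- exp(par)
    if (any(!is.finite(s2)) || any(s2 > 1e6 * scale)) return(1e10)
    ev <- remll_eval(s2, y, X, V, parts)
    if (!is.finite(ev$ll)) return(1e10)
    -ev$ll
  }
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    opt <- if (n_par == 1L) {
      stats::optim(st, negll, method = "Brent",
                   lower = log(scale) - 25, upper = log(scale) + 15,
                   control = list(reltol = control$reltol,
                                  maxit = control$maxit))
    } else {
      stats::optim(st, negll, method = "Nelder-Mead",
                   control = list(reltol = control$reltol,
                                  maxit = control$maxit))
    }
    if (is.null(best) || opt$value < best$value - 1e-12) {
      best <- opt
    }
    if (opt$convergence == 0) conv <- TRUE
  }
  sigma2 <- exp(best$par)
  sigma2[sigma2 < control$floor * scale] <- 0
  ev <- remll_eval(sigma2, y, X, V, parts)
  build_fit(ev, sigma2 = sigma2, labels = labels, y = y, X = X, V = V,
            species = species, obs_level = obs_level,
            converged = conv && is.finite(ev$ll), control = control)
}

build_fit <- function(ev, sigma2, labels, y, X, V, species, obs_level,
                      converged, control) {
  k <- length(y)
  p <- ncol(X)
  names(sigma2) <- labels
  beta <- ev$beta
  names(beta) <- colnames(X)
  vcov_beta <- ev$vcov_beta
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  df <- k - p
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df = df)
  fit <- structure(list(
    beta = beta, se = se, t = tstat, df = df, pval = pval,
    ci_lb = beta - tcrit * se, ci_ub = beta + tcrit * se,
    sigma2 = sigma2, loglik = ev$ll,
    aic = -2 * ev$ll + 2 * length(sigma2),
    k = k, p = p, vcov_beta = vcov_beta, converged = converged,
    y = y, X = X, V = V, species = species, obs_level = obs_level,
    control = control
  ), class = "darr_fit")
  fit
}

#' @export
print.darr_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (REML)\n")
  cat("k =", x$k, " fixed coefficients =", x$p, " df =", x$df, "\n")
  cat("restricted logLik =", format(x$loglik, digits = digits),
      " AIC =", format(x$aic, digits = digits),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n\n")
  cat("Variance components:\n")
  print(round(x$sigma2, digits))
  cat("\nFixed effects (t-based 95% CI):\n")
  print(round(t_inference(x), digits))
  invisible(x)
}

#' Fit the standard dARR meta-analysis / meta-regression
#'
#' Formula-level wrapper around [fit_reml()]: builds the fixed-effect design
#' from the effect-size table, the shared-treatment sampling VCV, and the
#' species mapping, then fits the multilevel model with phylogenetic,
#' non-phylogenetic species, and observation-level random effects.
#'
#' @param effects Effect-size table ([build_effects()] output) with columns
#'   `darr`, `variance`, `species`, and any moderators used in `fixed`.
#' @param A Phylogenetic correlation matrix (tip labels as dimnames). May be
#'   NULL when `"phylo"` is dropped from `random`.
#' @param fixed Model formula for the moderators, e.g. `~ 1` (intercept-only
#'   meta-analysis) or `~ 0 + habitat` (cell-means coding). Evaluated
#'   against `effects`.
#' @param residual_by Optional name of a categorical column: estimate one
#'   observation-level variance per level (heteroscedastic, zero-covariance
#'   structure).
#' @param r_shared Shared-treatment sampling correlation for the VCV
#'   (default 0.5).
#' @param random Random components (see [fit_reml()]).
#' @param control [reml_control()].
#' @return A `darr_fit`.
#' @export
darr_meta <- function(effects, A = NULL, fixed = ~1, residual_by = NULL,
                      r_shared = 0.5, random = c("phylo", "species", "obs"),
                      control = reml_control()) {
  stopifnot(is.data.frame(effects), !is.null(effects$darr),
            !is.null(effects$variance))
  X <- stats::model.matrix(fixed, data = effects)
  V <- build_sampling_vcv(effects, r_shared = r_shared)
  obs_level <- NULL
  if (!is.null(residual_by)) {
    stopifnot(residual_by %in% names(effects))
    obs_level <- as.factor(effects[[residual_by]])
  }
  species <- if (!is.null(effects$species)) {
    if (!is.null(A)) match_species_to_tips(effects$species,
                                           list(tip.label = rownames(A)))
    else as.character(effects$species)
  } else NULL
  fit <- fit_reml(y = effects$darr, X = X, V = V, species = species, A = A,
                  random = random, obs_level = obs_level, control = control)
  fit$fixed <- fixed
  fit$residual_by <- residual_by
  fit$r_shared <- r_shared
  fit$effects <- effects
  fit$A <- A
  fit
}

#' t-based inference table for the fixed effects
#'
#' Confidence intervals use `df = k - p`; the working significance
#' convention is a 95% CI excluding zero.
#'
#' @param fit A `darr_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with estimate, se, t, df, p, and CI bounds.
#' @export
t_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "darr_fit"))
  if (fit$df < 1) stop("k <= p: no residual degrees of freedom", call. = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  data.frame(
    estimate = fit$beta, se = fit$se, t = fit$t, df = fit$df,
    p = 2 * stats::pt(abs(fit$t), df = fit$df, lower.tail = FALSE),
    ci_lb = fit$beta - tcrit * fit$se,
    ci_ub = fit$beta + tcrit * fit$se,
    row.names = names(fit$beta)
  )
}

# total heterogeneity variance; for a heteroscedastic observation level the
# per-level variances enter as the effect-count-weighted mean
total_heterogeneity <- function(fit) {
  s2 <- fit$sigma2
  obs <- grep("^obs\\.", names(s2))
  if (length(obs)) {
    w <- table(fit$obs_level)[sub("^obs\\.", "", names(s2)[obs])]
    obs_var <- sum(s2[obs] * as.numeric(w)) / sum(w)
    sum(s2[-obs]) + obs_var
  } else {
    sum(s2)
  }
}

#' Prediction intervals for fixed-effect cells
#'
#' A 95% prediction interval is expected to contain the true effect of a new
#' study: it widens the confidence interval by the total heterogeneity,
#' \eqn{\hat\beta \pm t_{df} \sqrt{SE^2 + \sum \sigma^2}}. Under a
#' heteroscedastic observation level, the observation variance enters as the
#' effect-count-weighted mean of the per-level variances; per-level
#' intervals using each level's own variance are additionally returned when
#' available.
#'
#' @param fit A `darr_fit`.
#' @param level Coverage level (default 0.95).
#' @return Data frame with estimate, `pi_lb`, `pi_ub` per coefficient;
#'   attribute `"by_level"` holds per-level intervals for heteroscedastic
#'   fits.
#' @export
prediction_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "darr_fit"))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  tau2 <- total_heterogeneity(fit)
  hw <- tcrit * sqrt(fit$se^2 + tau2)
  out <- data.frame(estimate = fit$beta,
                    pi_lb = fit$beta - hw, pi_ub = fit$beta + hw,
                    row.names = names(fit$beta))
  obs <- grep("^obs\\.", names(fit$sigma2))
  if (length(obs)) {
    s2 <- fit$sigma2
    base <- sum(s2[-obs])
    lv <- sub("^obs\\.", "", names(s2)[obs])
    by_level <- lapply(seq_along(obs), function(i) {
      hwl <- tcrit * sqrt(fit$se^2 + base + s2[obs[i]])
      data.frame(estimate = fit$beta, pi_lb = fit$beta - hwl,
                 pi_ub = fit$beta + hwl, row.names = names(fit$beta))
    })
    names(by_level) <- lv
    attr(out, "by_level") <- by_level
  }
  out
}

#' Heterogeneity decomposition (multilevel I-squared)
#'
#' The proportion of total variance not attributable to sampling error,
#' split by random-effect level. The "typical" sampling variance is
#' \deqn{\bar{s}^2 = \frac{(k-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2}, \quad w_i = 1/v_i}
#' and each component's share is
#' \eqn{I^2_c = \sigma^2_c / (\sum_c \sigma^2_c + \bar{s}^2)} (in percent).
#' The component values share a denominator so they sum exactly to the
#' total.
#'
#' @param fit A `darr_fit`.
#' @param v Optional vector of sampling variances (defaults to `diag(V)` of
#'   the fit).
#' @return Named list: `i2_total` plus one `i2_<component>` per random
#'   component (percent scale), and `s2_typical`.
#' @export
i2_decomposition <- function(fit, v = NULL) {
  stopifnot(inherits(fit, "darr_fit"))
  if (is.null(v)) v <- diag(fit$V)
  if (any(v <= 0)) stop("sampling variances must be positive", call. = FALSE)
  k <- length(v)
  w <- 1 / v
  s2_typ <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  s2 <- fit$sigma2
  obs <- grep("^obs\\.", names(s2))
  comp <- if (length(obs)) {
    wts <- table(fit$obs_level)[sub("^obs\\.", "", names(s2)[obs])]
    c(s2[-obs], obs = sum(s2[obs] * as.numeric(wts)) / sum(wts))
  } else s2
  denom <- sum(comp) + s2_typ
  i2 <- 100 * comp / denom
  out <- as.list(i2)
  names(out) <- paste0("i2_", names(comp))
  c(list(i2_total = sum(i2)), out, list(s2_typical = s2_typ))
}

#' Post-stratified (equal-weight) marginal mean
#'
#' For a cell-means fit of a categorical moderator, averages the level
#' estimates with equal weights — a post-stratification correction for
#' unbalanced representation (e.g. the over-representation of aquatic
#' species). Inference is t-based with the fit's df; a prediction interval
#' is included.
#'
#' @param fit A `darr_fit` from a no-intercept cell-means model.
#' @param weights Either `"equal"` (default) or a numeric vector summing
#'   to 1, one weight per coefficient.
#' @param level Confidence level.
#' @return One-row data frame: estimate, se, t, df, p, CI and PI bounds.
#' @export
marginal_means <- function(fit, weights = "equal", level = 0.95) {
  stopifnot(inherits(fit, "darr_fit"))
  L <- fit$p
  cvec <- if (identical(weights, "equal")) rep(1 / L, L) else {
    stopifnot(is.numeric(weights), length(weights) == L)
    weights
  }
  if (anyNA(fit$beta)) stop("all levels must be estimated", call. = FALSE)
  est <- contrast_estimate(fit, cvec, level = level)
  tau2 <- total_heterogeneity(fit)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  est$pi_lb <- est$estimate - tcrit * sqrt(est$se^2 + tau2)
  est$pi_ub <- est$estimate + tcrit * sqrt(est$se^2 + tau2)
  rownames(est) <- "marginal_mean"
  est
}

#' Linear contrast of fixed-effect coefficients
#'
#' @param fit A `darr_fit`.
#' @param cvec Numeric weight vector, conformable with the coefficients
#'   (e.g. `c(1, -1)` for a difference between two cell means).
#' @param level Confidence level.
#' @return One-row data frame with estimate, se, t, df, p, CI bounds.
#' @export
contrast_estimate <- function(fit, cvec, level = 0.95) {
  stopifnot(inherits(fit, "darr_fit"))
  if (length(cvec) != fit$p) {
    stop("contrast vector not conformable with the ", fit$p,
         " fixed coefficients", call. = FALSE)
  }
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf)
  data.frame(
    estimate = est, se = se, t = tstat, df = fit$df,
    p = 2 * stats::pt(abs(tstat), df = fit$df, lower.tail = FALSE),
    ci_lb = est - tcrit * se, ci_ub = est + tcrit * se,
    row.names = "contrast"
  )
}

#' Compare random-effect structures by AIC
#'
#' REML AICs are comparable only for models sharing the same fixed-effect
#' design; the function refuses anything else. AIC counts the variance
#' parameters (`-2 logLik_R + 2 q`).
#'
#' @param ... Named `darr_fit` objects (or a single list of them).
#' @return Data frame with variance-parameter count, restricted logLik, AIC
#'   and delta-AIC against the best model.
#' @export
aic_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "darr_fit")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "darr_fit")))
  X0 <- fits[[1L]]$X
  for (f in fits[-1L]) {
    if (!isTRUE(all.equal(unname(f$X), unname(X0)))) {
      stop("fits have different fixed-effect designs; REML AICs are not ",
           "comparable", call. = FALSE)
    }
  }
  tab <- data.frame(
    q = vapply(fits, function(f) length(f$sigma2), numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  if (!is.null(names(fits))) rownames(tab) <- names(fits)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab[order(tab$aic), ]
}
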