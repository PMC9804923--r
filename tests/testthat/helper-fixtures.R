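# shared fixture builders for the test suite

make_group <- function(temperature, mean_ht, sd = NA_real_, se = NA_real_,
                       n = NA_real_, study_id = "s1", species = "Genus species",
                       metric = "ctmax", timing = "initial",
                       cohort_id = NA_character_, ...) {
  c(list(study_id = study_id, species = species, metric = metric,
         timing = timing, temperature = temperature, mean_ht = mean_ht,
         sd = sd, se = se, n = n, cohort_id = cohort_id), list(...))
}

# a block of groups at given temperatures, as a data frame
make_block <- function(temps, means = NULL, sd = 1, n = 10,
                       study_id = "s1", species = "Genus species",
                       cohort_id = NA_character_, ...) {
  if (is.null(means)) means <- 38 + 0.5 * (temps - temps[1])
  data.frame(study_id = study_id, species = species,
             population_id = paste0(study_id, "_p1"),
             cohort_id = cohort_id, temperature = temps, mean_ht = means,
             sd = sd, se = NA_real_, n = n, metric = "ctmax",
             timing = "initial", stringsAsFactors = FALSE, ...)
}

# small multi-study dataset with an A matrix, for model-level tests
make_small_dataset <- function(seed = 101, n_species = 8,
                               truth = sim_truth(n_species = n_species,
                                                 studies_per_species = 1:2,
                                                 frac_tdt = 0,
                                                 frac_missing_sd = 0,
                                                 frac_se_only = 0)) {
  sim <- simulate_dataset(truth, seed = seed)
  built <- build_effects(sim$groups)
  list(effects = built$effects, A = sim$A, sim = sim)
}

# independent dense REML log-likelihood: textbook matrix formulation with
# determinant()/solve(), no shared code with the package's chol path
dense_remll <- function(sigma2, y, X, V, ZAZ, ZZ, obs_ind = NULL) {
  k <- length(y)
  p <- ncol(X)
  Sigma <- V + sigma2[1] * ZAZ + sigma2[2] * ZZ
  if (is.null(obs_ind)) {
    Sigma <- Sigma + sigma2[3] * diag(k)
  } else {
    for (i in seq_along(obs_ind)) {
      Sigma <- Sigma + sigma2[2 + i] * diag(obs_ind[[i]])
    }
  }
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  ld1 <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  ld2 <- as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus)
  -0.5 * ((k - p) * log(2 * pi) + ld1 + ld2 +
            as.numeric(t(r) %*% Si %*% r))
}
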