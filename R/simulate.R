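#' Simulation truth for synthetic heat-tolerance datasets
#'
#' Bundles every knob of the generative model: the true overall dARR, the
#' between-species (phylogenetic and non-phylogenetic) and within-species
#' variance components, moderator effects, study-structure distributions and
#' the group-level measurement model. Defaults are anchored to the world the
#' meta-analysis describes: an overall dARR of 0.19, total heterogeneity
#' ~0.10 split phylo/species/residual roughly 26/10/64, a -0.15 terrestrial
#' habitat offset, ~86% aquatic effects and ~20% persistent-timing effects.
#'
#' @param beta0 True overall dARR (default 0.19).
#' @param sigma2_phylo,sigma2_species Between-species variance components
#'   (default 0.027 and 0.010).
#' @param sigma2_obs Observation-level variance; a scalar (default 0.066) or
#'   a named vector of per-level variances combined with `obs_level_by`.
#' @param obs_level_by Optional moderator name (`"habitat"` or `"timing"`)
#'   whose levels index `sigma2_obs` when it is a vector.
#' @param habitat_offset Additive shift of terrestrial vs aquatic true dARR
#'   (default -0.15).
#' @param year_slope True time-lag slope per mean-centered year (default 0).
#' @param n_species Number of species (default 40).
#' @param studies_per_species Integer vector sampled uniformly per species
#'   (default 2:4).
#' @param p_temps Probabilities of a study using 2, 3 or 4 developmental
#'   temperatures (default c(0.45, 0.35, 0.20)).
#' @param frac_paired_cohort Probability a study measures the same cohort at
#'   all temperatures (default 0.10).
#' @param frac_persistent Fraction of studies assaying persistent (post
#'   common-garden) rather than initial effects (default 0.20).
#' @param frac_tdt Fraction of studies reporting static thermal-death-time
#'   assays instead of direct tolerance means (default 0.05).
#' @param frac_missing_sd Fraction of group rows with sd withheld (n kept,
#'   so imputation applies; default 0.10).
#' @param frac_se_only Fraction of group rows reporting only a standard
#'   error (default 0.05).
#' @param frac_thesis Fraction of studies from theses (default 0.10).
#' @param prop_aquatic Proportion of aquatic species (default 0.857).
#' @param baseline_ht Mean and sd of the species baseline heat tolerance in
#'   degrees C (default c(38, 3)).
#' @param ind_sd_range Range of individual-level sd in degrees C
#'   (default c(0.5, 2)).
#' @param n_range Integer range of per-group sample sizes (default 5:30).
#' @param t_min_range Range of the lowest developmental temperature
#'   (default c(15, 25)).
#' @param dt_range Range of temperature-step sizes in degrees C
#'   (default c(2, 5)).
#' @param year_range Publication years sampled per study
#'   (default 1990:2020).
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(beta0 = 0.19,
                      sigma2_phylo = 0.027,
                      sigma2_species = 0.010,
                      sigma2_obs = 0.066,
                      obs_level_by = NULL,
                      habitat_offset = -0.15,
                      year_slope = 0,
                      n_species = 40L,
                      studies_per_species = 2:4,
                      p_temps = c(0.45, 0.35, 0.20),
                      frac_paired_cohort = 0.10,
                      frac_persistent = 0.20,
                      frac_tdt = 0.05,
                      frac_missing_sd = 0.10,
                      frac_se_only = 0.05,
                      frac_thesis = 0.10,
                      prop_aquatic = 0.857,
                      baseline_ht = c(38, 3),
                      ind_sd_range = c(0.5, 2),
                      n_range = 5:30,
                      t_min_range = c(15, 25),
                      dt_range = c(2, 5),
                      year_range = 1990:2020) {
  truth <- as.list(environment())
  fr <- unlist(truth[grep("^frac_|^prop_", names(truth))])
  stopifnot(sigma2_phylo >= 0, sigma2_species >= 0, all(sigma2_obs >= 0),
            all(fr >= 0 & fr <= 1), all(n_range >= 2), n_species >= 2,
            abs(sum(p_temps) - 1) < 1e-8)
  structure(truth, class = "sim_truth")
}

# sample() treats a length-1 numeric vector as 1:x; never what we want
sample_from <- function(x, n = 1L, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

#' Simulate a random species tree
#'
#' Builds a rooted binary topology by successive random joins of the tip
#' set, with tips `sp_1 ... sp_n` and no branch lengths (Grafen scaling
#' assigns them later). Deterministic for a given seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_species, seed) {
  stopifnot(n_species >= 2)
  local_seed(as.integer(seed), {
    nodes <- paste0("sp_", seq_len(n_species))
    while (length(nodes) > 1L) {
      pick <- sample.int(length(nodes), 2L)
      joined <- paste0("(", nodes[pick[1L]], ",", nodes[pick[2L]], ")")
      nodes <- c(nodes[-pick], joined)
    }
    read_tree(text = paste0(nodes, ";"))
  })
}

#' Simulate a thermal death time series
#'
#' Knockdown times follow `log10(time) = a + b * T + noise` with negative
#' slope `b`.
#'
#' @param a Intercept of the true line (log10 hours).
#' @param b Slope (must be negative).
#' @param noise_sd Gaussian noise sd on the log10 scale.
#' @param n_points Number of points (>= 3).
#' @param temps Optional test temperatures; defaults to an even grid of
#'   width 4 degrees C centred on the 1-h temperature `-a/b`.
#' @param seed Integer seed.
#' @return Data frame with `test_temperature` and `time_hours`.
#' @export
simulate_tdt <- function(a, b, noise_sd = 0, n_points = 6L, temps = NULL,
                         seed = 1L) {
  if (b >= 0) stop("TDT slope must be negative", call. = FALSE)
  stopifnot(n_points >= 3L)
  if (is.null(temps)) {
    t_star <- -a / b
    temps <- seq(t_star - 2, t_star + 2, length.out = n_points)
  }
  local_seed(as.integer(seed), {
    logt <- a + b * temps + stats::rnorm(length(temps), 0, noise_sd)
    data.frame(test_temperature = temps, time_hours = 10^logt)
  })
}

#' Simulate a group-level dataset with known truth
#'
#' Draws species effects from the multilevel model the analysis assumes
#' (phylogenetic Brownian component with covariance `sigma2_phylo * A`, an
#' independent species component, and a per-comparison observation-level
#' deviation), then constructs study designs (2-4 developmental
#' temperatures, optional shared cohorts, TDT assays, missing dispersion)
#' and group summaries from normal individual-level data: observed means are
#' `Normal(mu, sd^2/n)` and observed sds follow the exact
#' `sd * sqrt(chi^2_{n-1}/(n-1))` sampling law, so downstream sampling
#' variances are correctly calibrated.
#'
#' @param truth A [sim_truth()] object.
#' @param tree An `ape::phylo` with at least `n_species` tips named
#'   `sp_1...`; defaults to [simulate_tree()] under the same seed.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of `(truth, tree, seed)`.
#' @return List with `groups` (group-level table in the [read_groups()]
#'   schema), `truth_effects` (one row per latent stepwise comparison with
#'   the true slope and its components, keyed by `study_id`, `t1`, `t2`),
#'   `tdt_series` (list of simulated knockdown series), `tree`, and `A`
#'   (the Grafen correlation matrix actually used).
#' @export
simulate_dataset <- function(truth, tree = NULL, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  seed <- as.integer(seed)
  if (is.null(tree)) tree <- simulate_tree(truth$n_species, seed)
  tree <- resolve_polytomies(tree, seed)
  A <- phylo_correlation(grafen_lengths(tree))
  sp <- tree$tip.label[seq_len(truth$n_species)]
  stopifnot(length(tree$tip.label) >= truth$n_species)

  local_seed(seed + 1L, {
    # species-level true effects
    z_sp <- stats::rnorm(length(sp))
    tot_sp <- truth$sigma2_phylo + truth$sigma2_species
    u <- if (tot_sp > 0) {
      cov_sp <- truth$sigma2_phylo * A[sp, sp] +
        truth$sigma2_species * diag(length(sp))
      drop(crossprod(chol(cov_sp + tot_sp * 1e-10 * diag(length(sp))), z_sp))
    } else {
      rep(0, length(sp))
    }
    names(u) <- sp
    habitat <- ifelse(stats::runif(length(sp)) < truth$prop_aquatic,
                      "aquatic", "terrestrial")
    names(habitat) <- sp
    taxon <- ifelse(habitat == "aquatic", "fish", "terrestrial_invertebrate")

    groups <- list()
    truths <- list()
    tdt_series <- list()
    study_no <- 0L
    obs_sigma2 <- function(lvls) {
      s2 <- truth$sigma2_obs
      if (length(s2) == 1L) rep(s2, length(lvls)) else {
        stopifnot(!is.null(names(s2)), all(lvls %in% names(s2)))
        unname(s2[lvls])
      }
    }
    for (s in sp) {
      n_studies <- if (length(truth$studies_per_species) == 1L)
        truth$studies_per_species else sample_from(truth$studies_per_species)
      for (st in seq_len(n_studies)) {
        study_no <- study_no + 1L
        study_id <- sprintf("study_%03d", study_no)
        persistent <- stats::runif(1) < truth$frac_persistent
        timing <- if (persistent) "persistent" else "initial"
        design <- sample_from(if (persistent) c("D", "E", "F") else c("A", "B", "C"))
        metric <- if (stats::runif(1) < truth$frac_tdt) "tdt_derived"
                  else sample_from(c("ctmax", "lt50"), prob = c(0.8, 0.2))
        n_temps <- sample_from(2:4, prob = truth$p_temps)
        t_min <- stats::runif(1, truth$t_min_range[1], truth$t_min_range[2])
        temps <- t_min + cumsum(c(0, stats::runif(n_temps - 1L,
                                                  truth$dt_range[1],
                                                  truth$dt_range[2])))
        paired <- stats::runif(1) < truth$frac_paired_cohort
        year <- sample_from(truth$year_range)
        source_type <- if (stats::runif(1) < truth$frac_thesis) "thesis"
                       else "article"
        mod_level <- if (is.null(truth$obs_level_by)) "all"
                     else if (truth$obs_level_by == "habitat") habitat[s]
                     else timing
        s2_obs <- obs_sigma2(rep(mod_level, n_temps - 1L))
        hab_off <- if (habitat[s] == "terrestrial") truth$habitat_offset else 0
        yr_c <- year - mean(truth$year_range)
        slopes <- truth$beta0 + hab_off + truth$year_slope * yr_c + u[s] +
          stats::rnorm(n_temps - 1L, 0, sqrt(s2_obs))
        mu <- truth$baseline_ht[1] +
          stats::rnorm(1, 0, truth$baseline_ht[2]) +
          c(0, cumsum(slopes * diff(temps)))

        ind_sd <- stats::runif(n_temps, truth$ind_sd_range[1],
                               truth$ind_sd_range[2])
        n <- sample_from(truth$n_range, n_temps)
        obs_mean <- stats::rnorm(n_temps, mu, ind_sd / sqrt(n))
        obs_sd <- ind_sd * sqrt(stats::rchisq(n_temps, n - 1L) / (n - 1L))

        g <- data.frame(
          study_id = study_id, species = gsub("_", " ", s),
          population_id = paste0(study_id, "_pop1"),
          cohort_id = if (paired) paste0(study_id, "_cohort1") else NA_character_,
          temperature = temps, mean_ht = obs_mean, sd = obs_sd,
          se = NA_real_, n = n, metric = metric, design = design,
          timing = timing, habitat = unname(habitat[s]),
          taxon_group = unname(taxon[s]), heating_rate = 0.25, year = year,
          source_type = source_type, sd_imputed = FALSE,
          risk_of_bias = FALSE, stringsAsFactors = FALSE
        )
        if (metric == "tdt_derived") {
          # static assays: the group mean comes from inverting a simulated
          # knockdown series whose true 1-h temperature is mu
          for (j in seq_len(n_temps)) {
            b_tdt <- stats::runif(1, -0.6, -0.2)
            a_tdt <- -b_tdt * mu[j]
            ser <- simulate_tdt(a_tdt, b_tdt, noise_sd = 0.08, n_points = 6L,
                                seed = sample.int(2^30, 1L))
            conv <- suppressWarnings(tdt_to_heat_tolerance(ser))
            g$mean_ht[j] <- conv$mean_ht
            g$sd[j] <- NA_real_
            g$n[j] <- NA_real_
            g$se[j] <- conv$se
            tdt_series[[length(tdt_series) + 1L]] <-
              list(study_id = study_id, temperature = temps[j], series = ser)
          }
        } else {
          drop_sd <- stats::runif(n_temps) < truth$frac_missing_sd
          se_only <- !drop_sd & stats::runif(n_temps) < truth$frac_se_only
          g$sd[drop_sd] <- NA_real_
          g$se[se_only] <- g$sd[se_only] / sqrt(g$n[se_only])
          g$sd[se_only] <- NA_real_
          g$n[se_only] <- NA_real_
        }
        groups[[length(groups) + 1L]] <- g
        truths[[length(truths) + 1L]] <- data.frame(
          study_id = study_id, species = gsub("_", " ", s),
          t1 = temps[-n_temps], t2 = temps[-1L],
          true_slope = slopes, u_species = unname(u[s]),
          habitat = unname(habitat[s]), timing = timing, year = year,
          mu1 = mu[-n_temps], mu2 = mu[-1L],
          ind_sd1 = ind_sd[-n_temps], ind_sd2 = ind_sd[-1L],
          n1 = n[-n_temps], n2 = n[-1L],
          stringsAsFactors = FALSE
        )
      }
    }
    groups <- do.call(rbind, groups)
    groups$.group_id <- seq_len(nrow(groups))
    truth_effects <- do.call(rbind, truths)
    rownames(groups) <- rownames(truth_effects) <- NULL
    list(groups = groups, truth_effects = truth_effects,
         tdt_series = tdt_series, tree = tree, A = A)
  })
}

#' Censor non-significant effects (induced publication bias)
#'
#' Emulates a file-drawer process: effects whose z-score `|darr|/sqrt(v)`
#' falls below `crit` survive only with probability `keep_prob`. Used to
#' verify that the small-study meta-regression detects induced asymmetry.
#'
#' @param effects Effect-size table.
#' @param crit Significance threshold on the z scale (default 1.96).
#' @param keep_prob Survival probability of a non-significant effect
#'   (default 0.2).
#' @param seed Integer seed.
#' @return The censored effect-size table.
#' @export
censor_nonsignificant <- function(effects, crit = 1.96, keep_prob = 0.2,
                                  seed = 1L) {
  stopifnot(is.data.frame(effects))
  z <- abs(effects$darr) / sqrt(effects$variance)
  local_seed(as.integer(seed), {
    keep <- z >= crit | stats::runif(nrow(effects)) < keep_prob
    effects[keep, , drop = FALSE]
  })
}
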