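GROUP_COLUMNS <- c(
  study_id = "character", species = "character",
  population_id = "character", cohort_id = "character",
  temperature = "numeric", mean_ht = "numeric", sd = "numeric",
  se = "numeric", n = "numeric", metric = "character",
  design = "character", timing = "character", habitat = "character",
  taxon_group = "character", heating_rate = "numeric", year = "numeric",
  source_type = "character", sd_imputed = "logical",
  risk_of_bias = "logical"
)

MANDATORY_COLUMNS <- c("study_id", "species", "temperature", "mean_ht",
                       "metric")

#' Read a group-level summary CSV
#'
#' One row per acclimation-temperature group: developmental temperature,
#' mean heat tolerance, dispersion (sd and/or se), sample size and study
#' metadata. Unknown columns produce a warning and are carried through;
#' missing mandatory columns are an error. Missing values are empty cells.
#' A unique `.group_id` (row number) is attached for shared-treatment
#' bookkeeping.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return Data frame of typed group rows.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty group table: ", path, call. = FALSE)
  missing <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing mandatory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), names(GROUP_COLUMNS))
  if (length(unknown)) {
    warning("unknown columns carried through: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(names(df), names(GROUP_COLUMNS))) {
    df[[col]] <- switch(GROUP_COLUMNS[[col]],
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]),
                        as.character(df[[col]]))
    if (is.character(df[[col]])) df[[col]][df[[col]] == ""] <- NA_character_
  }
  validate_groups(df)
  df$.group_id <- seq_len(nrow(df))
  df
}

validate_groups <- function(df) {
  bad <- !is.finite(df$temperature) | !is.finite(df$mean_ht)
  if (any(bad)) {
    stop("non-finite temperature or mean_ht in rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(df$sd) && any(df$sd < 0, na.rm = TRUE)) {
    stop("negative sd", call. = FALSE)
  }
  if (!is.null(df$se) && any(df$se < 0, na.rm = TRUE)) {
    stop("negative se", call. = FALSE)
  }
  if (!is.null(df$n) && any(df$n < 1, na.rm = TRUE)) {
    stop("sample sizes must be >= 1", call. = FALSE)
  }
  invisible(df)
}

#' Write a group-level table to CSV
#'
#' @param groups Data frame in the [read_groups()] schema.
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  out <- groups[, setdiff(names(groups), ".group_id"), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Serializes fit objects and tables: each `darr_fit` becomes a JSON file
#' (coefficients, variance components, I-squared, prediction intervals) plus
#' a flat TSV coefficient table; plain data frames become TSVs; everything
#' else is JSON. A `run_metadata.json` records seeds, package version and
#' settings. Existing files are not silently overwritten.
#'
#' @param results Named list of `darr_fit` objects, data frames, or
#'   JSON-serializable lists.
#' @param dir Output directory (created if absent).
#' @param meta Named list merged into the run metadata (seeds, config).
#' @param force Overwrite existing files (default FALSE: an existing target
#'   file is an error).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, dir, meta = list(), force = FALSE) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit <- function(path, writer) {
    if (file.exists(path) && !force) {
      stop("refusing to overwrite ", path, " (use force = TRUE)",
           call. = FALSE)
    }
    writer(path)
    written <<- c(written, path)
  }
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "darr_fit")) {
      emit(file.path(dir, paste0(nm, ".json")), function(p)
        jsonlite::write_json(fit_to_list(x), p, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE))
      emit(file.path(dir, paste0(nm, "_coefficients.tsv")), function(p)
        utils::write.table(cbind(term = rownames(t_inference(x)),
                                 t_inference(x)),
                           p, sep = "\t", row.names = FALSE, quote = FALSE))
    } else if (is.data.frame(x)) {
      emit(file.path(dir, paste0(nm, ".tsv")), function(p)
        utils::write.table(x, p, sep = "\t", row.names = FALSE,
                           quote = FALSE, na = ""))
    } else {
      emit(file.path(dir, paste0(nm, ".json")), function(p)
        jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, force = TRUE))
    }
  }
  meta <- c(meta, list(package_version = as.character(
    utils::packageVersion("darrmeta")), written_at = format(Sys.time())))
  emit(file.path(dir, "run_metadata.json"), function(p)
    jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE))
  invisible(written)
}

fit_to_list <- function(fit) {
  list(
    coefficients = as.list(as.data.frame(t_inference(fit))),
    coefficient_names = names(fit$beta),
    variance_components = as.list(fit$sigma2),
    loglik = fit$loglik, aic = fit$aic, k = fit$k, p = fit$p,
    df = fit$df, converged = fit$converged,
    i2 = tryCatch(i2_decomposition(fit)[grep("^i2", names(
      i2_decomposition(fit)))], error = function(e) NULL),
    prediction_intervals = as.list(as.data.frame(prediction_interval(fit)))
  )
}

#' Write a symmetric matrix as TSV with identifier row/column
#'
#' @param M Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full meta-analytic pipeline on a group-level dataset
#'
#' Convenience driver mirroring the standard workflow: sd imputation, TDT
#' rows are assumed already converted, stepwise effect sizes,
#' shared-treatment VCV, Grafen phylogenetic correlation, intercept-only
#' REML fit with heterogeneity decomposition and prediction interval, and
#' (optionally) the habitat post-stratified marginal mean.
#'
#' @param groups Group-level table ([read_groups()] schema).
#' @param tree Species tree (`ape::phylo`) covering all dataset species.
#' @param seed Integer seed (polytomy resolution).
#' @param r_shared Shared-treatment correlation (default 0.5).
#' @param grafen_rho Grafen power (default 1).
#' @param habitat_model Also fit the habitat cell-means model and its
#'   marginal mean (default TRUE when a `habitat` column with 2 levels is
#'   present).
#' @param control [reml_control()].
#' @return List: `effects`, `rejects`, `imputation`, `A`, `overall` (fit),
#'   `i2`, `pi`, and optionally `habitat` (fit) and `habitat_marginal`.
#' @export
run_pipeline <- function(groups, tree, seed = 1L, r_shared = 0.5,
                         grafen_rho = 1, habitat_model = TRUE,
                         control = reml_control()) {
  built <- build_effects(groups, impute = TRUE)
  effects <- built$effects
  tree <- resolve_polytomies(tree, seed)
  A <- phylo_correlation(grafen_lengths(tree, rho = grafen_rho))
  overall <- darr_meta(effects, A = A, fixed = ~1, r_shared = r_shared,
                       control = control)
  out <- list(effects = effects, rejects = built$rejects,
              imputation = built$imputation, A = A, overall = overall,
              i2 = i2_decomposition(overall),
              pi = prediction_interval(overall))
  if (habitat_model && !is.null(effects$habitat) &&
      length(unique(effects$habitat)) == 2L) {
    hab <- darr_meta(effects, A = A, fixed = ~ 0 + habitat,
                     r_shared = r_shared, control = control)
    out$habitat <- hab
    out$habitat_marginal <- marginal_means(hab)
  }
  out
}
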