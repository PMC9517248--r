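# End-to-end orchestration: simulate/read -> preprocess -> LCA -> three-step
# -> mediation (-> bootstrap) -> report, with every artifact written to disk
# alongside seeds and checksums so a run is a pure function of its inputs.

#' Respondent-table CSV input/output
#'
#' Writes a respondent table as CSV with a sidecar JSON data dictionary
#' (category labels, item cardinalities, missing-value code), and reads it
#' back with the factor levels restored from the dictionary.
#'
#' @param df Respondent data frame (e.g. from [generate_population()]).
#' @param path CSV path.
#' @param dict_path JSON dictionary path (default: `path` with
#'   `.dict.json` appended).
#' @return `write_respondents()` returns the paths invisibly;
#'   `read_respondents()` returns the data frame with the dictionary
#'   attached as attribute `"dictionary"`.
#' @export
write_respondents <- function(df, path, dict_path = paste0(path, ".dict.json")) {
  dict <- attr(df, "dictionary")
  if (is.null(dict)) {
    dict <- list(gender = GENDER_LEVELS, age_band = AGE_LEVELS,
                 race_eth = RACE_LEVELS, nativity = NATIVITY_LEVELS,
                 wave = WAVE_LEVELS,
                 items = stats::setNames(
                   vapply(paste0("y", 1:11),
                          function(cn) max(df[[cn]], 2L, na.rm = TRUE), 0L),
                   paste0("y", 1:11)),
                 outcomes = intersect(c("srh_poor", "fmd"), names(df)),
                 missing_code = "NA")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  jsonlite::write_json(dict, dict_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, dict = dict_path))
}

#' @rdname write_respondents
#' @export
read_respondents <- function(path, dict_path = paste0(path, ".dict.json")) {
  dict <- jsonlite::read_json(dict_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, na.strings = "NA", stringsAsFactors = FALSE)
  for (nm in c("gender", "age_band", "race_eth", "nativity", "wave")) {
    if (!is.null(df[[nm]])) df[[nm]] <- factor(df[[nm]], levels = dict[[nm]])
  }
  for (cn in grep("^y[0-9]+$", names(df), value = TRUE))
    df[[cn]] <- as.integer(df[[cn]])
  attr(df, "dictionary") <- dict
  df
}

#' Pipeline run configuration
#'
#' @param out Output directory (created if needed).
#' @param input,dict Input respondent CSV and dictionary paths; leave `NULL`
#'   with `simulate = TRUE` to run on a simulated sample.
#' @param simulate Simulate the calibrated study sample instead of reading
#'   input ([simulate_study_sample()]).
#' @param sim_n Simulated sample size.  At the default 6421 the calibrated
#'   missingness counts are planted ([simulate_study_sample()]); any other
#'   value draws a complete sample of that size from [default_config()].
#' @param outcomes Outcomes to analyze.
#' @param n_classes Number of latent classes.
#' @param n_starts Random starts for the LCA.
#' @param tol LCA convergence tolerance.
#' @param B Bootstrap resamples per outcome (0 disables the bootstrap).
#' @param alpha Interval miscoverage level.
#' @param seed Master seed; per-stage seeds are derived as small offsets.
#' @param fix_measurement Keep Step-1 measurement model and D fixed across
#'   bootstrap resamples (the default and the only supported mode of
#'   [bc_bootstrap()]).
#' @return A `list` of class `eq_run_config`.
#' @export
pipeline_config <- function(out, input = NULL, dict = NULL, simulate = is.null(input),
                            sim_n = 6421L,
                            outcomes = c("srh_poor", "fmd"), n_classes = 6L,
                            n_starts = 20L, tol = 1e-7, B = 0L, alpha = 0.05,
                            seed = 1L, fix_measurement = TRUE) {
  structure(list(out = out, input = input, dict = dict, simulate = simulate,
                 sim_n = as.integer(sim_n),
                 outcomes = match.arg(outcomes, c("srh_poor", "fmd"),
                                      several.ok = TRUE),
                 n_classes = as.integer(n_classes),
                 n_starts = as.integer(n_starts), tol = tol,
                 B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 fix_measurement = isTRUE(fix_measurement)),
            class = "eq_run_config")
}

#' Run the full mediation pipeline
#'
#' Sequences all stages on either a simulated calibrated sample or an input
#' CSV: outcome dichotomization, the eligibility cascade, weighted LCA,
#' the classification-error matrix, the corrected structural model per
#' outcome, the effect decomposition with predicted probability tables, and
#' (when `B > 0`) bias-corrected bootstrap intervals.  All artifacts are
#' written under `config$out` (sample CSV + dictionary, exclusion report,
#' serialized LCA model and D, per-outcome effect and prediction tables,
#' and a run-metadata JSON with seeds, convergence flags, tie counts and
#' file checksums).
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "eq_run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  raw <- if (config$simulate) {
    if (config$sim_n == 6421L) {
      simulate_study_sample(seed = config$seed)
    } else {
      generate_population(default_config(n = config$sim_n, seed = config$seed))
    }
  } else {
    read_respondents(config$input,
                     config$dict %||% paste0(config$input, ".dict.json"))
  }
  raw <- dichotomize_outcomes(raw)
  raw$true_class <- NULL
  excl <- apply_exclusions(raw)
  write_respondents(excl$data, file.path(config$out, "analytic_sample.csv"))
  jsonlite::write_json(unclass(excl$report),
                       file.path(config$out, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  frames <- lapply(config$outcomes, function(oc) encode_covariates(excl$data, oc))
  names(frames) <- config$outcomes
  lca <- fit_lca(frames[[1L]], T = config$n_classes,
                 n_starts = config$n_starts, tol = config$tol,
                 seed = config$seed + 1L)
  post <- posterior_probs(lca, frames[[1L]])
  W <- suppressMessages(modal_assign(post))
  stats <- fit_statistics(lca, frames[[1L]], post)
  err <- classification_error_matrix(post, W, frames[[1L]]$w)
  jsonlite::write_json(
    list(pi = lca$pi, theta = lapply(lca$theta, unname),
         loglik = lca$loglik, converged = lca$converged,
         seed_of_best_start = lca$seed_of_best_start, fit = stats,
         D = unname(err$D), logit_D = unname(err$logit_D),
         floor_used = err$floor_used, n_ties = attr(W, "n_ties")),
    file.path(config$out, "lca_model.json"), auto_unbox = TRUE, digits = NA)
  results <- list()
  for (oc in config$outcomes) {
    frame <- frames[[oc]]
    dec <- if (config$B > 0L) {
      bc_bootstrap(frame, W, err, B = config$B, alpha = config$alpha,
                   seed = config$seed + 2L)
    } else {
      fit <- fit_structural(frame, W, err)
      d <- decompose(fit, frame)
      d$model <- fit
      d
    }
    pred <- predicted_tables(dec$model, frame)
    eff <- dec$effects
    eff$or <- dec$ors$or[match(eff$effect, dec$ors$effect)]
    if (!is.null(dec$ci)) {
      eff$pd_lower <- dec$ci$pd_lower
      eff$pd_upper <- dec$ci$pd_upper
    }
    utils::write.csv(eff, file.path(config$out, paste0("effects_", oc, ".csv")),
                     row.names = FALSE)
    ptab <- data.frame(class = seq_len(config$n_classes),
                       class_dist_woman = pred$class_dist[, "woman"],
                       class_dist_man = pred$class_dist[, "man"],
                       outcome_woman = pred$outcome_probs[, "woman"],
                       outcome_man = pred$outcome_probs[, "man"])
    utils::write.csv(ptab,
                     file.path(config$out, paste0("predicted_", oc, ".csv")),
                     row.names = FALSE)
    results[[oc]] <- list(decomposition = dec, predicted = pred)
  }
  files <- list.files(config$out, full.names = TRUE)
  files <- files[!grepl("run_metadata[.]json$", files)]
  meta <- list(
    seed = config$seed, n_classes = config$n_classes, B = config$B,
    alpha = config$alpha, outcomes = config$outcomes,
    exclusions = unclass(excl$report),
    lca_converged = lca$converged, n_posterior_ties = attr(W, "n_ties"),
    d_floor_used = err$floor_used,
    structural_converged = vapply(results,
                                  function(r) r$decomposition$model$converged,
                                  TRUE),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(meta, file.path(config$out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(raw = raw, exclusions = excl$report, lca = lca,
                 posterior = post, W = W, error_matrix = err,
                 fit_stats = stats, results = results, metadata = meta))
}
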