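# Counterfactual effect decomposition for a nominal mediator.
#
# With mu(a, a*) = E[Y(a, M(a*))]:
#   TE     = mu(w, w) - mu(m, m)          total effect
#   PDE    = mu(w, m) - mu(m, m)          pure direct effect
#   TIE    = mu(w, w) - mu(w, m)          total indirect effect
#   PIE    = mu(m, w) - mu(m, m)          pure indirect effect
#   INTmed = TIE - PIE                    mediated interaction
# so TE = PDE + TIE and TIE = PIE + INTmed identically.  Positive
# probability differences indicate worse expected health among women (men
# are the reference).

new_decomposition <- function(means, alpha = NULL) {
  pde <- means["wm"] - means["mm"]
  tie <- means["ww"] - means["wm"]
  pie <- means["mw"] - means["mm"]
  effects <- data.frame(
    effect = c("TE", "PDE", "TIE", "PIE", "INTmed"),
    pd = unname(c(pde + tie, pde, tie, pie, tie - pie)),
    row.names = NULL
  )
  ors <- data.frame(
    effect = c("TE", "PDE", "TIE"),
    or = unname(c(odds(means["ww"]) / odds(means["mm"]),
                  odds(means["wm"]) / odds(means["mm"]),
                  odds(means["ww"]) / odds(means["wm"]))),
    row.names = NULL
  )
  structure(list(means = means, effects = effects, ors = ors),
            class = "eq_decomposition")
}

#' Decompose the gender-health effect from a fitted structural model
#'
#' Computes the four counterfactual means by [counterfactual_mean()] and
#' the five-effect decomposition on the probability-difference scale, plus
#' odds ratios for TE, PDE and TIE formed from the corresponding marginal
#' counterfactual probabilities.
#'
#' @param model An `eq_structural` fit.
#' @param frame The `eq_frame` defining the standardization population.
#' @return An object of class `eq_decomposition` with elements `means`
#'   (named `mm`, `mw`, `wm`, `ww`, indexed as `a` then `a_star`),
#'   `effects` (probability differences) and `ors`.
#' @export
decompose <- function(model, frame) {
  means <- c(
    mm = counterfactual_mean(model, frame, "man", "man"),
    mw = counterfactual_mean(model, frame, "man", "woman"),
    wm = counterfactual_mean(model, frame, "woman", "man"),
    ww = counterfactual_mean(model, frame, "woman", "woman")
  )
  new_decomposition(means)
}

#' Decompose directly from marginal class and outcome probabilities
#'
#' Applies the decomposition formulas to per-class marginal quantities, as
#' when working from a published table of predicted probabilities:
#' `TIE = sum_t [P(t|woman) - P(t|man)] P(Y|woman, t)`,
#' `PIE = sum_t [P(t|woman) - P(t|man)] P(Y|man, t)`,
#' `PDE = sum_t P(t|man) [P(Y|woman, t) - P(Y|man, t)]`,
#' `INTmed = TIE - PIE`, `TE = PDE + TIE`.  Equivalent to [decompose()]
#' when there are no confounders (averaging commutes).
#'
#' @param class_dist `T x 2` matrix of class-membership probabilities with
#'   columns `woman` and `man` (each summing to 1).
#' @param outcome_probs `T x 2` matrix of outcome probabilities with the
#'   same column layout.
#' @return An `eq_decomposition`.
#' @export
#' @examples
#' cal <- default_calibration()
#' decompose_from_probabilities(cal$class_dist, cal$outcome_probs$srh_poor)
decompose_from_probabilities <- function(class_dist, outcome_probs) {
  cd <- as.matrix(class_dist); op <- as.matrix(outcome_probs)
  colnames(cd) <- sub("^women$", "woman", sub("^men$", "man", colnames(cd)))
  colnames(op) <- sub("^women$", "woman", sub("^men$", "man", colnames(op)))
  if (!all(c("woman", "man") %in% colnames(cd)) ||
      !all(c("woman", "man") %in% colnames(op)))
    stop("columns must be named 'woman' and 'man'", call. = FALSE)
  if (any(abs(colSums(cd) - 1) > 1e-6))
    stop("class distributions must sum to 1 per gender", call. = FALSE)
  if (any(op < 0 | op > 1))
    stop("outcome probabilities must lie in [0, 1]", call. = FALSE)
  pw <- cd[, "woman"]; pm <- cd[, "man"]
  qw <- op[, "woman"]; qm <- op[, "man"]
  means <- c(mm = sum(pm * qm), mw = sum(pw * qm),
             wm = sum(pm * qw), ww = sum(pw * qw))
  new_decomposition(means)
}

#' Model-predicted class and outcome probability tables
#'
#' Standardized summaries of a fitted structural model: the predicted EQ
#' class distribution by gender and the predicted outcome probability by
#' gender and class, each a survey-weighted average over the analytic
#' sample's confounder rows.
#'
#' @param model An `eq_structural` fit.
#' @param frame The `eq_frame` defining the standardization population.
#' @return An object of class `eq_predicted`: `class_dist` (`T x 2`, columns
#'   `woman`/`man`, columns sum to 1) and `outcome_probs` (`T x 2`).
#' @export
predicted_tables <- function(model, frame) {
  n <- frame$n; conf <- frame$conf; T <- model$T
  wsum <- sum(frame$w)
  cd <- sapply(c(woman = 1, man = 0), function(a) {
    p <- class_probs(model$gamma, rep(a, n), conf)
    colSums(p * frame$w) / wsum
  })
  op <- sapply(c(woman = 1, man = 0), function(a) {
    vapply(seq_len(T), function(t) {
      Z <- beta_design_at(rep(a, n), t, T, conf)
      sum(frame$w * stats::plogis(drop(Z %*% model$beta))) / wsum
    }, 0)
  })
  structure(list(class_dist = cd, outcome_probs = op,
                 outcome = model$outcome),
            class = "eq_predicted")
}

#' @export
print.eq_predicted <- function(x, ...) {
  cat("Predicted EQ distribution by gender (columns sum to 1):\n")
  print(round(x$class_dist, 3))
  cat("\nPredicted P(", x$outcome, " = 1) by gender and class:\n", sep = "")
  print(round(x$outcome_probs, 3))
  invisible(x)
}

#' @export
print.eq_decomposition <- function(x, ...) {
  cat("Counterfactual effect decomposition",
      "(positive = worse expected health among women)\n")
  tab <- x$effects
  tab$or <- x$ors$or[match(tab$effect, x$ors$effect)]
  if (!is.null(x$ci)) {
    tab$ci_lower <- x$ci$pd_lower
    tab$ci_upper <- x$ci$pd_upper
  }
  print(tab, digits = 3, row.names = FALSE)
  invisible(x)
}
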