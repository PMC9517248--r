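# Design-matrix conventions shared by the generator and the structural model.
#
# Mediator (multinomial) design, per respondent:
#   (intercept, A, confounder dummies)              length 2 + 11
# Outcome (logistic) design, per respondent and class t:
#   (intercept, A, I[class = 2..T], A * I[class = 2..T], confounder dummies)
# Reference levels: man; age 30-50; white; US-born; wave 2002; class 1
# (SER-like).

conf_dummies <- function(df) {
  m <- cbind(
    age_lt30 = as.numeric(df$age_band == "<30"),
    age_gt50 = as.numeric(df$age_band == ">50"),
    race_black = as.numeric(df$race_eth == "black"),
    race_hispanic = as.numeric(df$race_eth == "hispanic"),
    race_asian_pi = as.numeric(df$race_eth == "asian_pi"),
    race_aian = as.numeric(df$race_eth == "aian"),
    nativity_foreign = as.numeric(df$nativity == "foreign_born"),
    wave_2006 = as.numeric(df$wave == "2006"),
    wave_2010 = as.numeric(df$wave == "2010"),
    wave_2014 = as.numeric(df$wave == "2014"),
    wave_2018 = as.numeric(df$wave == "2018")
  )
  storage.mode(m) <- "double"
  m
}

gamma_design <- function(A, conf) {
  cbind(intercept = 1, woman = A, conf)
}

#' Coefficient layouts of the structural models
#'
#' `gamma_coef_names()` gives the column order of the multinomial
#' class-membership coefficients (one row per non-reference class);
#' `beta_coef_names(T)` gives the order of the logistic outcome
#' coefficients for a `T`-class model.  Use these when building
#' `gamma_true`/`beta_true` for [eq_config()].
#'
#' @param T Number of classes.
#' @return Character vector of coefficient names.
#' @export
gamma_coef_names <- function() c("intercept", "woman", CONF_DUMMY_NAMES)

#' @rdname gamma_coef_names
#' @export
beta_coef_names <- function(T) {
  cls <- paste0("class", 2:T)
  c("intercept", "woman", cls, paste0("woman_x_", cls), CONF_DUMMY_NAMES)
}

#' Outcome-model design matrices
#'
#' `beta_design_at()` evaluates the logistic outcome design for every
#' respondent at a fixed mediator class `t`; `beta_design_obs()` uses an
#' observed class vector.  Columns follow [beta_coef_names()].
#'
#' @param A Exposure vector (0 = man, 1 = woman).
#' @param t Fixed class index.
#' @param class Observed class vector.
#' @param T Number of classes.
#' @param conf Confounder dummy matrix (see [conf_dummy_names()]).
#' @return Numeric design matrix.
#' @export
beta_design_at <- function(A, t, T, conf) {
  n <- length(A)
  cls <- matrix(0, n, T - 1)
  if (t > 1L) cls[, t - 1L] <- 1
  out <- cbind(1, A, cls, A * cls, conf)
  colnames(out) <- beta_coef_names(T)
  out
}

#' @rdname beta_design_at
#' @export
beta_design_obs <- function(A, class, T, conf) {
  n <- length(A)
  cls <- matrix(0, n, T - 1)
  for (t in 2:T) cls[, t - 1L] <- as.numeric(class == t)
  out <- cbind(1, A, cls, A * cls, conf)
  colnames(out) <- beta_coef_names(T)
  out
}

# Class-membership probabilities under the multinomial-logit model.
# gamma: (T-1) x P matrix, reference class 1 has coefficients 0.
class_probs <- function(gamma, A, conf) {
  Xg <- gamma_design(A, conf)
  softmax_rows(cbind(0, Xg %*% t(gamma)))
}
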