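#' Construct a synthetic-sample generator configuration
#'
#' Bundles every parameter of the data-generating process: the multinomial
#' class-membership model, the item-response (measurement) model, the two
#' logistic outcome models with gender-by-class interaction, confounder
#' margins, survey-weight law and missingness rates.
#'
#' @param n Number of respondents to generate.
#' @param T Number of latent employment-quality classes (default 6).
#' @param gamma_true `(T-1) x 13` matrix of multinomial-logit coefficients
#'   for class membership (reference class 1): columns are intercept, woman,
#'   and the 11 confounder dummies (see [conf_dummy_names()]).
#' @param theta_true list of 11 item-response matrices, each `T x K_j`, rows
#'   summing to 1: `theta_true[[j]][t, k] = P(item j = k | class t)`.
#' @param beta_true named list (one element per outcome, e.g. `srh_poor`,
#'   `fmd`) of logistic coefficient vectors of length `2 + 2(T-1) + 11`:
#'   intercept, woman, class main effects, woman-by-class interactions,
#'   confounder dummies.
#' @param confounder_marginals list with elements `age_band`, `race_eth`,
#'   `nativity`, `wave`; each either a probability vector or a 2-row matrix
#'   (rows `man`, `woman`) for gender-dependent margins.
#' @param prop_women Probability that a respondent is a woman.
#' @param missing_rates list with `items` (length-11 vector of per-item MCAR
#'   rates), and scalar rates `srh_poor`, `fmd`, `age`.
#' @param weight_law list; `list(type = "constant")` for unit weights or
#'   `list(type = "lognormal", sdlog = s)` for mean-1 lognormal weights.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `eq_config` (a validated list).
#' @seealso [default_config()], [generate_population()]
#' @export
eq_config <- function(n, T = 6L, gamma_true, theta_true, beta_true,
                      confounder_marginals = default_calibration()$confounder_marginals,
                      prop_women = 0.5,
                      missing_rates = list(items = rep(0, 11),
                                           srh_poor = 0, fmd = 0, age = 0),
                      weight_law = list(type = "constant"),
                      seed = 1L) {
  cfg <- structure(list(n = as.integer(n), T = as.integer(T),
                        gamma_true = gamma_true, theta_true = theta_true,
                        beta_true = beta_true,
                        confounder_marginals = confounder_marginals,
                        prop_women = prop_women,
                        missing_rates = missing_rates,
                        weight_law = weight_law, seed = as.integer(seed)),
                   class = "eq_config")
  validate_config(cfg)
  cfg
}

#' @rdname eq_config
#' @export
conf_dummy_names <- function() CONF_DUMMY_NAMES

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n) || cfg$n < 1) config_error("n", "must be >= 1")
  if (!is.numeric(cfg$T) || cfg$T < 2) config_error("T", "must be >= 2")
  T <- cfg$T
  P <- 2L + length(CONF_DUMMY_NAMES)
  g <- cfg$gamma_true
  if (!is.matrix(g) || nrow(g) != T - 1L || ncol(g) != P)
    config_error("gamma_true", sprintf("must be a (T-1) x %d matrix", P))
  th <- cfg$theta_true
  if (!is.list(th) || length(th) != 11L)
    config_error("theta_true", "must be a list of 11 item-response matrices")
  for (j in seq_along(th)) {
    m <- th[[j]]
    if (!is.matrix(m) || nrow(m) != T || ncol(m) < 2L)
      config_error("theta_true",
                   sprintf("item %d must be a T x K matrix with K >= 2", j))
    if (any(abs(rowSums(m) - 1) > 1e-12) || any(m < 0))
      config_error("theta_true",
                   sprintf("item %d rows must be probability vectors", j))
  }
  Q <- 2L + 2L * (T - 1L) + length(CONF_DUMMY_NAMES)
  if (!is.list(cfg$beta_true) || !length(cfg$beta_true))
    config_error("beta_true", "must be a non-empty named list")
  for (nm in names(cfg$beta_true)) {
    if (length(cfg$beta_true[[nm]]) != Q)
      config_error("beta_true", sprintf("element '%s' must have length %d", nm, Q))
  }
  cm <- cfg$confounder_marginals
  need <- list(age_band = 3L, race_eth = 5L, nativity = 2L, wave = 5L)
  for (nm in names(need)) {
    v <- cm[[nm]]
    if (is.null(v)) config_error("confounder_marginals", paste("missing", nm))
    vv <- if (is.matrix(v)) v else matrix(v, 1L)
    if (ncol(vv) != need[[nm]])
      config_error("confounder_marginals",
                   sprintf("'%s' must have %d categories", nm, need[[nm]]))
    if (any(abs(rowSums(vv) - 1) > 1e-12) || any(vv < 0))
      config_error("confounder_marginals",
                   sprintf("'%s' rows must sum to 1", nm))
  }
  if (cfg$prop_women < 0 || cfg$prop_women > 1)
    config_error("prop_women", "must be in [0, 1]")
  mr <- cfg$missing_rates
  rates <- c(mr$items, mr$srh_poor, mr$fmd, mr$age %||% 0)
  if (length(mr$items) != 11L)
    config_error("missing_rates", "items must have length 11")
  if (any(rates < 0) || any(rates >= 1))
    config_error("missing_rates", "rates must lie in [0, 1)")
  if (!cfg$weight_law$type %in% c("constant", "lognormal"))
    config_error("weight_law", "type must be 'constant' or 'lognormal'")
  invisible(cfg)
}

#' Default item-response profiles of the six EQ classes
#'
#' Eleven indicators mixing binary and 3-category items, spanning the
#' contractual and relational dimensions of employment quality: permanent
#' contract, income band, weekly hours, irregular shifts, mandatory extra
#' hours, development opportunity, union representation, schedule control,
#' decision involvement, workplace harassment, adequate resources.  Class
#' profiles follow the qualitative character of the six types (SER-like,
#' Portfolio, Inflexible skilled, Dead-end, Precarious, Optimistic
#' precarious).
#'
#' @return List of 11 matrices (`6 x K_j`, rows summing to 1).
#' @export
default_theta <- function() {
  bin <- function(p) cbind(p, 1 - p)
  tri <- function(m) m / rowSums(m)
  list(
    permanent   = bin(c(0.95, 0.95, 0.90, 0.95, 0.25, 0.30)),
    income      = tri(rbind(c(.15, .60, .25), c(.05, .25, .70), c(.10, .30, .60),
                            c(.30, .55, .15), c(.75, .20, .05), c(.60, .30, .10))),
    hours       = tri(rbind(c(.10, .75, .15), c(.02, .38, .60), c(.05, .40, .55),
                            c(.10, .70, .20), c(.60, .35, .05), c(.55, .35, .10))),
    irregular   = bin(c(0.15, 0.15, 0.70, 0.30, 0.65, 0.50)),
    extra_hours = bin(c(0.20, 0.50, 0.75, 0.35, 0.15, 0.10)),
    development = tri(rbind(c(.20, .50, .30), c(.05, .25, .70), c(.15, .35, .50),
                            c(.70, .25, .05), c(.70, .25, .05), c(.10, .30, .60))),
    union       = bin(c(0.15, 0.10, 0.55, 0.50, 0.05, 0.05)),
    sched_ctrl  = tri(rbind(c(.35, .45, .20), c(.05, .35, .60), c(.70, .25, .05),
                            c(.70, .25, .05), c(.75, .20, .05), c(.15, .35, .50))),
    involvement = bin(c(0.55, 0.90, 0.70, 0.15, 0.15, 0.70)),
    harassment  = bin(c(0.10, 0.08, 0.35, 0.40, 0.35, 0.10)),
    resources   = bin(c(0.90, 0.90, 0.75, 0.50, 0.60, 0.80))
  )
}

#' Default calibrated generator configuration
#'
#' Builds the package's reference data-generating process: six EQ classes
#' whose gender-specific membership distributions and class-specific outcome
#' probabilities equal the calibration targets of [default_calibration()].
#' Class-model (`gamma`) and outcome-model (`beta`) coefficients are
#' back-solved exactly by inverting the multinomial/logistic links on the
#' confounder-free reduced model; confounder and wave coefficients are zero,
#' so the implied marginal tables equal the targets exactly while the
#' covariates still flow through every downstream model as adjustment terms.
#'
#' @param n Sample size (default: the calibrated analytic n, 6367).
#' @param seed Integer seed stored in the configuration.
#' @param weight_law Passed to [eq_config()].
#' @param missing_rates Passed to [eq_config()]; defaults to no missingness.
#' @return An `eq_config` object.
#' @export
#' @examples
#' cfg <- default_config(n = 500, seed = 7)
#' pop <- generate_population(cfg)
#' table(pop$gender)
default_config <- function(n = 6367L, seed = 1L,
                           weight_law = list(type = "constant"),
                           missing_rates = list(items = rep(0, 11),
                                                srh_poor = 0, fmd = 0, age = 0)) {
  cal <- default_calibration()
  T <- 6L
  pw <- cal$class_dist[, "woman"]
  pm <- cal$class_dist[, "man"]
  gamma <- matrix(0, T - 1L, 2L + length(CONF_DUMMY_NAMES),
                  dimnames = list(paste0("class", 2:T), gamma_coef_names()))
  gamma[, "intercept"] <- log(pm[-1] / pm[1])
  gamma[, "woman"] <- log(pw[-1] / pw[1]) - gamma[, "intercept"]
  beta <- lapply(cal$outcome_probs, function(tab) {
    lw <- stats::qlogis(tab[, "woman"])
    lm <- stats::qlogis(tab[, "man"])
    b <- stats::setNames(numeric(2L + 2L * (T - 1L) + length(CONF_DUMMY_NAMES)),
                         beta_coef_names(T))
    b["intercept"] <- lm[1]
    b["woman"] <- lw[1] - lm[1]
    b[paste0("class", 2:T)] <- lm[-1] - lm[1]
    b[paste0("woman_x_class", 2:T)] <- (lw[-1] - lm[-1]) - b["woman"]
    b
  })
  eq_config(n = n, T = T, gamma_true = gamma, theta_true = default_theta(),
            beta_true = beta,
            confounder_marginals = cal$confounder_marginals,
            prop_women = cal$sample$prop_women,
            missing_rates = missing_rates, weight_law = weight_law,
            seed = seed)
}

draw_categorical <- function(marginal, levels, A) {
  n <- length(A)
  if (is.matrix(marginal)) {
    p <- marginal[match(ifelse(A == 1, "woman", "man"), rownames(marginal)), ,
                  drop = FALSE]
  } else {
    p <- matrix(marginal, n, length(marginal), byrow = TRUE)
  }
  factor(levels[sample_rows(p)], levels = levels)
}

#' Generate a synthetic respondent sample
#'
#' Draws `config$n` respondents: gender, confounders, a true latent EQ class
#' from the multinomial model, 11 categorical item responses from the
#' measurement model, the binary outcomes from the logistic models (with
#' gender-by-class interaction), survey weights, and finally MCAR
#' missingness.  Byte-identical output is returned for identical
#' configurations (the seed lives in the config).
#'
#' @param config An [eq_config()] object.
#' @return A data frame with columns `id`, `gender`, `age_band`, `race_eth`,
#'   `nativity`, `wave`, `weight`, `y1`..`y11`, one column per outcome in
#'   `config$beta_true`, and `true_class` (hidden ground truth; drop before
#'   estimation to emulate real data).  A data dictionary is attached as
#'   attribute `"dictionary"`.
#' @export
generate_population <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n
  T <- config$T
  A <- stats::rbinom(n, 1L, config$prop_women)
  cm <- config$confounder_marginals
  df <- data.frame(
    id = seq_len(n),
    gender = factor(GENDER_LEVELS[A + 1L], levels = GENDER_LEVELS),
    age_band = draw_categorical(cm$age_band, AGE_LEVELS, A),
    race_eth = draw_categorical(cm$race_eth, RACE_LEVELS, A),
    nativity = draw_categorical(cm$nativity, NATIVITY_LEVELS, A),
    wave = draw_categorical(cm$wave, WAVE_LEVELS, A),
    stringsAsFactors = FALSE
  )
  conf <- conf_dummies(df)
  p_class <- class_probs(config$gamma_true, A, conf)
  cls <- sample_rows(p_class)
  items <- matrix(NA_integer_, n, 11L,
                  dimnames = list(NULL, paste0("y", 1:11)))
  for (j in 1:11) {
    items[, j] <- sample_rows(config$theta_true[[j]][cls, , drop = FALSE])
  }
  df$weight <- switch(config$weight_law$type,
    constant = rep(1, n),
    lognormal = {
      s <- config$weight_law$sdlog %||% 0.5
      stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    }
  )
  outcomes <- names(config$beta_true)
  for (nm in outcomes) {
    Z <- beta_design_obs(A, cls, T, conf)
    p <- stats::plogis(drop(Z %*% config$beta_true[[nm]]))
    df[[nm]] <- stats::rbinom(n, 1L, p)
  }
  # MCAR missingness, applied after generation.
  mr <- config$missing_rates
  for (j in 1:11) {
    if (mr$items[j] > 0)
      items[stats::runif(n) < mr$items[j], j] <- NA_integer_
  }
  for (nm in outcomes) {
    rate <- mr[[nm]] %||% 0
    if (rate > 0) df[[nm]][stats::runif(n) < rate] <- NA_integer_
  }
  if ((mr$age %||% 0) > 0)
    df$age_band[stats::runif(n) < mr$age] <- NA
  out <- cbind(df[, c("id", "gender", "age_band", "race_eth", "nativity",
                      "wave", "weight")],
               as.data.frame(items), df[outcomes])
  out$true_class <- cls
  attr(out, "dictionary") <- build_dictionary(config)
  out
}

build_dictionary <- function(config) {
  list(
    gender = GENDER_LEVELS, age_band = AGE_LEVELS, race_eth = RACE_LEVELS,
    nativity = NATIVITY_LEVELS, wave = WAVE_LEVELS,
    items = stats::setNames(vapply(config$theta_true, ncol, 0L),
                            paste0("y", 1:11)),
    outcomes = names(config$beta_true),
    missing_code = "NA"
  )
}

#' Simulate the calibrated study sample with its missingness profile
#'
#' Generates an initial sample of 6421 respondents from [default_config()]
#' and plants the calibrated missingness pattern as exact counts on disjoint
#' row sets: 32 respondents with fewer than two observed EQ indicators, 22
#' missing age, and (within the remaining analytic rows) 32 missing poor
#' self-rated health and 71 missing frequent mental distress.  Background
#' item-level MCAR missingness (rate `item_rate`) is applied first, capped so
#' no row falls below two observed indicators by chance.
#'
#' @param seed Integer seed.
#' @param item_rate Background per-item MCAR missingness rate.
#' @param weight_law Passed to [default_config()].
#' @return A respondent data frame of 6421 rows, ready for
#'   [apply_exclusions()].
#' @export
simulate_study_sample <- function(seed = 1L, item_rate = 0.05,
                                  weight_law = list(type = "constant")) {
  cal <- default_calibration()$sample
  cfg <- default_config(n = cal$n_initial, seed = seed, weight_law = weight_law)
  pop <- generate_population(cfg)
  set.seed(seed + 1L)
  item_cols <- paste0("y", 1:11)
  items <- as.matrix(pop[item_cols])
  if (item_rate > 0) {
    miss <- matrix(stats::runif(length(items)) < item_rate, nrow(items))
    # keep at least two observed indicators per row
    over <- rowSums(miss) > 9L
    if (any(over)) {
      for (i in which(over)) {
        keep <- sample(which(miss[i, ]), rowSums(miss)[i] - 9L)
        miss[i, keep] <- FALSE
      }
    }
    items[miss] <- NA_integer_
  }
  n <- nrow(pop)
  m <- cal$missing
  pick <- sample(n, m$indicators + m$age)
  ind_rows <- pick[seq_len(m$indicators)]
  age_rows <- pick[m$indicators + seq_len(m$age)]
  for (i in ind_rows) {
    keep <- sample(11L, 1L)          # leave a single observed indicator
    items[i, -keep] <- NA_integer_
  }
  pop[item_cols] <- items
  pop$age_band[age_rows] <- NA
  analytic <- setdiff(seq_len(n), pick)
  srh_rows <- sample(analytic, m$srh_poor)
  fmd_rows <- sample(analytic, m$fmd)
  pop$srh_poor[srh_rows] <- NA_integer_
  pop$fmd[fmd_rows] <- NA_integer_
  pop
}

#' Brute-force Monte-Carlo oracle for the true counterfactual effects
#'
#' Computes, by direct simulation from a generator configuration, the four
#' counterfactual outcome means `E[Y(a, M(a*))]` for gender assignments
#' `(a, a*)` in \{man, woman\}^2, and the implied effect decomposition:
#' total effect `TE`, pure direct effect `PDE`, total indirect effect `TIE`,
#' pure indirect effect `PIE`, and mediated interaction `INTmed = TIE - PIE`.
#' Confounders are drawn once and shared across scenarios; within each
#' scenario the class is drawn under gender `a*` and the Bernoulli outcome
#' under gender `a` and that class.  `TE = PDE + TIE` and
#' `TIE = PIE + INTmed` hold exactly by construction.
#'
#' @param config An [eq_config()] object.
#' @param n_mc Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed.
#' @return An object of class `eq_true_effects`: per outcome, a list with
#'   `means` (2 x 2 matrix indexed by `a`, `a_star`) and `effects` (data
#'   frame with columns `effect`, `estimate`, `mc_se`).
#' @export
true_effect_oracle <- function(config, n_mc = 20000L, seed = 1L) {
  validate_config(config)
  stopifnot(n_mc >= 1000L)
  set.seed(seed)
  n_mc <- as.integer(n_mc)
  T <- config$T
  cm <- config$confounder_marginals
  # Pooled confounder distribution (mixing gender-specific margins if given).
  Apool <- stats::rbinom(n_mc, 1L, config$prop_women)
  df <- data.frame(
    age_band = draw_categorical(cm$age_band, AGE_LEVELS, Apool),
    race_eth = draw_categorical(cm$race_eth, RACE_LEVELS, Apool),
    nativity = draw_categorical(cm$nativity, NATIVITY_LEVELS, Apool),
    wave = draw_categorical(cm$wave, WAVE_LEVELS, Apool)
  )
  conf <- conf_dummies(df)
  scen <- list(mm = c(0, 0), mw = c(0, 1), wm = c(1, 0), ww = c(1, 1))
  cls_for <- list()
  for (astar in c(0, 1)) {
    p <- class_probs(config$gamma_true, rep(astar, n_mc), conf)
    cls_for[[as.character(astar)]] <- sample_rows(p)
  }
  out <- list()
  for (nm in names(config$beta_true)) {
    y <- list()
    for (s in names(scen)) {
      a <- scen[[s]][1]; astar <- scen[[s]][2]
      cls <- cls_for[[as.character(astar)]]
      Z <- beta_design_obs(rep(a, n_mc), cls, T, conf)
      p <- stats::plogis(drop(Z %*% config$beta_true[[nm]]))
      y[[s]] <- stats::rbinom(n_mc, 1L, p)
    }
    means <- matrix(c(mean(y$mm), mean(y$mw), mean(y$wm), mean(y$ww)), 2, 2,
                    byrow = TRUE,
                    dimnames = list(a = c("man", "woman"),
                                    a_star = c("man", "woman")))
    per_draw <- list(
      TE = y$ww - y$mm,
      PDE = y$wm - y$mm,
      TIE = y$ww - y$wm,
      PIE = y$mw - y$mm,
      INTmed = (y$ww - y$wm) - (y$mw - y$mm)
    )
    eff <- data.frame(
      effect = names(per_draw),
      estimate = vapply(per_draw, mean, 0),
      mc_se = vapply(per_draw, function(v) stats::sd(v) / sqrt(n_mc), 0),
      row.names = NULL
    )
    out[[nm]] <- list(means = means, effects = eff)
  }
  structure(list(outcomes = out, n_mc = n_mc, seed = seed),
            class = "eq_true_effects")
}

#' @export
print.eq_true_effects <- function(x, ...) {
  cat("True counterfactual effects (Monte-Carlo oracle, n_mc =",
      x$n_mc, ")\n")
  for (nm in names(x$outcomes)) {
    cat("\nOutcome:", nm, "\n")
    print(x$outcomes[[nm]]$effects, digits = 4)
  }
  invisible(x)
}
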