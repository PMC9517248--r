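# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Mid-sized calibrated sample with the full Step-1/Step-2 chain fitted.
study_fixture <- function() {
  memo("study", {
    cfg <- default_config(n = 1500, seed = 101,
                          missing_rates = list(items = rep(0.03, 11),
                                               srh_poor = 0.005, fmd = 0.01,
                                               age = 0))
    pop <- generate_population(cfg)
    ex <- apply_exclusions(dichotomize_outcomes(pop))
    frame <- encode_covariates(ex$data, "srh_poor")
    lca <- fit_lca(frame, T = 6, n_starts = 2, seed = 7)
    post <- posterior_probs(lca, frame)
    W <- suppressMessages(modal_assign(post))
    err <- classification_error_matrix(post, W, frame$w)
    list(cfg = cfg, pop = pop, exclusions = ex, frame = frame,
         lca = lca, post = post, W = W, err = err)
  })
}

# Scaled-down bootstrap on the study fixture (shared across test files).
boot_fixture <- function() {
  memo("boot", {
    fx <- study_fixture()
    suppressWarnings(bc_bootstrap(fx$frame, fx$W, fx$err, B = 100, seed = 17))
  })
}

# Confounder-free two-class configuration matching the hand-enumerable
# example: P(class2 | woman) = 0.3, P(class2 | man) = 0.6,
# P(Y | woman, class) = (0.1, 0.3), P(Y | man, class) = (0.2, 0.2),
# so TIE = -0.06, PIE = 0, PDE = +0.02, INTmed = -0.06, TE = -0.04.
hand_config <- function(n = 5000, seed = 11) {
  T <- 2L
  gamma <- matrix(0, 1, 13, dimnames = list("class2", gamma_coef_names()))
  gamma[1, "intercept"] <- log(0.6 / 0.4)
  gamma[1, "woman"] <- log(0.3 / 0.7) - gamma[1, "intercept"]
  b <- stats::setNames(numeric(15), beta_coef_names(T))
  b["intercept"] <- stats::qlogis(0.2)
  b["woman"] <- stats::qlogis(0.1) - stats::qlogis(0.2)
  b["class2"] <- 0
  b["woman_x_class2"] <- (stats::qlogis(0.3) - stats::qlogis(0.2)) - b["woman"]
  theta2 <- lapply(default_theta(), function(m) m[c(1, 5), , drop = FALSE])
  eq_config(n = n, T = T, gamma_true = gamma, theta_true = theta2,
            beta_true = list(srh_poor = b), prop_women = 0.5, seed = seed)
}

# Tiny data frame with every confounder at its reference level, for
# closed-form checks that should not involve standardization.
reference_frame <- function(n = 4, outcome = "srh_poor") {
  df <- data.frame(
    id = seq_len(n),
    gender = factor(rep(c("man", "woman"), length.out = n),
                    levels = c("man", "woman")),
    age_band = factor("30-50", levels = c("<30", "30-50", ">50")),
    race_eth = factor("white", levels = c("white", "black", "hispanic",
                                          "asian_pi", "aian")),
    nativity = factor("us_born", levels = c("us_born", "foreign_born")),
    wave = factor("2002", levels = c("2002", "2006", "2010", "2014", "2018")),
    weight = 1
  )
  for (j in 1:11) df[[paste0("y", j)]] <- 1L
  df$srh_poor <- 0L
  df$fmd <- 0L
  encode_covariates(df, outcome)
}

# Hand-built two-class structural model on the reference frame.
hand_structural <- function(p_cls2_man = 0.6, p_cls2_woman = 0.3,
                            py_man = c(0.2, 0.2), py_woman = c(0.1, 0.3)) {
  gamma <- matrix(0, 1, 13, dimnames = list("class2", gamma_coef_names()))
  gamma[1, "intercept"] <- stats::qlogis(p_cls2_man)
  gamma[1, "woman"] <- stats::qlogis(p_cls2_woman) - stats::qlogis(p_cls2_man)
  b <- stats::setNames(numeric(15), beta_coef_names(2L))
  b["intercept"] <- stats::qlogis(py_man[1])
  b["woman"] <- stats::qlogis(py_woman[1]) - stats::qlogis(py_man[1])
  b["class2"] <- stats::qlogis(py_man[2]) - stats::qlogis(py_man[1])
  b["woman_x_class2"] <- stats::qlogis(py_woman[2]) - stats::qlogis(py_man[2]) -
    b["woman"]
  structure(list(gamma = gamma, beta = b, T = 2L, outcome = "srh_poor",
                 loglik = NA_real_, converged = TRUE),
            class = "eq_structural")
}
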