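# Step 3: joint estimation of the mediator and outcome regressions with the
# latent class as mediator, correcting for classification error in the modal
# assignment W via the fixed matrix D (Vermunt's ML three-step correction).
#
# Observed-data weighted log-likelihood:
#   sum_i w_i log sum_t P(X=t | A_i, C_i; gamma) * D[t, W_i] *
#                        P(Y_i | A_i, X=t, C_i; beta)^{r_i}
# where r_i = 1 when the outcome is observed.  Outcome-missing rows inform
# the gender->class coefficients only.  Maximization is by quasi-Newton
# (BFGS) with the analytic score; writing q_it for the posterior of the
# true class and g_it for the multinomial class probability,
#   d ll / d gamma_t = sum_i w_i (q_it - g_it) x_i            (t = 2..T)
#   d ll / d beta    = sum_i w_i r_i sum_t q_it (y_i - p_ity) z_it.
# The naive known-class fits (nnet::multinom for W, stats::glm for Y given
# W) provide the starting values.

#' Fit the corrected structural (mediator + outcome) model
#'
#' @param frame An `eq_frame` from [encode_covariates()].
#' @param W Modal class assignment from [modal_assign()] (length `frame$n`).
#' @param D Classification-error matrix: an `eq_class_error` or a `T x T`
#'   matrix with rows summing to 1.  Pass the identity to treat `W` as the
#'   true class.
#' @param n_starts Number of optimizer starts; the first uses the
#'   deterministic naive initialization (regressions treating `W` as
#'   known), additional starts perturb it.
#' @param max_iter Maximum BFGS iterations.
#' @param grad_tol Convergence criterion: maximum absolute score component,
#'   scaled by the summed weights, below this value.
#' @param seed Seed for perturbed starts (only used when `n_starts > 1`).
#' @param init Optional list with `gamma` and `beta` to warm-start the
#'   optimizer (used by the bootstrap).
#' @param reltol Relative function-value tolerance handed to the optimizer
#'   (converted to its `factr` control).
#' @param coef_bound Box bound on every coefficient.  Near-separated cells
#'   (e.g. an almost event-free gender-by-class combination) push their
#'   logit toward infinity along an essentially flat likelihood direction;
#'   the bound truncates that walk at a probability of ~2e-9 without
#'   affecting the remaining coefficients.  Bound components are excluded
#'   from the score-based convergence check.
#' @return An object of class `eq_structural` with the multinomial
#'   coefficients `gamma` (`(T-1) x 13`, reference class 1), logistic
#'   coefficients `beta` (with gender-by-class interactions), `loglik`,
#'   convergence information and the `D` used.  A separation warning is
#'   issued when any coefficient exceeds 15 in absolute value.
#' @export
fit_structural <- function(frame, W, D, n_starts = 1L, max_iter = 1000L,
                           grad_tol = 1e-6, seed = 1L, init = NULL,
                           reltol = 1e-14, coef_bound = 20) {
  stopifnot(inherits(frame, "eq_frame"))
  Dm <- if (inherits(D, "eq_class_error")) D$D else as.matrix(D)
  T <- nrow(Dm)
  n <- frame$n
  stopifnot(length(W) == n, ncol(Dm) == T)
  A <- frame$A; conf <- frame$conf; w <- frame$w
  y <- frame$y; r <- !is.na(y)
  yv <- ifelse(r, y, 0L)
  Xg <- gamma_design(A, conf)                      # n x P
  P <- ncol(Xg)
  Q <- 2L + 2L * (T - 1L) + ncol(conf)
  logD_rows <- log(t(Dm))[W, , drop = FALSE]       # n x T, log D[t, W_i]
  n_gamma <- (T - 1L) * P
  # Index layout of beta: intercept, woman, class main effects, woman-by-
  # class interactions, confounder dummies.  The per-class outcome design
  # differs from the base design only in the class and interaction columns,
  # which keeps the linear predictor to a single matrix product.
  i_cls <- 2L + seq_len(T - 1L)
  i_int <- 2L + (T - 1L) + seq_len(T - 1L)
  i_cnf <- 2L + 2L * (T - 1L) + seq_len(ncol(conf))

  unpack <- function(par) {
    list(gamma = matrix(par[seq_len(n_gamma)], T - 1L, P),
         beta = par[n_gamma + seq_len(Q)])
  }

  # Log-likelihood and score in one pass (optim calls fn and gr at the same
  # point; the last evaluation is cached).
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    th <- unpack(par)
    beta <- th$beta
    lg <- cbind(0, Xg %*% t(th$gamma))
    lse_g <- logsumexp_rows(lg)
    lp_class <- lg - lse_g
    base <- beta[1L] + A * beta[2L] + drop(conf %*% beta[i_cnf])
    eta <- matrix(base, n, T)
    for (t in 2:T) eta[, t] <- eta[, t] + beta[i_cls[t - 1L]] +
      A * beta[i_int[t - 1L]]
    lp1 <- stats::plogis(eta, log.p = TRUE)
    lp0 <- stats::plogis(-eta, log.p = TRUE)
    ll_y <- (yv * lp1 + (1L - yv) * lp0) * r
    logq <- lp_class + logD_rows + ll_y
    lse <- logsumexp_rows(logq)
    q <- exp(logq - lse)
    loglik <- sum(w * lse)
    g <- exp(lp_class)
    grad_gamma <- crossprod(Xg, (q - g)[, -1L, drop = FALSE] * w)  # P x (T-1)
    resid <- (q * (yv - stats::plogis(eta))) * (w * r)             # n x T
    rs <- rowSums(resid)
    grad_beta <- numeric(Q)
    grad_beta[1L] <- sum(rs)
    grad_beta[2L] <- sum(A * rs)
    grad_beta[i_cls] <- colSums(resid[, -1L, drop = FALSE])
    grad_beta[i_int] <- colSums(A * resid[, -1L, drop = FALSE])
    grad_beta[i_cnf] <- drop(crossprod(conf, rs))
    val <- list(loglik = loglik, grad = c(t(grad_gamma), grad_beta), q = q)
    cache$par <- par
    cache$val <- val
    val
  }
  negll <- function(par) -evaluate(par)$loglik
  neggr <- function(par) -evaluate(par)$grad

  naive_init <- function() {
    onehot <- matrix(0, n, T)
    onehot[cbind(seq_len(n), W)] <- 1
    gamma <- fit_known_class(onehot * w, A, conf)
    Zobs <- beta_design_obs(A, W, T, conf)
    fit <- suppressWarnings(stats::glm.fit(
      x = Zobs[r, , drop = FALSE], y = y[r], weights = w[r],
      family = stats::quasibinomial()))
    list(gamma = gamma, beta = stats::setNames(fit$coefficients,
                                               beta_coef_names(T)))
  }

  run_opt <- function(start) {
    par0 <- c(t(start$gamma), start$beta)
    par0 <- pmin(pmax(par0, -coef_bound), coef_bound)
    opt <- stats::optim(par0, fn = negll, gr = neggr, method = "L-BFGS-B",
                        lower = -coef_bound, upper = coef_bound,
                        control = list(maxit = max_iter,
                                       factr = reltol / .Machine$double.eps))
    ev <- evaluate(opt$par)
    at_bound <- abs(abs(opt$par) - coef_bound) < 1e-8
    gnorm <- max(abs(ev$grad[!at_bound]), 0) / sum(w)
    list(par = opt$par, loglik = ev$loglik, grad_norm = gnorm,
         converged = gnorm < grad_tol, n_iter = opt$counts[["function"]])
  }

  start0 <- init %||% naive_init()
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- start0
    if (s > 1L) {
      set.seed(seed + s - 1L)
      start$gamma <- start$gamma +
        matrix(stats::rnorm(length(start$gamma), 0, 0.25), nrow(start$gamma))
      start$beta <- start$beta + stats::rnorm(length(start$beta), 0, 0.25)
    }
    fit <- run_opt(start)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  th <- unpack(best$par)
  gamma <- th$gamma
  dimnames(gamma) <- list(paste0("class", 2:T), gamma_coef_names())
  beta <- stats::setNames(th$beta, beta_coef_names(T))
  separation <- max(abs(c(gamma, beta))) > 15
  if (separation)
    warning("possible separation: coefficient exceeding 15 in absolute value",
            call. = FALSE)
  if (!best$converged)
    warning(sprintf("structural fit: scaled score norm %.2e above tolerance %g",
                    best$grad_norm, grad_tol), call. = FALSE)
  structure(list(gamma = gamma, beta = beta, loglik = best$loglik,
                 grad_norm = best$grad_norm, converged = best$converged,
                 n_iter = best$n_iter, T = T, D_used = Dm,
                 outcome = frame$outcome, separation = separation),
            class = "eq_structural")
}

# Weighted multinomial-logit fit on known class memberships (counts-matrix
# response); used for initialization.
fit_known_class <- function(resp, A, conf) {
  Xmat <- cbind(woman = A, conf)
  gm <- nnet::multinom(resp ~ Xmat, trace = FALSE, maxit = 500,
                       reltol = 1e-12, MaxNWts = 10000)
  co <- stats::coef(gm)
  if (is.null(dim(co))) co <- matrix(co, 1L)
  dimnames(co) <- list(NULL, gamma_coef_names())
  co
}

#' @export
print.eq_structural <- function(x, ...) {
  cat("Three-step structural model | outcome:", x$outcome,
      "| classes:", x$T, "\n")
  cat("  loglik", format(x$loglik, digits = 8),
      "| BFGS gradient evaluations:", x$n_iter,
      "| converged:", x$converged, "\n")
  cat("  gender coefficient (outcome model):",
      sprintf("%.3f", x$beta["woman"]), "\n")
  invisible(x)
}

#' Counterfactual outcome mean by g-computation
#'
#' Standardizes over the full analytic sample's confounder distribution
#' (both genders pooled, survey-weighted): the weighted average over rows of
#' `sum_t P(Y = 1 | A = a, X = t, C_i) * P(X = t | A = a_star, C_i)`.
#'
#' @param model An `eq_structural` fit.
#' @param frame The `eq_frame` whose confounder rows define the standard
#'   population.
#' @param a Gender setting the outcome model (`"man"`/`"woman"` or 0/1).
#' @param a_star Gender setting the mediator distribution.
#' @return A probability.
#' @export
counterfactual_mean <- function(model, frame, a, a_star) {
  av <- gender_code(a); asv <- gender_code(a_star)
  n <- frame$n; conf <- frame$conf; T <- model$T
  p_class <- class_probs(model$gamma, rep(asv, n), conf)
  py <- matrix(0, n, T)
  for (t in seq_len(T)) {
    Z <- beta_design_at(rep(av, n), t, T, conf)
    py[, t] <- stats::plogis(drop(Z %*% model$beta))
  }
  sum(frame$w * rowSums(p_class * py)) / sum(frame$w)
}

gender_code <- function(a) {
  if (is.character(a) || is.factor(a)) {
    a <- as.character(a)
    stopifnot(a %in% GENDER_LEVELS)
    as.numeric(a == "woman")
  } else {
    stopifnot(a %in% c(0, 1))
    as.numeric(a)
  }
}
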