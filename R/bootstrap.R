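# Bias-corrected (BC) percentile bootstrap.  The bias-correction constant
# z0 = qnorm(#{theta*_b < theta_hat} / B) shifts the percentile interval:
# endpoints are the bootstrap quantiles at pnorm(2 * z0 +/- z_{1-alpha/2}).
# No acceleration constant (BC, not BCa).

#' Bias-corrected bootstrap interval for a scalar estimate
#'
#' @param t_hat Point estimate.
#' @param t_boot Vector of bootstrap replicates (NAs dropped).
#' @param alpha Two-sided miscoverage level (default 0.05).
#' @return Named vector `lower`, `upper`, `z0`.  When all replicates are
#'   equal the interval collapses to that point with a warning.  The
#'   bias-correction proportion is clamped to `[1/(B+1), B/(B+1)]` so `z0`
#'   stays finite when the estimate falls outside the bootstrap range.
#' @export
bc_interval <- function(t_hat, t_boot, alpha = 0.05) {
  t_boot <- t_boot[!is.na(t_boot)]
  B <- length(t_boot)
  if (B == 0L) stop("no bootstrap replicates", call. = FALSE)
  if (max(t_boot) - min(t_boot) < .Machine$double.eps * max(1, abs(t_hat))) {
    warning("degenerate bootstrap distribution; interval collapses to a point",
            call. = FALSE)
    return(c(lower = t_boot[1], upper = t_boot[1], z0 = 0))
  }
  prop <- sum(t_boot < t_hat) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  zc <- stats::qnorm(1 - alpha / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  q <- stats::quantile(t_boot, probs, names = FALSE, type = 7)
  c(lower = q[1], upper = q[2], z0 = z0)
}

#' Bias-corrected bootstrap intervals for the effect decomposition
#'
#' Resamples respondents with replacement (rows carry their survey weights),
#' refits the corrected structural model on each resample — warm-started
#' from the full-sample fit, with the classification-error matrix `D` and
#' the Step-1 measurement model held fixed — and recomputes the
#' decomposition.  Intervals are bias-corrected percentile intervals per
#' scalar effect.  Failed resample fits are dropped and counted; more than
#' 5% failures is an error.
#'
#' @param frame `eq_frame` for the outcome of interest.
#' @param W Modal assignment vector on `frame`'s rows.
#' @param D Classification-error matrix (held fixed across resamples).
#' @param B Number of bootstrap resamples (>= 100; the reference analysis
#'   uses 10,000).
#' @param alpha Two-sided miscoverage level.
#' @param seed Integer seed; intervals are deterministic given it.
#' @param max_iter,grad_tol,reltol Passed to [fit_structural()] for the
#'   resample fits (the default `reltol` is looser than the full-sample
#'   fit's: quantile noise at realistic `B` dwarfs the resulting
#'   coefficient error).
#' @return The full-sample `eq_decomposition` augmented with `ci` (data
#'   frame of `pd_lower`/`pd_upper`/`z0` per effect), `or_ci`, and `boot`
#'   metadata (`B`, failures, the replicate matrix).
#' @export
bc_bootstrap <- function(frame, W, D, B = 1000L, alpha = 0.05, seed = 1L,
                         max_iter = 500L, grad_tol = 1e-6, reltol = 1e-8) {
  stopifnot(B >= 100L)
  full_fit <- fit_structural(frame, W, D, max_iter = max_iter,
                             grad_tol = grad_tol)
  full_dec <- decompose(full_fit, frame)
  init <- list(gamma = full_fit$gamma, beta = full_fit$beta)
  eff_names <- full_dec$effects$effect
  or_names <- full_dec$ors$effect
  set.seed(seed)
  pd_boot <- matrix(NA_real_, B, length(eff_names),
                    dimnames = list(NULL, eff_names))
  or_boot <- matrix(NA_real_, B, length(or_names),
                    dimnames = list(NULL, or_names))
  n <- frame$n
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- resample_frame(frame, idx)
    dec_b <- tryCatch({
      fit_b <- suppressWarnings(
        fit_structural(fb, W[idx], D, max_iter = max_iter,
                       grad_tol = grad_tol, reltol = reltol, init = init))
      decompose(fit_b, fb)
    }, error = function(e) NULL)
    if (is.null(dec_b)) {
      n_failed <- n_failed + 1L
    } else {
      stopifnot(abs(dec_b$effects$pd[1] -
                      (dec_b$effects$pd[2] + dec_b$effects$pd[3])) < 1e-12)
      pd_boot[b, ] <- dec_b$effects$pd
      or_boot[b, ] <- dec_b$ors$or
    }
  }
  if (n_failed > 0.05 * B)
    stop(sprintf("bootstrap unstable: %d of %d resample fits failed",
                 n_failed, B), call. = FALSE)
  ci <- t(vapply(eff_names, function(e) {
    bc_interval(full_dec$effects$pd[full_dec$effects$effect == e],
                pd_boot[, e], alpha)
  }, c(lower = 0, upper = 0, z0 = 0)))
  or_ci <- t(vapply(or_names, function(e) {
    bc_interval(full_dec$ors$or[full_dec$ors$effect == e],
                or_boot[, e], alpha)
  }, c(lower = 0, upper = 0, z0 = 0)))
  full_dec$ci <- data.frame(effect = eff_names,
                            pd_lower = ci[, "lower"],
                            pd_upper = ci[, "upper"],
                            z0 = ci[, "z0"], row.names = NULL)
  full_dec$or_ci <- data.frame(effect = or_names,
                               or_lower = or_ci[, "lower"],
                               or_upper = or_ci[, "upper"],
                               z0 = or_ci[, "z0"], row.names = NULL)
  full_dec$boot <- list(B = B, n_failed = n_failed, alpha = alpha,
                        seed = seed, pd_boot = pd_boot)
  full_dec$model <- full_fit
  full_dec
}

resample_frame <- function(frame, idx) {
  structure(list(
    data = frame$data[idx, , drop = FALSE],
    A = frame$A[idx],
    conf = frame$conf[idx, , drop = FALSE],
    items = frame$items[idx, , drop = FALSE],
    y = frame$y[idx],
    w = frame$w[idx],
    outcome = frame$outcome,
    n = length(idx)
  ), class = "eq_frame")
}
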