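# Weighted latent class analysis for categorical EQ indicators (Step 1 of
# the three-step procedure).  The measurement model is an unconditional
# multinomial mixture: P(y_i) = sum_t pi_t prod_{j in obs(i)} theta_{t,j,y_ij}.
# Missing items are marginalized by omission from the product; survey
# weights multiply log-likelihood contributions (pseudo-ML).

lca_inputs <- function(frame, weights = NULL) {
  if (inherits(frame, "eq_frame")) {
    list(items = frame$items, w = frame$w)
  } else {
    items <- as.matrix(frame)
    storage.mode(items) <- "integer"
    list(items = items, w = weights %||% rep(1, nrow(items)))
  }
}

# n x T matrix of per-row class log-densities (prior excluded).
item_loglik <- function(items, theta) {
  n <- nrow(items)
  T <- nrow(theta[[1]])
  ll <- matrix(0, n, T)
  for (j in seq_along(theta)) {
    lth <- log(theta[[j]])            # T x K_j
    obs <- !is.na(items[, j])
    ll[obs, ] <- ll[obs, ] + t(lth)[items[obs, j], , drop = FALSE]
  }
  ll
}

#' Fit a weighted latent class model by EM
#'
#' Maximizes the survey-weighted log-likelihood of a `T`-class multinomial
#' mixture over the 11 categorical EQ indicators.  Missing item responses
#' are marginalized (rows need at least one observed indicator).  The best
#' of `n_starts` random starts is returned; each start initializes the
#' item-response probabilities from Dirichlet perturbations of the weighted
#' empirical frequencies and the mixing proportions uniformly.  Response
#' probabilities are floored at `1e-6` and renormalized each M-step.
#'
#' @param frame An `eq_frame` from [encode_covariates()], or a matrix/data
#'   frame of integer item codes (categories `1..K_j`, `NA` allowed).
#' @param T Number of classes (>= 1).
#' @param n_starts Number of random starts (default 20).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param seed Integer seed governing all starts.
#' @param weights Optional weights when `frame` is a plain matrix.
#' @return An object of class `eq_lca`: mixing proportions `pi`, response
#'   probabilities `theta` (list of `T x K_j` matrices), the weighted
#'   `loglik` and its per-iteration `loglik_trace` for the best start,
#'   `n_params`, `converged`, `n_iter`, and `seed_of_best_start`.
#' @export
fit_lca <- function(frame, T = 6L, n_starts = 20L, max_iter = 2000L,
                    tol = 1e-7, seed = 1L, weights = NULL) {
  inp <- lca_inputs(frame, weights)
  items <- inp$items; w <- inp$w
  n <- nrow(items)
  if (n == 0L) stop("no rows to fit", call. = FALSE)
  if (any(rowSums(!is.na(items)) == 0L))
    stop("rows with zero observed indicators present; exclude them first",
         call. = FALSE)
  T <- as.integer(T)
  J <- ncol(items)
  K <- vapply(seq_len(J), function(j) max(items[, j], na.rm = TRUE), 0L)
  # Weighted empirical item frequencies (basis for initialization; exact
  # solution when T = 1).
  emp <- lapply(seq_len(J), function(j) {
    f <- vapply(seq_len(K[j]), function(k) {
      sum(w[!is.na(items[, j]) & items[, j] == k])
    }, 0)
    f / sum(f)
  })
  n_params <- (T - 1L) + T * sum(K - 1L)
  if (T == 1L) {
    theta <- lapply(emp, function(f) matrix(f, 1L))
    ll <- sum(w * item_loglik(items, theta))
    return(structure(list(T = 1L, pi = 1, theta = theta, cardinalities = K,
                          loglik = ll, loglik_trace = ll,
                          n_params = n_params, converged = TRUE, n_iter = 0L,
                          seed_of_best_start = seed, n = n, sum_w = sum(w)),
                     class = "eq_lca"))
  }
  distinct <- nrow(unique(items))
  support_warning <- T > distinct
  if (support_warning)
    warning("number of classes exceeds distinct response-pattern support; ",
            "fit may not be identified", call. = FALSE)
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    pi <- rep(1 / T, T)
    theta <- lapply(seq_len(J), function(j) {
      t(vapply(seq_len(T), function(t) rdirichlet_one(emp[[j]] * 20 + 0.5),
               numeric(K[j])))
    })
    fit <- lca_em(items, w, pi, theta, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$seed_of_best_start <- seed + s - 1L
    }
  }
  best$converged <- best$converged && !support_warning
  structure(c(best, list(T = T, cardinalities = K, n_params = n_params,
                         n = n, sum_w = sum(w))),
            class = "eq_lca")
}

lca_em <- function(items, w, pi, theta, max_iter, tol) {
  floor_theta <- function(th) {
    th <- pmax(th, 1e-6)
    th / rowSums(th)
  }
  J <- ncol(items)
  obs_w <- lapply(seq_len(J), function(j) w * !is.na(items[, j]))
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lp <- sweep(item_loglik(items, theta), 2L, log(pi), `+`)
    lse <- logsumexp_rows(lp)
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it > max_iter) break
    ll_old <- ll
    post <- exp(lp - lse)
    wp <- post * w
    pi <- colSums(wp) / sum(w)
    pi <- pmax(pi, 1e-10); pi <- pi / sum(pi)
    for (j in seq_len(J)) {
      K <- ncol(theta[[j]])
      num <- matrix(0, nrow(theta[[j]]), K)
      yj <- items[, j]
      for (k in seq_len(K)) {
        sel <- !is.na(yj) & yj == k
        if (any(sel)) num[, k] <- colSums(wp[sel, , drop = FALSE])
      }
      theta[[j]] <- floor_theta(num / pmax(rowSums(num), .Machine$double.xmin))
    }
  }
  list(pi = pi, theta = theta, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged, n_iter = it)
}

#' Posterior class-membership probabilities
#'
#' Bayes posterior of the latent class given each respondent's observed
#' indicators: `p_it` proportional to `pi_t * prod_j theta_{t,j,y_ij}` over
#' observed items, normalized per row.
#'
#' @param model An `eq_lca` fit.
#' @param frame `eq_frame` or item matrix (as in [fit_lca()]).
#' @return `n x T` matrix with rows summing to 1.
#' @export
posterior_probs <- function(model, frame) {
  items <- lca_inputs(frame)$items
  lp <- sweep(item_loglik(items, model$theta), 2L, log(model$pi), `+`)
  exp(lp - logsumexp_rows(lp))
}

#' Modal class assignment
#'
#' Assigns each respondent to the class with the highest posterior
#' probability; ties are broken toward the lowest class index and counted
#' in the `n_ties` attribute.
#'
#' @param post Posterior matrix from [posterior_probs()].
#' @return Integer assignment vector with attribute `n_ties`.
#' @export
modal_assign <- function(post) {
  W <- max.col(post, ties.method = "first")
  rowmax <- post[cbind(seq_len(nrow(post)), W)]
  n_ties <- sum(rowSums(abs(post - rowmax) < 1e-12) > 1L)
  if (n_ties > 0L)
    message(n_ties, " posterior tie(s) broken toward the lowest class index")
  attr(W, "n_ties") <- n_ties
  W
}

#' Model fit statistics for a latent class fit
#'
#' @param model An `eq_lca` fit.
#' @param frame Data used for the fit (for the entropy denominator).
#' @param post Posterior matrix; computed from `model` and `frame` when
#'   omitted.
#' @return List with `AIC`, `BIC` (penalty uses the log of the summed
#'   weights), and `relative_entropy` (1 for a one-class model by
#'   convention; 1 = perfect class separation, 0 = uninformative posteriors).
#' @export
fit_statistics <- function(model, frame, post = NULL) {
  if (is.null(post)) post <- posterior_probs(model, frame)
  aic <- -2 * model$loglik + 2 * model$n_params
  bic <- -2 * model$loglik + model$n_params * log(model$sum_w)
  if (model$T == 1L) {
    ent <- 1
  } else {
    plogp <- ifelse(post > 0, -post * log(post), 0)
    ent <- 1 - sum(plogp) / (nrow(post) * log(model$T))
  }
  list(AIC = aic, BIC = bic, relative_entropy = ent)
}

#' Align class labels against a reference measurement model
#'
#' Mixture class labels are arbitrary; this permutes them to minimize the
#' total absolute difference between the model's item-response
#' probabilities and a reference (exhaustive search over all permutations,
#' intended for T <= 6).
#'
#' @param model An `eq_lca` fit.
#' @param reference_theta Reference: an `eq_lca` object or a list of
#'   `T x K_j` matrices.
#' @return The model with `pi` and `theta` permuted; the permutation used is
#'   stored in element `perm` (`perm[t]` = original label of new class `t`).
#' @export
align_classes <- function(model, reference_theta) {
  ref <- if (inherits(reference_theta, "eq_lca")) reference_theta$theta
         else reference_theta
  T <- model$T
  if (length(ref) != length(model$theta) ||
      any(vapply(ref, nrow, 0L) != T) ||
      any(vapply(ref, ncol, 0L) != vapply(model$theta, ncol, 0L)))
    stop("reference dimensions do not match the model", call. = FALSE)
  pm <- all_perms(T)
  cost <- apply(pm, 1L, function(p) {
    sum(vapply(seq_along(ref), function(j) {
      sum(abs(model$theta[[j]][p, , drop = FALSE] - ref[[j]]))
    }, 0))
  })
  p <- pm[which.min(cost), ]
  model$pi <- model$pi[p]
  model$theta <- lapply(model$theta, function(m) m[p, , drop = FALSE])
  model$perm <- p
  model
}

#' @export
print.eq_lca <- function(x, ...) {
  cat("Weighted latent class model:", x$T, "classes,", x$n, "respondents\n")
  cat("  loglik", format(x$loglik, digits = 8),
      "| parameters", x$n_params,
      "| converged:", x$converged,
      "| EM iterations:", x$n_iter, "\n")
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "),
      "\n")
  invisible(x)
}
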