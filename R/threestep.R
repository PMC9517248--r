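# Step 2 of the Vermunt three-step procedure: quantify how noisy the modal
# assignment W is as a single nominal indicator of the true class X.

#' Classification-error matrix of the modal assignment
#'
#' Computes `D[t, s] = P(W = s | X = t)`, the probability that a respondent
#' whose true class is `t` is modally assigned to class `s`, from the Step-1
#' posteriors:
#' `D[t, s] = sum_i w_i p_it 1[W_i = s] / sum_i w_i p_it`.
#' The fixed logits used by the corrected structural model are
#' `log(D[t, s] / D[t, T])` after flooring zero cells at `1e-8`.
#'
#' @param post Posterior matrix from [posterior_probs()].
#' @param W Modal assignment vector from [modal_assign()].
#' @param weights Survey weights (default: unit).
#' @return An object of class `eq_class_error` with elements `D` (rows sum
#'   to 1), `logit_D` (reference category: the last class), and `floor_used`.
#' @export
classification_error_matrix <- function(post, W, weights = NULL) {
  n <- nrow(post)
  T <- ncol(post)
  w <- weights %||% rep(1, n)
  stopifnot(length(W) == n, length(w) == n)
  wp <- post * w
  denom <- colSums(wp)
  if (any(denom <= 0))
    stop("empty class (zero posterior mass); refit with fewer classes",
         call. = FALSE)
  D <- matrix(0, T, T, dimnames = list(true = seq_len(T),
                                       assigned = seq_len(T)))
  for (s in seq_len(T)) {
    sel <- W == s
    if (any(sel)) D[, s] <- colSums(wp[sel, , drop = FALSE])
  }
  D <- D / denom
  floor_used <- any(D < 1e-8)
  Df <- pmax(D, 1e-8)
  logit_D <- log(Df) - log(Df[, T])
  structure(list(D = D, logit_D = logit_D, floor_used = floor_used),
            class = "eq_class_error")
}

#' Measurement density of an assigned class given the true class
#'
#' The probability `P(W = w | X = t)` entering the Step-3 likelihood
#' multiplicatively: a direct lookup `D[t, w]`.
#'
#' @param W_i Assigned class (scalar or vector).
#' @param t True class (scalar or vector, recycled against `W_i`).
#' @param D An `eq_class_error` object or a `T x T` matrix.
#' @return Probability vector.
#' @export
measurement_density <- function(W_i, t, D) {
  Dm <- if (inherits(D, "eq_class_error")) D$D else D
  T <- nrow(Dm)
  if (any(W_i < 1L | W_i > T) || any(t < 1L | t > T))
    stop("class index out of range", call. = FALSE)
  Dm[cbind(t, W_i)]
}

#' @export
print.eq_class_error <- function(x, ...) {
  cat("Classification-error matrix D[true, assigned]",
      if (x$floor_used) "(zero cells floored for logits)" else "", "\n")
  print(round(x$D, 4))
  invisible(x)
}
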