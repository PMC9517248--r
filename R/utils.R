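# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp; tolerates -Inf entries as long as each row has at
# least one finite value.
logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) {
    for (j in 2L:ncol(m)) mx <- pmax(mx, m[, j])
  }
  mx + log(rowSums(exp(m - mx)))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# All permutations of 1:n as an (n!) x n matrix; n is small (<= 6 classes).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# Vectorized categorical sampling: one draw per row of a probability matrix.
sample_rows <- function(p) {
  n <- nrow(p)
  k <- ncol(p)
  cp <- p %*% upper.tri(matrix(0, k, k), diag = TRUE)
  u <- stats::runif(n)
  1L + as.integer(rowSums(u > cp[, -k, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

odds <- function(p) p / (1 - p)
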