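make_mixture_items <- function(n, theta, pi, seed) {
  set.seed(seed)
  cls <- sample(length(pi), n, replace = TRUE, prob = pi)
  items <- sapply(seq_along(theta), function(j) {
    p <- theta[[j]][cls, , drop = FALSE]
    apply(p, 1, function(row) sample(ncol(p), 1, prob = row))
  })
  list(items = items, cls = cls)
}

two_class_theta <- function(J = 11) {
  lapply(seq_len(J), function(j) {
    if (j %% 2) rbind(c(0.9, 0.1), c(0.1, 0.9)) else rbind(c(0.1, 0.9), c(0.9, 0.1))
  })
}

test_that("one-class fit equals the weighted empirical frequencies", {
  set.seed(1)
  items <- cbind(sample(1:3, 50, TRUE), sample(1:2, 50, TRUE))
  w <- runif(50, 0.5, 2)
  m <- fit_lca(items, T = 1, weights = w)
  for (j in 1:2) {
    f <- vapply(seq_len(max(items[, j])),
                function(k) sum(w[items[, j] == k]) / sum(w), 0)
    expect_equal(drop(m$theta[[j]]), f, tolerance = 1e-12)
  }
  expect_equal(m$pi, 1)
  expect_true(is.finite(m$loglik))
})

test_that("well-separated two-class structure is recovered", {
  th <- two_class_theta()
  d <- make_mixture_items(2000, th, c(0.6, 0.4), seed = 21)
  m <- fit_lca(d$items, T = 2, n_starts = 5, seed = 3)
  m <- align_classes(m, th)
  err <- max(vapply(1:11, function(j) max(abs(m$theta[[j]] - th[[j]])), 0))
  expect_lt(err, 0.05)
  expect_lt(max(abs(sort(m$pi) - c(0.4, 0.6))), 0.05)
  expect_true(m$converged)
})

test_that("fits are deterministic given the seed and monotone in log-likelihood", {
  fx <- study_fixture()
  m1 <- fit_lca(fx$frame, T = 3, n_starts = 2, seed = 9)
  m2 <- fit_lca(fx$frame, T = 3, n_starts = 2, seed = 9)
  expect_identical(m1$loglik, m2$loglik)
  expect_identical(m1$theta, m2$theta)
  expect_true(all(diff(m1$loglik_trace) > -1e-8))
  expect_true(all(diff(fx$lca$loglik_trace) > -1e-8))
})

test_that("simplex constraints hold after fitting", {
  fx <- study_fixture()
  m <- fx$lca
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  for (j in seq_along(m$theta)) {
    expect_equal(rowSums(m$theta[[j]]), rep(1, m$T), tolerance = 1e-10)
    expect_true(all(m$theta[[j]] >= 0))
  }
})

test_that("posteriors normalize, recover the prior when items are uninformative, and go one-hot under certainty", {
  fx <- study_fixture()
  expect_equal(rowSums(fx$post), rep(1, nrow(fx$post)), tolerance = 1e-10)
  expect_true(all(fx$post >= 0 & fx$post <= 1))
  # uninformative: single observed item with identical response profiles
  uninf <- structure(list(
    T = 2L, pi = c(0.3, 0.7),
    theta = c(list(rbind(c(0.5, 0.5), c(0.5, 0.5))),
              lapply(1:10, function(j) rbind(c(0.9, 0.1), c(0.1, 0.9))))),
    class = "eq_lca")
  row <- matrix(c(1L, rep(NA_integer_, 10)), 1)
  expect_equal(drop(posterior_probs(uninf, row)), c(0.3, 0.7),
               tolerance = 1e-12)
  # degenerate response probabilities give one-hot posteriors
  degen <- structure(list(
    T = 2L, pi = c(0.5, 0.5),
    theta = lapply(1:11, function(j) rbind(c(1, 0), c(0, 1)))),
    class = "eq_lca")
  p <- posterior_probs(degen, matrix(1L, 1, 11))
  expect_equal(drop(p), c(1, 0))
})

test_that("modal assignment takes the argmax and logs ties toward the lowest index", {
  expect_equal(suppressMessages(modal_assign(rbind(c(0.6, 0.4))))[1], 1L)
  expect_equal(suppressMessages(modal_assign(rbind(c(0.4, 0.6))))[1], 2L)
  tied <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  expect_message(W <- modal_assign(tied), "tie")
  expect_equal(W[1], 1L)
  expect_equal(attr(W, "n_ties"), 1L)
  # brute-force argmax agreement on a random fixture
  set.seed(31)
  p <- matrix(rgamma(600, 1), 100, 6)
  p <- p / rowSums(p)
  expect_equal(as.integer(suppressMessages(modal_assign(p))),
               as.integer(apply(p, 1, which.max)))
})

test_that("fit statistics: entropy is 1 for one-hot and 0 for uniform posteriors", {
  dummy <- list(T = 4L, loglik = -100, n_params = 10, sum_w = 50)
  onehot <- diag(4)[rep(1:4, 5), ]
  expect_equal(fit_statistics(dummy, NULL, onehot)$relative_entropy, 1)
  unif <- matrix(0.25, 20, 4)
  expect_equal(fit_statistics(dummy, NULL, unif)$relative_entropy, 0,
               tolerance = 1e-12)
  expect_equal(fit_statistics(dummy, NULL, onehot)$AIC, 220)
  expect_equal(fit_statistics(dummy, NULL, onehot)$BIC, 200 + 10 * log(50))
})

test_that("BIC selects the generating class count on a separated three-class design", {
  th3 <- lapply(1:11, function(j) {
    p <- c(0.9, 0.5, 0.1)
    if (j %% 2 == 0) p <- rev(p)
    if (j %% 3 == 0) p <- p[c(2, 3, 1)]
    cbind(p, 1 - p)
  })
  d <- make_mixture_items(1500, th3, c(0.4, 0.35, 0.25), seed = 51)
  bic <- vapply(2:4, function(T) {
    m <- fit_lca(d$items, T = T, n_starts = 3, seed = 17)
    fit_statistics(m, d$items)$BIC
  }, 0)
  expect_equal(which.min(bic), 2L)  # T = 3 among candidates 2,3,4
})

test_that("unit weights and constant rescaled weights give the same estimates", {
  th <- two_class_theta()
  d <- make_mixture_items(500, th, c(0.5, 0.5), seed = 61)
  m1 <- fit_lca(d$items, T = 2, n_starts = 2, seed = 5)
  m2 <- fit_lca(d$items, T = 2, n_starts = 2, seed = 5,
                weights = rep(2, 500))
  expect_equal(m1$pi, m2$pi, tolerance = 1e-6)
  expect_equal(m1$theta, m2$theta, tolerance = 1e-6)
  expect_equal(2 * m1$loglik, m2$loglik, tolerance = 1e-6)
})

test_that("class alignment recovers an applied permutation", {
  fx <- study_fixture()
  m <- fx$lca
  self <- align_classes(m, m)
  expect_equal(self$perm, 1:6)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  shuffled <- m
  shuffled$pi <- m$pi[perm]
  shuffled$theta <- lapply(m$theta, function(x) x[perm, , drop = FALSE])
  back <- align_classes(shuffled, m)
  expect_equal(back$pi, m$pi)
  expect_equal(back$theta, m$theta)
  expect_error(align_classes(m, m$theta[1:5]), "dimensions")
})

test_that("rows with no observed indicators are rejected", {
  items <- matrix(c(1L, NA, NA, 1L), 2, 2)
  items[1, ] <- NA
  expect_error(fit_lca(items, T = 2), "zero observed")
})
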