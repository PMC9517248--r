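test_that("decomposition identities hold to machine precision on fitted models", {
  fx <- study_fixture()
  fit <- suppressWarnings(fit_structural(fx$frame, fx$W, fx$err))
  d <- decompose(fit, fx$frame)
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_lt(abs(pd["TE"] - (pd["PDE"] + pd["TIE"])), 1e-12)
  expect_lt(abs(pd["TIE"] - (pd["PIE"] + pd["INTmed"])), 1e-12)
  expect_true(all(d$means >= 0 & d$means <= 1))
  expect_true(all(d$ors$or > 0))
})

test_that("zero gender coefficients in the mediator model give exactly null indirect effects", {
  m <- hand_structural()
  m$gamma[, "woman"] <- 0
  d <- decompose(m, reference_frame(5))
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_identical(unname(pd["TIE"]), 0)
  expect_identical(unname(pd["PIE"]), 0)
  expect_identical(unname(pd["INTmed"]), 0)
})

test_that("zero gender and interaction coefficients in the outcome model give exactly null direct effects", {
  m <- hand_structural()
  m$beta["woman"] <- 0
  m$beta["woman_x_class2"] <- 0
  d <- decompose(m, reference_frame(5))
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_identical(unname(pd["PDE"]), 0)
  expect_identical(unname(pd["INTmed"]), 0)
})

test_that("probability-table decomposition reproduces the hand-enumerated example exactly", {
  cd <- cbind(woman = c(0.7, 0.3), man = c(0.4, 0.6))
  op <- cbind(woman = c(0.1, 0.3), man = c(0.2, 0.2))
  d <- decompose_from_probabilities(cd, op)
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_equal(unname(pd["TIE"]), -0.06, tolerance = 1e-12)
  expect_equal(unname(pd["PIE"]), 0, tolerance = 1e-12)
  expect_equal(unname(pd["PDE"]), 0.02, tolerance = 1e-12)
  expect_equal(unname(pd["INTmed"]), -0.06, tolerance = 1e-12)
  expect_equal(unname(pd["TE"]), -0.04, tolerance = 1e-12)
})

test_that("identical class distributions across gender give exactly null indirect effects", {
  cd <- cbind(woman = c(0.5, 0.5), man = c(0.5, 0.5))
  op <- cbind(woman = c(0.1, 0.4), man = c(0.3, 0.2))
  d <- decompose_from_probabilities(cd, op)
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_identical(unname(pd["TIE"]), 0)
  expect_identical(unname(pd["PIE"]), 0)
})

test_that("probability-table decomposition validates its inputs", {
  cd <- cbind(woman = c(0.7, 0.2), man = c(0.4, 0.6))
  op <- cbind(woman = c(0.1, 0.3), man = c(0.2, 0.2))
  expect_error(decompose_from_probabilities(cd, op), "sum to 1")
  cd2 <- cbind(woman = c(0.7, 0.3), man = c(0.4, 0.6))
  op2 <- cbind(woman = c(1.1, 0.3), man = c(0.2, 0.2))
  expect_error(decompose_from_probabilities(cd2, op2), "\\[0, 1\\]")
  expect_error(decompose_from_probabilities(unname(cd2), op),
               "woman.*man|named")
})

test_that("model-based and table-based decompositions agree without confounders", {
  m <- hand_structural(p_cls2_man = 0.55, p_cls2_woman = 0.25,
                       py_man = c(0.15, 0.3), py_woman = c(0.12, 0.35))
  fr <- reference_frame(8)
  d_model <- decompose(m, fr)
  pred <- predicted_tables(m, fr)
  d_tab <- decompose_from_probabilities(pred$class_dist, pred$outcome_probs)
  expect_equal(d_model$effects$pd, d_tab$effects$pd, tolerance = 1e-12)
  expect_equal(d_model$ors$or, d_tab$ors$or, tolerance = 1e-12)
})

test_that("predicted tables are normalized and match closed forms without confounders", {
  m <- hand_structural()
  fr <- reference_frame(4)
  pred <- predicted_tables(m, fr)
  expect_equal(colSums(pred$class_dist), c(woman = 1, man = 1),
               tolerance = 1e-10)
  expect_equal(unname(pred$class_dist[2, "man"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(pred$class_dist[2, "woman"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(pred$outcome_probs[, "man"]), c(0.2, 0.2),
               tolerance = 1e-12)
  expect_equal(unname(pred$outcome_probs[, "woman"]), c(0.1, 0.3),
               tolerance = 1e-12)
})

test_that("sign convention: harming women through the mediator yields TIE > 0", {
  # women concentrated in class 2, where the outcome is much more likely
  m <- hand_structural(p_cls2_man = 0.2, p_cls2_woman = 0.8,
                       py_man = c(0.05, 0.4), py_woman = c(0.05, 0.4))
  d <- decompose(m, reference_frame(5))
  pd <- stats::setNames(d$effects$pd, d$effects$effect)
  expect_gt(pd["TIE"], 0)
  expect_gt(pd["TE"], 0)
})

test_that("effect decomposition recovers the generator truth on the calibrated design", {
  fx <- study_fixture()
  fit <- suppressWarnings(fit_structural(fx$frame, fx$W, fx$err))
  d <- decompose(fit, fx$frame)
  oracle <- true_effect_oracle(fx$cfg, n_mc = 20000, seed = 3)
  e <- oracle$outcomes$srh_poor$effects
  for (k in seq_len(nrow(e))) {
    est <- d$effects$pd[d$effects$effect == e$effect[k]]
    # estimator noise at n = 1500 dominates; allow a generous but fixed band
    expect_lt(abs(est - e$estimate[k]), 0.08)
  }
})
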