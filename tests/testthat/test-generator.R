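test_that("generation is deterministic given the configured seed", {
  cfg <- default_config(n = 300, seed = 42)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  cfg2 <- default_config(n = 300, seed = 43)
  expect_false(identical(generate_population(cfg2), a))
})

test_that("invalid configurations fail naming the offending field", {
  cfg <- default_config(n = 100)
  bad <- cfg; bad$theta_true[[3]] <- bad$theta_true[[3]][, 1, drop = FALSE]
  expect_error(generate_population(bad), "theta_true")
  bad <- cfg; bad$gamma_true <- bad$gamma_true[, 1:5]
  expect_error(generate_population(bad), "gamma_true")
  bad <- cfg; bad$missing_rates$items[2] <- 1.2
  expect_error(generate_population(bad), "missing_rates")
  bad <- cfg; bad$confounder_marginals$age_band <- c(0.5, 0.6, 0.1)
  expect_error(generate_population(bad), "confounder_marginals")
  expect_error(eq_config(n = 0, T = 6, gamma_true = cfg$gamma_true,
                         theta_true = cfg$theta_true,
                         beta_true = cfg$beta_true), "'n'")
})

test_that("zero gender effect on class membership yields symmetric class distributions", {
  cfg <- default_config(n = 50000, seed = 5)
  cfg$gamma_true[, "woman"] <- 0
  pop <- generate_population(cfg)
  tab <- table(pop$gender, pop$true_class)
  pw <- tab["woman", ] / sum(tab["woman", ])
  pm <- tab["man", ] / sum(tab["man", ])
  p <- colSums(tab) / sum(tab)
  se <- sqrt(p * (1 - p) * (1 / sum(tab["woman", ]) + 1 / sum(tab["man", ])))
  expect_true(all(abs(pw - pm) < 3 * se))
})

test_that("calibrated config reproduces its gender-specific class distributions and item margins", {
  cfg <- default_config(n = 50000, seed = 8)
  pop <- generate_population(cfg)
  cal <- default_calibration()
  for (g in c("woman", "man")) {
    sel <- pop$gender == g
    emp <- tabulate(pop$true_class[sel], 6) / sum(sel)
    tgt <- cal$class_dist[, g]
    se <- sqrt(tgt * (1 - tgt) / sum(sel))
    expect_true(all(abs(emp - tgt) < 3.5 * se))
  }
  # item frequencies converge to theta mixed over class prevalences
  prev <- tabulate(pop$true_class, 6) / nrow(pop)
  for (j in c(1, 2, 8)) {
    mix <- drop(prev %*% cfg$theta_true[[j]])
    emp <- tabulate(pop[[paste0("y", j)]], ncol(cfg$theta_true[[j]])) / nrow(pop)
    se <- sqrt(mix * (1 - mix) / nrow(pop))
    expect_true(all(abs(emp - mix) < 3.5 * se))
  }
})

test_that("calibrated outcome probabilities match the per-class targets", {
  cfg <- default_config(n = 50000, seed = 13)
  pop <- generate_population(cfg)
  cal <- default_calibration()
  for (oc in c("srh_poor", "fmd")) {
    for (g in c("woman", "man")) {
      for (t in c(1, 5)) {   # reference and a high-risk class
        sel <- pop$gender == g & pop$true_class == t
        tgt <- cal$outcome_probs[[oc]][t, g]
        se <- sqrt(tgt * (1 - tgt) / sum(sel))
        expect_lt(abs(mean(pop[[oc]][sel]) - tgt), 3.5 * se)
      }
    }
  }
})

test_that("lognormal weight law produces positive weights with mean near one", {
  cfg <- default_config(n = 20000, seed = 3,
                        weight_law = list(type = "lognormal", sdlog = 0.5))
  pop <- generate_population(cfg)
  expect_true(all(pop$weight > 0))
  expect_lt(abs(mean(pop$weight) - 1), 0.02)
})

test_that("oracle satisfies the decomposition identities exactly", {
  eff <- true_effect_oracle(default_config(), n_mc = 5000, seed = 2)
  for (oc in names(eff$outcomes)) {
    e <- eff$outcomes[[oc]]$effects
    est <- stats::setNames(e$estimate, e$effect)
    expect_lt(abs(est["TE"] - (est["PDE"] + est["TIE"])), 1e-12)
    expect_lt(abs(est["TIE"] - (est["PIE"] + est["INTmed"])), 1e-12)
    expect_true(all(eff$outcomes[[oc]]$means >= 0 & eff$outcomes[[oc]]$means <= 1))
  }
})

test_that("oracle recovers the hand-enumerated two-class effects", {
  eff <- true_effect_oracle(hand_config(), n_mc = 100000, seed = 4)
  e <- eff$outcomes$srh_poor$effects
  truth <- c(TE = -0.04, PDE = 0.02, TIE = -0.06, PIE = 0, INTmed = -0.06)
  for (k in seq_len(nrow(e))) {
    expect_lt(abs(e$estimate[k] - truth[[e$effect[k]]]), 3 * e$mc_se[k])
  }
})

test_that("oracle nulls: zero direct path and zero mediator path", {
  cfg <- default_config()
  cfg0 <- cfg
  for (nm in names(cfg0$beta_true)) {
    b <- cfg0$beta_true[[nm]]
    b[grep("woman", names(b))] <- 0
    cfg0$beta_true[[nm]] <- b
  }
  eff <- true_effect_oracle(cfg0, n_mc = 40000, seed = 6)
  e <- eff$outcomes$srh_poor$effects
  expect_lt(abs(e$estimate[e$effect == "PDE"]), 3 * e$mc_se[e$effect == "PDE"])
  expect_lt(abs(e$estimate[e$effect == "INTmed"]),
            3 * e$mc_se[e$effect == "INTmed"])
  cfg1 <- cfg
  cfg1$gamma_true[, "woman"] <- 0
  eff1 <- true_effect_oracle(cfg1, n_mc = 40000, seed = 7)
  e1 <- eff1$outcomes$srh_poor$effects
  expect_lt(abs(e1$estimate[e1$effect == "TIE"]), 3 * e1$mc_se[e1$effect == "TIE"])
  expect_lt(abs(e1$estimate[e1$effect == "PIE"]), 3 * e1$mc_se[e1$effect == "PIE"])
})
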