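test_that("noiseless 4PL data are recovered to numerical precision", {
  s <- gen_competition_series(seed = 1, cv = 0,
                              truth = list(top = 100, bottom = 0,
                                           hill = 1, midpoint = 10))
  fit <- fit_4pl(s)
  expect_true(fit$converged)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_lt(abs(fit$bottom), 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$midpoint, 10, tolerance = 1e-6)

  est <- ic50_from_fit(fit, s)
  expect_equal(est$censor, "none")
  expect_equal(est$value, fit$midpoint)

  # steeper curve, offset asymptotes
  s2 <- gen_competition_series(seed = 2, cv = 0,
                               truth = list(top = 4200, bottom = 300,
                                            hill = 1.8, midpoint = 3.5))
  fit2 <- fit_4pl(s2)
  expect_equal(fit2$midpoint, 3.5, tolerance = 1e-6)
  expect_equal(fit2$hill, 1.8, tolerance = 1e-6)
})

test_that("noisy series recover the midpoint within 15% in the median", {
  err <- vapply(1:50, function(s) {
    series <- gen_competition_series(seed = 100 + s, cv = 0.05)
    fit <- fit_4pl(series)
    if (!fit$converged) return(NA_real_)
    abs(log(fit$midpoint / 10))
  }, numeric(1))
  expect_true(all(!is.na(err)))
  expect_lt(median(err), log(1.15))
})

test_that("reported +-2 SE intervals for log-midpoint have near-nominal coverage", {
  covered <- vapply(1:200, function(s) {
    series <- gen_competition_series(seed = 5000 + s, cv = 0.05)
    fit <- fit_4pl(series)
    if (!fit$converged || is.na(fit$se_log_midpoint)) return(NA)
    abs(log(fit$midpoint) - log(10)) <= 2 * fit$se_log_midpoint
  }, logical(1))
  expect_gte(mean(covered, na.rm = TRUE), 0.9)
})

test_that("flat series censor as non-binders; out-of-range midpoints censor", {
  flat <- competition_series("p", "a", c(0.1, 1, 10, 100), rep(250, 4))
  fit <- fit_4pl(flat)
  expect_true(fit$converged)
  expect_equal(fit$top, fit$bottom)
  expect_equal(ic50_from_fit(fit, flat)$censor, "nb")

  # noisy but spanless
  noisy_flat <- gen_competition_series(seed = 3, cv = 0.05,
                                       truth = list(top = 200, bottom = 200,
                                                    hill = 1, midpoint = 10))
  est <- ic50_from_fit(fit_4pl(noisy_flat), noisy_flat)
  expect_equal(est$censor, "nb")
  expect_equal(est$label, "NB")

  # true midpoint above the tested range
  high <- gen_competition_series(seed = 4, cv = 0,
                                 truth = list(top = 100, bottom = 0,
                                              hill = 1, midpoint = 200))
  est <- ic50_from_fit(fit_4pl(high), high)
  expect_equal(est$censor, "gt_max")
  expect_match(est$label, "^> ")

  # true midpoint below the tested range
  low <- gen_competition_series(seed = 5, cv = 0,
                                truth = list(top = 100, bottom = 0,
                                             hill = 1, midpoint = 0.01))
  est <- ic50_from_fit(fit_4pl(low), low)
  expect_equal(est$censor, "lt_min")
})

test_that("fits are invariant to signal rescaling", {
  s <- gen_competition_series(seed = 6, cv = 0.03)
  scaled <- competition_series(s$peptide_id, s$allele_id,
                               s$concentrations, 37 * s$signals)
  f1 <- fit_4pl(s); f2 <- fit_4pl(scaled)
  expect_equal(f2$top, 37 * f1$top, tolerance = 1e-5)
  expect_equal(f2$bottom, 37 * f1$bottom, tolerance = 1e-3)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-5)
  expect_equal(f2$midpoint, f1$midpoint, tolerance = 1e-5)
})

test_that("affinity classes split at 25 and 50 uM with censor vocabulary", {
  expect_equal(classify_affinity(7.5), "high")
  expect_equal(classify_affinity(95.8), "weak")
  expect_equal(classify_affinity(31.3), "moderate")
  expect_equal(classify_affinity(c("<5", "<25", ">50", "NB")),
               c("high", "high", "weak", "non-binder"))
  expect_warning(cls <- classify_affinity("<40"), "multiple affinity classes")
  expect_true(is.na(cls))
  expect_error(classify_affinity(-3), "nonnegative")

  # the full DR4 fixture column: 7 high, 2 weak, 5 non-binders
  fx <- load_fixture("gad65_binding")
  cls <- classify_affinity(fx$ic50_drb1_0401)
  expect_equal(sum(cls == "high"), 7)
  expect_equal(sum(cls == "weak"), 2)
  expect_equal(sum(cls == "non-binder"), 5)
})

test_that("concordance tabulation reproduces the 11/14 worked example", {
  fx <- load_fixture("gad65_binding")
  cls <- classify_affinity(fx$ic50_drb1_0401)
  ct <- concordance_table(fx$dr4_predicted_inferred, cls)
  expect_equal(ct$tp, 9)
  expect_equal(ct$tn, 2)
  expect_equal(ct$n, 14)
  expect_equal(ct$accuracy, 11 / 14)

  expect_equal(concordance_table(c(TRUE, FALSE),
                                 c("high", "non-binder"))$accuracy, 1)

  # random predictions on balanced truth hover near 50%
  set.seed(17)
  truth <- rep(c("high", "non-binder"), 500)
  acc <- concordance_table(runif(1000) < 0.5, truth)$accuracy
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("competition series validate their inputs", {
  expect_error(competition_series("p", "a", c(-1, 1, 10, 100), rep(1, 4)),
               "strictly positive")
  expect_error(competition_series("p", "a", c(1, 1, 10, 100), rep(1, 4)),
               "4 distinct")
  expect_error(competition_series("p", "a", c(1, 2, 10, 100), c(-1, 1, 1, 1)),
               "nonnegative")
})
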