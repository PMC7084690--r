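test_that("noiseless decays are recovered exactly", {
  d <- r1_delays_ms() / 1000
  f <- fit_rate(d, 100 * exp(-10 * d))
  expect_true(f$ok)
  expect_lt(abs(f$rate - 10) / 10, 1e-6)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  # two-point closed form: ln(100/36.788)/0.1
  f2 <- fit_rate(c(0, 0.1, 0.2), 100 * exp(-10 * c(0, 0.1, 0.2)))
  expect_equal(f2$rate, 10, tolerance = 1e-6)
})

test_that("fit_rate is scale-invariant and flags pathologies instead of failing", {
  d <- r2_delays_ms() / 1000
  set.seed(2)
  y <- 100 * exp(-11.47 * d) * (1 + rnorm(length(d), 0, 0.02))
  f1 <- fit_rate(d, y)
  f3 <- fit_rate(d, 1e4 * y)
  expect_equal(f1$rate, f3$rate, tolerance = 1e-8)
  expect_equal(f3$amplitude / f1$amplitude, 1e4, tolerance = 1e-6)
  # growing intensities give a negative rate -> flagged, not an error
  fneg <- fit_rate(c(0, 0.1, 0.2), c(10, 20, 40))
  expect_false(fneg$ok)
  expect_match(fneg$reason, "negative")
  expect_error(fit_rate(c(0, 0.1), c(1, 2)), "at least 3")
  expect_error(fit_rate(c(0.1, 0.1, 0.1), c(3, 2, 1)), "distinct")
})

test_that("batch fitting is order-independent and keeps flagged residues", {
  g <- gen_decays(c("3" = 8, "1" = 12, "2" = 10), seed = 4,
                  noise_sd = 0.02)
  fwd <- fit_rates(g$decays)
  rev <- fit_rates(g$decays[rev(seq_len(nrow(g$decays))), ])
  expect_equal(fwd, rev)
  expect_equal(fwd$residue_index, 1:3)
})

test_that("fitted rates are unbiased with calibrated uncertainties at 2% noise", {
  n <- 500
  truth <- 11.47
  g <- gen_decays(rep(truth, n), seed = 17, noise_sd = 0.02)
  fits <- fit_rates(g$decays)
  expect_true(all(fits$ok))
  bias <- abs(mean(fits$rate) - truth) / truth
  expect_lt(bias, 0.01)
  covered <- abs(fits$rate - truth) <= 2 * fits$se
  expect_gte(mean(covered), 0.9)
  # reported se consistent with the empirical spread
  expect_lt(abs(mean(fits$se) - sd(fits$rate)) / sd(fits$rate), 0.25)
})

test_that("hetNOE is the saturated/unsaturated ratio with sign passthrough", {
  expect_equal(hetnoe(1, 1)$noe, 1)
  expect_equal(hetnoe(0.70, 1.00)$noe, 0.70)
  expect_equal(hetnoe(-0.2, 1.0)$noe, -0.2)
  expect_error(hetnoe(1, 0), "zero")
  se <- hetnoe(0.7, 1.0, sd_saturated = 0.07, sd_unsaturated = 0.1)$se
  expect_equal(se, 0.7 * sqrt(0.01 + 0.01))
})

test_that("tumbling time reproduces the closed form and its invariances", {
  est <- tau_c_from_ratio(1.26, 11.47, 60.81)
  expect_equal(est$tau_c_ns, 9.03, tolerance = 0.01)
  expect_equal(tau_c_from_ratio(1.38, 10.31, 60.81)$tau_c_ns, 8.05,
               tolerance = 0.01)
  # ratio invariance: doubling both rates changes nothing
  expect_equal(tau_c_from_ratio(2 * 1.26, 2 * 11.47, 60.81)$tau_c_ns,
               est$tau_c_ns)
  # strictly increasing in R2/R1
  taus <- sapply(seq(2, 20, by = 0.5),
                 function(r2) tau_c_from_ratio(1, r2, 60.81)$tau_c_ns)
  expect_true(all(diff(taus) > 0))
  expect_error(tau_c_from_ratio(1, 1.1, 60.81), "sub-nanosecond")
  expect_error(tau_c_from_ratio(-1, 10, 60.81), "positive")
})

test_that("oligomer calls are a deterministic interval lookup", {
  expect_equal(classify_oligomer(r1 = 2.26, r2 = 6.08)$state, "monomer")
  expect_equal(classify_oligomer(r1 = 1.38, r2 = 10.31)$state, "dimer")
  expect_equal(classify_oligomer(r1 = 1.26, r2 = 11.47)$state, "dimer")
  expect_equal(classify_oligomer(r1 = 1, r2 = 40)$state,
               "higher-order/indeterminate")
  # invalid tumbling regime also falls through, not an error
  expect_equal(classify_oligomer(r1 = 10, r2 = 10)$state,
               "higher-order/indeterminate")
})

test_that("protein-level averages exclude flagged fits and flexible tails", {
  rates <- data.frame(residue_index = 1:4, rate = c(10, 10.2, 9.8, 50),
                      se = 0.1, amplitude = 100,
                      ok = c(TRUE, TRUE, TRUE, FALSE), reason = NA)
  noe <- data.frame(residue_index = 1:4, noe = c(0.8, 0.3, 0.75, 0.8))
  avg <- average_rates(rates, noe, noe_min = 0.6, trim = 0)
  expect_equal(avg$n_used, 2)
  expect_equal(avg$mean_rate, mean(c(10, 9.8)))
  expect_setequal(avg$excluded, c(2, 4))
})
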