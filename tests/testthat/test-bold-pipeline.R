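test_that("hrf_kernel: causality, peak location, limits, errors", {
  h <- hrf_kernel(hrf_params(), tr = 0.05, duration = 32)
  t <- seq(0, 32, by = 0.05)
  expect_true(all(h[t < 2.25] == 0))
  # analytic peak of t^alpha exp(-t/tau) shifted by delta: 2.25 + 2 * 1.25
  expect_lt(abs(t[which.max(h)] - 4.75), 0.05 + 1e-9)
  expect_equal(max(h), 1)
  # alpha = 0: the shape term drops out, leaving pure exponential decay
  # from onset (unit peak at the first sample at/after delta)
  h0 <- hrf_kernel(hrf_params(alpha = 0), tr = 0.5, duration = 10)
  t0 <- seq(0, 10, by = 0.5)
  on <- t0 >= 2.25
  t_peak <- min(t0[on])
  expect_equal(h0[on], exp(-(t0[on] - t_peak) / 1.25), tolerance = 1e-12)
  expect_true(all(h0[!on] == 0))
  expect_error(hrf_kernel(hrf_params(), tr = 1, duration = 2), "onset")
  expect_error(hrf_params(tau = 0), "tau")
})

test_that("build_design matches a direct-summation convolution oracle", {
  sched <- data.frame(onset_vol = c(1L, 41L), duration_vol = 8L,
                      condition = c("a", "b"))
  X <- build_design(sched, 60, 2)
  kern <- hrf_kernel(hrf_params(), 2)
  for (cc in c("a", "b")) {
    box <- numeric(60)
    i <- which(sched$condition == cc)
    box[sched$onset_vol[i] + 0:7] <- 1
    ref <- oracle_convolve(box, kern)
    ref <- ref / max(ref)
    expect_equal(unname(X[, cc]), ref, tolerance = 1e-10)
  }
  # columns are unit peak; block at run start peaks after onset then decays
  expect_equal(unname(apply(X[, c("a", "b")], 2, max)), c(1, 1))
  expect_lt(X[60, "a"], 0.01)
})

test_that("build_design structure and schedule validation", {
  X0 <- build_design(data.frame(onset_vol = integer(), duration_vol = integer(),
                                condition = character()), 20, 2)
  expect_identical(colnames(X0), c("intercept", "drift"))
  expect_error(
    build_design(data.frame(onset_vol = c(1L, 4L), duration_vol = 8L,
                            condition = c("a", "b")), 30, 2),
    "overlapping")
  expect_error(
    build_design(data.frame(onset_vol = 28L, duration_vol = 8L,
                            condition = "a"), 30, 2),
    "outside run")
})

test_that("fit_glm: OLS identities and rank handling", {
  sched <- data.frame(onset_vol = 5L, duration_vol = 8L, condition = "a")
  X <- build_design(sched, 40, 2)
  # constant signal: intercept only
  f <- fit_glm(rep(7, 40), X)
  expect_equal(unname(f$beta["intercept"]), 7)
  expect_equal(unname(f$beta[c("drift", "a")]), c(0, 0), tolerance = 1e-12)
  expect_equal(f$dof, 37)
  # adding a pure linear trend moves only the drift beta
  y1 <- 100 + 3 * X[, "a"]
  y2 <- y1 + 0.5 * X[, "drift"]
  b1 <- fit_glm(y1, X)$beta; b2 <- fit_glm(y2, X)$beta
  expect_equal(b2["drift"] - b1["drift"], c(drift = 0.5), tolerance = 1e-10)
  expect_equal(b1[c("intercept", "a")], b2[c("intercept", "a")],
               tolerance = 1e-10)
  # duplicated condition column -> singularity naming the column
  Xbad <- cbind(X, a2 = X[, "a"])
  expect_error(fit_glm(rep(1, 40), Xbad), "collinear.*a")
  expect_error(fit_glm(rep(1, 10), X), "does not match")
})

test_that("percent_signal_change and crowding_indices algebra", {
  expect_equal(
    unname(percent_signal_change(list(beta = c(intercept = 1000, drift = 2,
                                               a = 10, b = 0)))),
    c(1, 0))
  expect_error(percent_signal_change(list(beta = c(intercept = -5, a = 1))),
               "positive")

  idx <- crowding_indices(c(radial_present = 0.5, radial_absent = 0.8,
                            tangential_present = 0.9,
                            tangential_absent = 0.7))
  expect_equal(idx$c_bold_rad, -0.3)
  expect_equal(idx$c_bold_tan, 0.2)
  expect_equal(idx$a_bold, -0.5 / 1.5)
  # all equal -> zero; doubling all PSCs leaves A_BOLD unchanged
  same <- crowding_indices(c(radial_present = 0.4, radial_absent = 0.4,
                             tangential_present = 0.4,
                             tangential_absent = 0.4))
  expect_equal(c(same$c_bold_rad, same$c_bold_tan, same$a_bold), c(0, 0, 0))
  dbl <- crowding_indices(2 * c(radial_present = 0.5, radial_absent = 0.8,
                                tangential_present = 0.9,
                                tangential_absent = 0.7))
  expect_equal(dbl$a_bold, idx$a_bold)
  # zero denominator -> flagged missing, not an error
  z <- crowding_indices(c(radial_present = 0.1, radial_absent = 0.2,
                          tangential_present = 0.1,
                          tangential_absent = -0.2))
  expect_false(z$a_bold_defined)
  expect_true(is.na(z$a_bold))
  expect_error(crowding_indices(c(radial_present = 1)), "all four")
})

test_that("zero-noise round trip recovers amplitudes to 1e-6 relative", {
  cfg <- bold_config(noise_sd = 0, drift_slope = 0)
  for (session in c("pre", "post")) {
    amps <- crowdaniso:::session_amplitudes(cfg, session)
    run <- simulate_bold_run(cfg, amps, seed = 17)
    res <- analyze_bold_session(list(run), cfg$hrf)
    expect_equal(unname(res$psc[names(amps)]), unname(amps),
                 tolerance = 1e-6)
  }
  # drift and a baseline shift do not leak into condition betas
  cfg2 <- bold_config(noise_sd = 0, drift_slope = 0.4)
  amps <- crowdaniso:::session_amplitudes(cfg2, "pre")
  run2 <- simulate_bold_run(cfg2, amps, seed = 18)
  res2 <- analyze_bold_session(list(run2), cfg2$hrf)
  expect_equal(unname(res2$psc[names(amps)]), unname(amps),
               tolerance = 1e-6)
})

test_that("concatenated fitting agrees with run-averaged fitting", {
  cfg <- bold_config(noise_sd = 1, seed = 2)
  amps <- crowdaniso:::session_amplitudes(cfg, "pre")
  runs <- lapply(1:4, function(r) simulate_bold_run(cfg, amps, seed = 50 + r))
  avg <- analyze_bold_session(runs, cfg$hrf)
  cat_fit <- analyze_bold_session(runs, cfg$hrf, concatenate = TRUE)
  expect_equal(unname(cat_fit$psc), unname(avg$psc[names(cat_fit$psc)]),
               tolerance = 0.05)
})

test_that("averaging 8 runs shrinks the PSC standard error by ~ 1/sqrt(8)", {
  cfg <- bold_config(noise_sd = 5, ar1_coef = 0, drift_slope = 0)
  amps <- crowdaniso:::session_amplitudes(cfg, "pre")
  set.seed(99)
  one <- replicate(240, {
    analyze_bold_session(list(simulate_bold_run(cfg, amps)),
                         cfg$hrf)$psc[["radial_present"]]
  })
  eight <- replicate(60, {
    runs <- lapply(1:8, function(r) simulate_bold_run(cfg, amps))
    analyze_bold_session(runs, cfg$hrf)$psc[["radial_present"]]
  })
  ratio <- sd(eight) / sd(one)
  expect_lt(abs(ratio - 1 / sqrt(8)), 0.12)
})
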