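levels5 <- c(0.75, 1.25, 1.75, 2.25, 2.75)

test_that("fit recovers parameters from exact model proportions", {
  p <- psy_prob(levels5, mu = 1.8, sigma = 0.4, lapse = 0)
  fit <- fit_psychometric(levels5, p * 1000, n_trials = rep(1000, 5))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 1.8), 1e-3)
  expect_lt(abs(fit$sigma - 0.4), 1e-2)
  expect_lt(fit$lapse, 1e-3)
})

test_that("degenerate data are flagged, never a silent success", {
  # chance performance at every level
  fit <- fit_psychometric(levels5, rep(0.25 * 400, 5), n_trials = rep(400, 5))
  expect_false(fit$converged)
  # all correct
  fit2 <- fit_psychometric(levels5, rep(400, 5), n_trials = rep(400, 5))
  expect_false(fit2$converged)
  # all incorrect
  fit3 <- fit_psychometric(levels5, rep(0, 5), n_trials = rep(400, 5))
  expect_false(fit3$converged)
  # too few levels
  expect_error(fit_psychometric(c(1, 1), c(1, 0)), "2 distinct spacing")
})

test_that("threshold_at inverts the fitted curve analytically", {
  fit <- list(mu = 2, sigma = 0.5, guess = 0.25, lapse = 0)
  # closed form: 2 + 0.5 * qnorm(0.43 / 0.75)
  expect_equal(threshold_at(fit, 0.68), 2.092434, tolerance = 1e-6)
  # criterion at the curve midpoint returns mu
  mid <- 0.25 + 0.75 / 2
  expect_equal(threshold_at(fit, mid), 2)
  expect_error(threshold_at(fit, 0.2), "outside attainable")
  expect_error(threshold_at(list(mu = 2, sigma = 0.5, guess = 0.25,
                                 lapse = 0.05), 0.96),
               "outside attainable")
})

test_that("evaluating the fit at its threshold returns the criterion exactly", {
  set.seed(5)
  for (rep in 1:5) {
    mu <- runif(1, 1.2, 2.4); sig <- runif(1, 0.2, 0.6)
    n <- rep(337, 5)
    k <- rbinom(5, n, psy_prob(levels5, mu, sig, lapse = 0.02))
    fit <- fit_psychometric(levels5, k, n_trials = n)
    if (!fit$converged) next
    s_star <- threshold_at(fit, 0.68)
    expect_equal(unname(predict(fit, s_star)), 0.68, tolerance = 1e-12)
  }
})

test_that("fitted curve is monotone non-decreasing in spacing", {
  set.seed(6)
  k <- rbinom(5, 300, psy_prob(levels5, 1.7, 0.5, lapse = 0.01))
  fit <- fit_psychometric(levels5, k, n_trials = rep(300, 5))
  grid <- seq(0, 5, by = 0.01)
  expect_true(all(diff(predict(fit, grid)) >= 0))
})

test_that("threshold estimation is equivariant under affine rescaling", {
  p <- psy_prob(levels5, 1.9, 0.35, lapse = 0)
  fit1 <- fit_psychometric(levels5, p * 2000, n_trials = rep(2000, 5))
  for (ab in list(c(2, 0), c(0.5, 1), c(1.5, -0.3))) {
    a <- ab[1]; b <- ab[2]
    fit2 <- fit_psychometric(a * levels5 + b, p * 2000,
                             n_trials = rep(2000, 5))
    expect_equal(threshold_at(fit2), a * threshold_at(fit1) + b,
                 tolerance = 1e-4)
  }
})

test_that("parameter recovery at the study's per-day trial count", {
  set.seed(31)
  errs <- replicate(50, {
    mu <- runif(1, 1.0, 2.2)
    sig <- runif(1, 0.25, 0.55)
    counts <- c(67, 67, 67, 68, 68)
    k <- rbinom(5, counts, psy_prob(levels5, mu, sig, lapse = 0.02))
    fit <- fit_psychometric(levels5, k, n_trials = counts)
    fit$mu - mu
  })
  expect_lt(median(abs(errs)), 0.15)
})

test_that("anisotropy index: identities and domain", {
  expect_equal(anisotropy_psy(1.5, 1.5), 0)
  expect_equal(anisotropy_psy(3, 1), 0.5)
  # group means: (2.16 - 1.61) / (2.16 + 1.61)
  expect_equal(anisotropy_psy(2.16, 1.61), 0.1458886, tolerance = 1e-6)
  expect_error(anisotropy_psy(-1, 1), "positive")
  expect_error(anisotropy_psy(1, 0), "positive")
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0.1, 4); b <- runif(1, 0.1, 4)
    expect_equal(anisotropy_psy(a, b), -anisotropy_psy(b, a))
    expect_true(abs(anisotropy_psy(a, b)) < 1)
  }
  cz <- crowding_zone(2.16, 1.61)
  expect_equal(cz$ratio, 2.16 / 1.61)
  expect_equal(cz$a_psy, anisotropy_psy(2.16, 1.61))
})

test_that("weber_contrast: identities and the scanner luminances", {
  expect_equal(weber_contrast(100, 100), 0)
  expect_equal(weber_contrast(200, 100), 1)
  expect_equal(round(weber_contrast(0.19, 171.5), 3), 0.999)
  expect_error(weber_contrast(1, 0), "positive")
})

test_that("fit_study returns one converged row per cell on default data", {
  cfg <- tiny_study(seed = 3, n_subjects = 2, trials = 300)
  sim <- simulate_study(cfg)
  fits <- fit_study(sim$trials)
  expect_equal(nrow(fits), 2 * 2 * 4)
  expect_true(all(c("mu", "sigma", "lapse", "converged",
                    "critical_spacing") %in% names(fits)))
  expect_true(all(fits$n_trials == 300))
  expect_error(fit_study(data.frame(x = 1)), "must have columns")
})
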