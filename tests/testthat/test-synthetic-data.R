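test_that("sample_observers: degenerate draw, size, invariants", {
  cfg <- study_config(seed = 4)
  obs0 <- sample_observers(cfg, degenerate_group())
  expect_equal(nrow(obs0), 17)
  expect_true(all(abs(obs0$c_rad_pre - 2.16) < 1e-12))
  expect_true(all(abs(obs0$c_tan_pre - 1.61) < 1e-12))
  expect_true(all(abs(obs0$c_rad_post - 1.46) < 1e-12))
  expect_true(all(abs(obs0$c_tan_post - 1.05) < 1e-12))

  obs1 <- sample_observers(study_config(n_subjects = 1, seed = 2))
  expect_equal(nrow(obs1), 1)

  obs <- sample_observers(study_config(seed = 7))
  expect_true(all(obs$c_rad_pre >= obs$c_tan_pre))
  expect_true(all(obs$c_rad_post <= obs$c_rad_pre))
  expect_true(all(obs$c_tan_post <= obs$c_tan_pre))
  expect_true(all(obs[, c("c_rad_pre", "c_tan_pre", "c_rad_post",
                          "c_tan_post")] > 0))
  expect_true(all(obs$guess == 0.25))
  expect_true(all(obs$lapse >= 0 & obs$lapse <= 0.06))

  # Monte-Carlo check of the configured radial pre-training mean
  expect_lt(abs(mean(obs$c_rad_pre) - 2.16), 3 * 0.20 / sqrt(17))

  expect_error(observer_group(c_rad_pre = list(mean = -1, sd = 0.1)),
               "positive")
})

test_that("sample_observers is reproducible under seed", {
  a <- sample_observers(study_config(seed = 11))
  b <- sample_observers(study_config(seed = 11))
  c <- sample_observers(study_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("true_threshold: endpoints, limits, frozen arithmetic, monotone", {
  obs <- list(c_rad_pre = 2.16, c_rad_post = 1.46, c_tan_pre = 1.61,
              c_tan_post = 1.05, learn_tau = 1)
  expect_identical(true_threshold(obs, "radial", 1), 2.16)
  obs_fast <- within_list <- obs; obs_fast$learn_tau <- 1e-12
  expect_equal(true_threshold(obs_fast, "radial", 2), 1.46)
  # C_post + (C_pre - C_post) * exp(-3) with tau = 1
  expect_equal(true_threshold(obs, "radial", 4), 1.46 + 0.70 * exp(-3),
               tolerance = 1e-12)
  expect_equal(round(true_threshold(obs, "radial", 4), 4), 1.4949)
  expect_error(true_threshold(obs, "radial", 5), "out of range")
  expect_error(true_threshold(obs, "radial", 0), "out of range")

  # monotone non-increasing in day, across sampled observers
  many <- sample_observers(study_config(seed = 3))
  for (i in seq_len(nrow(many)))
    for (ax in c("radial", "tangential")) {
      cs <- sapply(1:4, function(d) true_threshold(many[i, ], ax, d))
      expect_true(all(diff(cs) <= 1e-12))
    }
})

test_that("simulate_training: counts, allocation, schema invariants", {
  cfg <- study_config(seed = 5)
  obs <- sample_observers(cfg)
  tr <- simulate_training(obs[1, ], cfg, seed = 99)
  # per-condition totals forced by the design
  expect_equal(unname(table(tr$axis)["radial"]), 1348)
  expect_equal(unname(table(tr$axis)["tangential"]), 1348)
  counts <- table(tr$spacing_deg[tr$day == 1 & tr$axis == "radial"])
  expect_equal(as.numeric(counts), c(67, 67, 67, 68, 68))
  expect_true(all(tr$spacing_deg %in% cfg$spacing_levels))
  expect_identical(tr$correct, tr$response == tr$gap_direction)
  expect_true(all(tr$gap_direction %in% c("left", "right", "up", "down")))
})

test_that("simulate_training is bit-reproducible under seed", {
  cfg <- tiny_study(seed = 2)
  obs <- sample_observers(cfg)
  a <- simulate_training(obs[1, ], cfg, seed = 123)
  b <- simulate_training(obs[1, ], cfg, seed = 123)
  c <- simulate_training(obs[1, ], cfg, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("empirical accuracy converges to the generative value at the
           true critical spacing", {
  # put the observer's (constant) threshold exactly on a tested level
  grp <- degenerate_group()
  grp$c_rad_pre$mean <- 1.75; grp$c_rad_post$mean <- 1.75
  cfg <- study_config(n_subjects = 1, n_days = 1,
                      trials_per_condition_per_day = 40000, seed = 1)
  obs <- sample_observers(cfg, grp)
  tr <- simulate_training(obs[1, ], cfg, seed = 42)
  sel <- tr$axis == "radial" & tr$spacing_deg == 1.75
  acc <- mean(tr$correct[sel])
  se <- sqrt(0.68 * 0.32 / sum(sel))
  expect_lt(abs(acc - 0.68), 4 * se)
})

test_that("psychometric ceiling: huge spacing, tiny spread, zero lapse", {
  grp <- degenerate_group()
  grp$sigma_psy$mean <- 0.01; grp$lapse$mean <- 0
  cfg <- study_config(n_subjects = 1, n_days = 1,
                      trials_per_condition_per_day = 2000, seed = 1)
  obs <- sample_observers(cfg, grp)
  tr <- simulate_training(obs[1, ], cfg, seed = 8)
  top <- tr$axis == "radial" & tr$spacing_deg == 2.75
  expect_equal(mean(tr$correct[top]), 1)
})

test_that("simulate_bold_run: structure, schedule, determinism, errors", {
  cfg <- bold_config(seed = 1)
  run <- simulate_bold_run(cfg, seed = 7)
  expect_equal(length(run$signal), 136)
  expect_equal(nrow(run$schedule), 8)
  expect_true(all(run$schedule$duration_vol * run$tr == 16))
  expect_equal(as.numeric(table(run$schedule$condition)), rep(2, 4))
  # alternation: stimulation onsets every 16 volumes starting at volume 9
  expect_equal(sort(run$schedule$onset_vol), 9 + 16 * (0:7))

  a <- simulate_bold_run(cfg, seed = 31)
  b <- simulate_bold_run(cfg, seed = 31)
  c <- simulate_bold_run(cfg, seed = 32)
  expect_identical(a, b)
  expect_false(identical(a$signal, c$signal))

  expect_error(simulate_bold_run(cfg, amplitudes = c(radial_present = 1)),
               "missing condition amplitude")
})

test_that("zero-everything BOLD run is constant at baseline", {
  cfg <- bold_config(noise_sd = 0, drift_slope = 0)
  amps <- c(radial_present = 0, radial_absent = 0,
            tangential_present = 0, tangential_absent = 0)
  run <- simulate_bold_run(cfg, amps, seed = 1)
  expect_equal(run$signal, rep(1000, 136))
})

test_that("bold_config validates its invariants", {
  expect_error(bold_config(n_fix_blocks = 8), "alternation")
  expect_error(bold_config(n_stim_blocks = 6), "multiple of the 4")
  expect_error(bold_config(ar1_coef = 1), "ar1_coef")
  expect_error(bold_config(block_duration = 15), "multiple of tr")
})

test_that("observer_amplitudes couples the radial change to the gain", {
  cfg <- bold_config()
  obs <- sample_observers(study_config(seed = 21))
  pre <- observer_amplitudes(obs[3, ], cfg, "pre")
  post <- observer_amplitudes(obs[3, ], cfg, "post")
  cfg_pre <- c(0.60, 0.90); cfg_post <- c(0.90, 0.86)
  g <- obs$gain[3]
  expect_equal(unname(post[c("radial_present", "radial_absent")]),
               cfg_pre + g * (cfg_post - cfg_pre))
  # uncoupled config uses the independent gain instead
  cfg_off <- bold_config(coupling = FALSE)
  post_off <- observer_amplitudes(obs[3, ], cfg_off, "post")
  g2 <- obs$gain_bold_indep[3]
  expect_equal(unname(post_off[c("radial_present", "radial_absent")]),
               cfg_pre + g2 * (cfg_post - cfg_pre))
})

test_that("child_seed is deterministic and in integer range", {
  expect_identical(child_seed(1, 5), child_seed(1, 5))
  expect_false(child_seed(1, 5) == child_seed(1, 6))
  s <- sapply(0:50, function(k) child_seed(2^30, k))
  expect_true(all(s >= 0 & s < 2^31))
  expect_true(all(s == as.integer(s)))
})
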