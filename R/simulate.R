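#' Behavioural study configuration
#'
#' Defaults mirror the study design: 17 subjects trained over 4 consecutive
#' days on a 4AFC Landolt-C crowding task with radial and tangential flanker
#' arrangements, spacings sampled by the method of constant stimuli at
#' 0.75--2.75 degrees in 0.5-degree steps, 337 trials per flanker condition
#' per day (1348 over the 4 days).
#'
#' @param n_subjects number of observers.
#' @param n_days number of training days.
#' @param trials_per_condition_per_day trials per flanker axis per day.
#' @param spacing_levels strictly increasing positive spacings (degrees).
#' @param seed integer seed controlling observer sampling and trial noise.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 17, n_days = 4,
                         trials_per_condition_per_day = 337,
                         spacing_levels = c(0.75, 1.25, 1.75, 2.25, 2.75),
                         seed = 1L) {
  if (n_subjects < 1 || n_days < 1 || trials_per_condition_per_day < 1)
    stop("counts must be positive")
  if (any(spacing_levels <= 0) || is.unsorted(spacing_levels, strictly = TRUE))
    stop("spacing_levels must be strictly increasing and positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days),
                 trials_per_condition_per_day =
                   as.integer(trials_per_condition_per_day),
                 spacing_levels = as.numeric(spacing_levels),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Group-level observer parameter summary
#'
#' Means and between-subject SDs of the generative observer parameters.
#' Defaults: pre-training critical spacing 2.16 (SD 0.2) deg radial and
#' 1.61 (SD 0.15) deg tangential; post-training 1.46 (SD 0.13) deg radial
#' and 1.05 (SD 0.11) deg tangential. The dispersions are used directly as
#' between-subject SDs: larger spreads would place observers outside the
#' 0.75--2.75 deg constant-stimuli range, i.e. outside what the behavioural
#' design can measure.
#'
#' Each observer carries a latent training gain (mean 1) that scales both
#' axes' critical-spacing shrinkage: radial shrinkage scales with `gain`,
#' tangential with `1 + coupling_kappa * (gain - 1)` plus independent noise.
#' When BOLD coupling is on, the same gain scales that observer's
#' training-induced change in radial BOLD suppression, which is what makes
#' the per-subject behavioural and BOLD anisotropy-index changes correlate
#' positively; `coupling_kappa` sets the strength of that correlation (its
#' default is calibrated so the coupled replicate-level Spearman correlation
#' is near the mid-0.5s at n = 17, the order of effect the study design is
#' built around).
#'
#' @param c_rad_pre,c_tan_pre,c_rad_post,c_tan_post lists `(mean, sd)` in
#'   degrees.
#' @param learn_tau list `(mean, sd)`: exponential learning time constant
#'   (days).
#' @param sigma_psy list `(mean, sd)`: psychometric spread (degrees).
#' @param lapse list `(mean, sd)`: lapse rate, truncated to `[0, 0.06]`.
#' @param gain_sd SD of the latent training gain (mean 1, truncated to
#'   `[0.1, 1.9]`).
#' @param coupling_kappa slope of the tangential gain on the common latent
#'   gain (1 = both axes share the gain exactly).
#' @param tan_gain_noise SD of the independent tangential-gain noise.
#' @return object of class `observer_group`.
#' @export
observer_group <- function(c_rad_pre = list(mean = 2.16, sd = 0.20),
                           c_tan_pre = list(mean = 1.61, sd = 0.15),
                           c_rad_post = list(mean = 1.46, sd = 0.13),
                           c_tan_post = list(mean = 1.05, sd = 0.11),
                           learn_tau = list(mean = 1.0, sd = 0.3),
                           sigma_psy = list(mean = 0.4, sd = 0.08),
                           lapse = list(mean = 0.02, sd = 0.01),
                           gain_sd = 0.35, coupling_kappa = 2,
                           tan_gain_noise = 0.15) {
  for (p in list(c_rad_pre, c_tan_pre, c_rad_post, c_tan_post)) {
    if (p$mean <= 0) stop("critical-spacing means must be positive")
    if (p$sd < 0) stop("SDs must be non-negative")
  }
  if (c_rad_post$mean > c_rad_pre$mean || c_tan_post$mean > c_tan_pre$mean)
    stop("post-training means must not exceed pre-training means")
  if (c_tan_pre$mean > c_rad_pre$mean)
    stop("radial pre-training mean must be >= tangential (radial elongation)")
  structure(list(c_rad_pre = c_rad_pre, c_tan_pre = c_tan_pre,
                 c_rad_post = c_rad_post, c_tan_post = c_tan_post,
                 learn_tau = learn_tau, sigma_psy = sigma_psy,
                 lapse = lapse, gain_sd = gain_sd,
                 coupling_kappa = coupling_kappa,
                 tan_gain_noise = tan_gain_noise),
            class = "observer_group")
}

# truncated-normal draws by rejection; exact, fine at these acceptance rates
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample a cohort of simulated observers
#'
#' Draws per-subject generative parameters from truncated normals (truncated
#' at 0.1 degrees below and at twice the group mean above). The pair of
#' pre-training spacings is redrawn until the radial value is at least the
#' tangential one (radial elongation of the crowding zone). Post-training
#' spacings are constructed from the pre-training values minus the latent
#' training gain times the configured mean pre-post shrinkage, clamped to
#' stay positive and not exceed the pre value:
#' radial shrinkage scales with the latent `gain`, tangential with
#' `gain_tan = 1 + coupling_kappa * (gain - 1) + noise`. `gain_bold_indep`
#' is an independent gain used for the BOLD amplitudes when
#' behavioural-BOLD coupling is switched off.
#'
#' @param config a [study_config()].
#' @param group an [observer_group()] parameter summary.
#' @return data frame of class `observer_params`, one row per observer:
#'   `subject_id`, `c_rad_pre`, `c_tan_pre`, `c_rad_post`, `c_tan_post`,
#'   `learn_tau`, `sigma_psy`, `lapse`, `guess`, `gain`, `gain_tan`,
#'   `gain_bold_indep`.
#' @export
#' @examples
#' obs <- sample_observers(study_config(seed = 42))
#' colMeans(obs[, c("c_rad_pre", "c_tan_pre")])
sample_observers <- function(config = study_config(),
                             group = observer_group()) {
  stopifnot(inherits(config, "study_config"), inherits(group, "observer_group"))
  set.seed(config$seed)
  n <- config$n_subjects

  c_rad_pre <- numeric(n); c_tan_pre <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- rtruncnorm(1, group$c_rad_pre$mean, group$c_rad_pre$sd,
                      0.1, 2 * group$c_rad_pre$mean)
      t <- rtruncnorm(1, group$c_tan_pre$mean, group$c_tan_pre$sd,
                      0.1, 2 * group$c_tan_pre$mean)
      if (r >= t) break
    }
    c_rad_pre[i] <- r; c_tan_pre[i] <- t
  }

  gain <- rtruncnorm(n, 1, group$gain_sd, 0.1, 1.9)
  gain_tan <- pmin(pmax(1 + group$coupling_kappa * (gain - 1) +
                          stats::rnorm(n, 0, group$tan_gain_noise),
                        0.05), 1.95)
  gain_bold_indep <- rtruncnorm(n, 1, group$gain_sd, 0.1, 1.9)

  d_rad <- group$c_rad_pre$mean - group$c_rad_post$mean
  d_tan <- group$c_tan_pre$mean - group$c_tan_post$mean
  c_rad_post <- pmin(pmax(c_rad_pre - gain * d_rad, 0.1), c_rad_pre)
  c_tan_post <- pmin(pmax(c_tan_pre - gain_tan * d_tan, 0.1), c_tan_pre)

  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    c_rad_pre = c_rad_pre, c_tan_pre = c_tan_pre,
    c_rad_post = c_rad_post, c_tan_post = c_tan_post,
    learn_tau = rtruncnorm(n, group$learn_tau$mean, group$learn_tau$sd,
                           0.05, 2 * group$learn_tau$mean),
    sigma_psy = rtruncnorm(n, group$sigma_psy$mean, group$sigma_psy$sd,
                           0.05, 2 * group$sigma_psy$mean),
    lapse = rtruncnorm(n, group$lapse$mean, group$lapse$sd, 0, 0.06),
    guess = 0.25,
    gain = gain, gain_tan = gain_tan, gain_bold_indep = gain_bold_indep,
    stringsAsFactors = FALSE)
  class(out) <- c("observer_params", "data.frame")
  out
}

#' True critical spacing of an observer on a given training day
#'
#' Exponential learning curve interpolating between the pre- and
#' post-training endpoints:
#' `C(day) = C_post + (C_pre - C_post) * exp(-(day - 1) / learn_tau)`,
#' so day 1 equals `C_pre` exactly and the curve decays monotonically
#' towards `C_post`.
#'
#' @param observer one row of an `observer_params` frame (or an equivalent
#'   list).
#' @param axis `"radial"` or `"tangential"`.
#' @param day training day, `1..n_days`.
#' @param n_days number of training days (range check).
#' @return critical spacing in degrees.
#' @export
true_threshold <- function(observer, axis = c("radial", "tangential"),
                           day, n_days = 4) {
  axis <- match.arg(axis)
  if (any(day < 1) || any(day > n_days)) stop("day out of range")
  pre <- if (axis == "radial") observer$c_rad_pre else observer$c_tan_pre
  post <- if (axis == "radial") observer$c_rad_post else observer$c_tan_post
  ifelse(day == 1, pre,
         post + (pre - post) * exp(-(day - 1) / observer$learn_tau))
}

# per-level trial allocation: floor(n/levels) each, remainder to the largest
# spacings (stabilises the upper asymptote of the psychometric fit)
allocate_levels <- function(n_trials, levels) {
  k <- length(levels)
  base <- n_trials %/% k
  rem <- n_trials %% k
  counts <- rep(base, k)
  if (rem > 0) counts[(k - rem + 1):k] <- base + 1
  counts
}

#' Simulate the 4-day training trial table for one observer
#'
#' For each day x flanker axis, presents `trials_per_condition_per_day`
#' trials by the method of constant stimuli (levels allocated as evenly as
#' possible, remainder to the largest spacings, order randomised). The
#' probability of a correct gap report at spacing `s` is the 4AFC
#' cumulative-normal model with the location set so that accuracy is exactly
#' 68% at that day's true critical spacing. Wrong responses are uniform over
#' the three incorrect gap directions.
#'
#' Uses the current RNG state; call [set.seed()] or pass `seed` for
#' reproducibility.
#'
#' @param observer one row of an `observer_params` frame.
#' @param config a [study_config()].
#' @param seed optional integer seed.
#' @param criterion accuracy defining the critical spacing (0.68).
#' @return data frame: `subject_id`, `day`, `axis`, `spacing_deg`,
#'   `gap_direction`, `response`, `correct`.
#' @export
simulate_training <- function(observer, config = study_config(), seed = NULL,
                              criterion = 0.68) {
  if (!is.null(seed)) set.seed(seed)
  dirs <- c("left", "right", "up", "down")
  counts <- allocate_levels(config$trials_per_condition_per_day,
                            config$spacing_levels)
  out <- vector("list", config$n_days * 2)
  idx <- 1
  for (day in seq_len(config$n_days)) {
    for (axis in c("radial", "tangential")) {
      c_day <- true_threshold(observer, axis, day, config$n_days)
      # location such that P(correct | c_day) = criterion
      z <- stats::qnorm((criterion - observer$guess) /
                          (1 - observer$guess - observer$lapse))
      mu <- c_day - observer$sigma_psy * z
      spacing <- sample(rep(config$spacing_levels, counts))
      p <- psy_prob(spacing, mu, observer$sigma_psy, observer$guess,
                    observer$lapse)
      gap <- sample(dirs, length(spacing), replace = TRUE)
      correct <- stats::runif(length(spacing)) < p
      response <- gap
      nwrong <- sum(!correct)
      if (nwrong > 0) {
        wrong_pick <- function(g) sample(setdiff(dirs, g), 1)
        response[!correct] <- vapply(gap[!correct], wrong_pick, character(1))
      }
      out[[idx]] <- data.frame(
        subject_id = observer$subject_id, day = day, axis = axis,
        spacing_deg = spacing, gap_direction = gap, response = response,
        correct = correct, stringsAsFactors = FALSE)
      idx <- idx + 1
    }
  }
  do.call(rbind, out)
}

#' Simulate the full behavioural study
#'
#' Samples (or reuses) a cohort and simulates every observer's training
#' trials, seeded from `config$seed` so the result is bit-reproducible.
#'
#' @param config a [study_config()].
#' @param group an [observer_group()].
#' @param observers optional pre-sampled `observer_params` frame.
#' @return list with `observers` and the pooled `trials` table.
#' @export
simulate_study <- function(config = study_config(), group = observer_group(),
                           observers = NULL) {
  if (is.null(observers)) observers <- sample_observers(config, group)
  set.seed(child_seed(config$seed, 1L))
  trials <- do.call(rbind, lapply(seq_len(nrow(observers)), function(i) {
    simulate_training(observers[i, ], config)
  }))
  list(observers = observers, trials = trials)
}

#' Derive a child seed from a master seed
#'
#' Counter-based fan-out so pipeline stages can be rerun independently yet
#' reproducibly. Result is a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param counter stage counter (>= 0).
#' @return integer seed.
#' @export
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + counter) %% 2147483647)
}
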