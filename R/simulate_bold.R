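#' Default per-condition BOLD response amplitudes (percent signal change)
#'
#' Group-mean evoked amplitudes for the four stimulus conditions (flanker
#' axis x target present/absent) in the pre- and post-training sessions.
#' The defaults are configuration, not measured ground truth: they are
#' chosen to reproduce the qualitative pre/post pattern in early visual
#' cortex -- before training, adding a target to radial flankers suppresses
#' the response (radial `C_BOLD < 0`) while adding it to tangential flankers
#' enhances it; after training the radial suppression is released
#' (`C_BOLD_rad` near zero or positive) and tangential changes are small.
#'
#' @return data frame with columns `session`, `axis`, `target`, `psc`.
#' @export
default_bold_amplitudes <- function() {
  data.frame(
    session = rep(c("pre", "post"), each = 4),
    axis = rep(c("radial", "radial", "tangential", "tangential"), 2),
    target = rep(c("present", "absent"), 4),
    psc = c(0.60, 0.90, 0.95, 0.75,   # pre:  C_rad = -0.30, C_tan = +0.20
            0.90, 0.86, 0.92, 0.78),  # post: C_rad = +0.04, C_tan = +0.14
    stringsAsFactors = FALSE)
}

#' BOLD simulation configuration
#'
#' Defaults mirror the scanning protocol: TR = 2 s; alternating 16-s
#' fixation and stimulation blocks (9 fixation, 8 stimulation, so each run
#' is 17 x 16 s = 272 s = 136 volumes); each of the four stimulus conditions
#' occupies exactly 2 stimulation blocks per run, in randomised order; 8
#' runs per scanning session.
#'
#' Noise is stationary AR(1) Gaussian plus a linear drift, the minimal
#' temporally correlated model for an ROI-averaged time series. At
#' `baseline_level = 1000` and `noise_sd = 3` the temporal SNR is about 330,
#' at the optimistic end of what averaging over a multi-voxel early-visual ROI achieves.
#'
#' @param tr repetition time (seconds).
#' @param block_duration block length (seconds); must be a multiple of `tr`.
#' @param n_stim_blocks stimulation blocks per run (multiple of 4).
#' @param n_fix_blocks fixation blocks per run (`n_stim_blocks + 1`,
#'   alternation starting and ending with fixation).
#' @param runs_per_session fMRI runs per scanning session.
#' @param amplitudes condition amplitude table as in
#'   [default_bold_amplitudes()].
#' @param baseline_level baseline signal level (arbitrary scanner units).
#' @param noise_sd stationary SD of the AR(1) noise (signal units).
#' @param ar1_coef AR(1) autocorrelation, in `[0, 1)`.
#' @param drift_slope linear drift (signal units per volume).
#' @param hrf an [hrf_params()].
#' @param coupling logical: couple the post-training radial amplitude change
#'   to the observer's behavioural training gain (see [sample_observers()]).
#' @param seed integer seed.
#' @return object of class `bold_config`.
#' @export
bold_config <- function(tr = 2, block_duration = 16, n_stim_blocks = 8,
                        n_fix_blocks = 9, runs_per_session = 8,
                        amplitudes = default_bold_amplitudes(),
                        baseline_level = 1000, noise_sd = 3,
                        ar1_coef = 0.3, drift_slope = 0.05,
                        hrf = hrf_params(), coupling = TRUE, seed = 1L) {
  if (tr <= 0 || block_duration <= 0) stop("tr and block_duration must be > 0")
  if (block_duration %% tr != 0)
    stop("block_duration must be a multiple of tr")
  if (n_stim_blocks %% 4 != 0)
    stop("n_stim_blocks must be a multiple of the 4 conditions")
  if (n_fix_blocks != n_stim_blocks + 1)
    stop("alternation requires n_fix_blocks = n_stim_blocks + 1")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must be in [0, 1)")
  if (baseline_level <= 0) stop("baseline_level must be positive")
  need <- c("session", "axis", "target", "psc")
  if (!all(need %in% names(amplitudes)))
    stop("amplitudes needs columns: ", paste(need, collapse = ", "))
  structure(list(tr = tr, block_duration = block_duration,
                 n_stim_blocks = as.integer(n_stim_blocks),
                 n_fix_blocks = as.integer(n_fix_blocks),
                 runs_per_session = as.integer(runs_per_session),
                 amplitudes = amplitudes, baseline_level = baseline_level,
                 noise_sd = noise_sd, ar1_coef = ar1_coef,
                 drift_slope = drift_slope, hrf = hrf,
                 coupling = isTRUE(coupling), seed = as.integer(seed)),
            class = "bold_config")
}

#' Run length in volumes for a BOLD configuration
#' @param config a [bold_config()].
#' @return integer number of volumes
#'   (`(n_stim_blocks + n_fix_blocks) * block_duration / tr`; 136 at
#'   defaults).
#' @export
run_volumes <- function(config) {
  as.integer((config$n_stim_blocks + config$n_fix_blocks) *
               config$block_duration / config$tr)
}

# amplitudes of one session as a named vector keyed "axis_target"
session_amplitudes <- function(config, session) {
  a <- config$amplitudes[config$amplitudes$session == session, ]
  key <- paste(a$axis, a$target, sep = "_")
  need <- c("radial_present", "radial_absent",
            "tangential_present", "tangential_absent")
  if (!all(need %in% key))
    stop("missing condition amplitude(s) for session '", session, "': ",
         paste(setdiff(need, key), collapse = ", "))
  stats::setNames(a$psc, key)[need]
}

#' Per-observer condition amplitudes for one session
#'
#' The pre-training amplitudes are the configured group values. For the
#' post-training session the radial amplitudes are obtained by scaling the
#' configured pre-to-post radial change by the observer's training gain
#' (`gain` when `coupling = TRUE`, the independent `gain_bold_indep`
#' otherwise), so that subjects who learn more show a larger release of
#' radial suppression. Tangential amplitudes use the configured values.
#'
#' @param observer one row of an `observer_params` frame.
#' @param config a [bold_config()].
#' @param session `"pre"` or `"post"`.
#' @return named numeric vector of four condition amplitudes (PSC units).
#' @export
observer_amplitudes <- function(observer, config, session = c("pre", "post")) {
  session <- match.arg(session)
  pre <- session_amplitudes(config, "pre")
  if (session == "pre") return(pre)
  post <- session_amplitudes(config, "post")
  g <- if (config$coupling) observer$gain else observer$gain_bold_indep
  rad <- c("radial_present", "radial_absent")
  post[rad] <- pre[rad] + g * (post[rad] - pre[rad])
  post
}

#' Simulate one ROI-averaged BOLD run
#'
#' Builds a randomised block schedule (each condition in exactly
#' `n_stim_blocks / 4` stimulation blocks, alternating with fixation) and
#' generates
#' `signal = baseline * (1 + sum_c (amp_c / 100) * regressor_c) + drift +
#' AR(1) noise`, where `regressor_c` is the unit-peak HRF-convolved boxcar
#' also used by [build_design()] -- so with zero noise the configured
#' amplitudes are recovered exactly by the GLM.
#'
#' @param config a [bold_config()].
#' @param amplitudes named numeric vector of the four condition amplitudes
#'   (PSC units), e.g. from [observer_amplitudes()].
#' @param seed optional integer seed for this run.
#' @return object of class `bold_run`: list with `signal`, `schedule`
#'   (data frame `onset_vol`, `duration_vol`, `condition`), `tr`.
#' @export
#' @examples
#' run <- simulate_bold_run(bold_config(), seed = 7)
#' length(run$signal)  # 136
simulate_bold_run <- function(config = bold_config(),
                              amplitudes = session_amplitudes(config, "pre"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("radial_present", "radial_absent",
            "tangential_present", "tangential_absent")
  if (!all(need %in% names(amplitudes)))
    stop("missing condition amplitude(s): ",
         paste(setdiff(need, names(amplitudes)), collapse = ", "))
  volumes <- run_volumes(config)
  block_vols <- as.integer(config$block_duration / config$tr)
  conds <- sample(rep(need, config$n_stim_blocks / 4L))
  # run starts and ends with fixation: stim block b occupies the 2b-th block
  schedule <- data.frame(
    onset_vol = block_vols * (2L * seq_len(config$n_stim_blocks) - 1L) + 1L,
    duration_vol = block_vols,
    condition = conds, stringsAsFactors = FALSE)
  reg <- condition_regressors(schedule, volumes, config$tr, config$hrf)
  evoked <- drop(reg %*% (amplitudes[colnames(reg)] / 100))
  drift <- config$drift_slope * (seq_len(volumes) - (volumes + 1) / 2)
  noise <- if (config$noise_sd > 0) {
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coef^2)
    e <- stats::rnorm(volumes, 0, innov_sd)
    as.numeric(stats::filter(e, config$ar1_coef, method = "recursive",
                             init = stats::rnorm(1, 0, config$noise_sd)))
  } else numeric(volumes)
  structure(list(
    signal = config$baseline_level * (1 + evoked) + drift + noise,
    schedule = schedule, tr = config$tr), class = "bold_run")
}

#' Simulate all runs of one observer's scanning session
#'
#' @param observer one row of an `observer_params` frame.
#' @param config a [bold_config()].
#' @param session `"pre"` or `"post"`.
#' @param seed integer seed; per-run child seeds are derived from it.
#' @return list of `bold_run` objects of length `runs_per_session`.
#' @export
simulate_bold_session <- function(observer, config = bold_config(),
                                  session = c("pre", "post"),
                                  seed = config$seed) {
  session <- match.arg(session)
  amps <- observer_amplitudes(observer, config, session)
  lapply(seq_len(config$runs_per_session), function(r)
    simulate_bold_run(config, amps, seed = child_seed(seed, r)))
}

#' Simulate and analyse the full fMRI arm of the study
#'
#' For every observer and session (pre, post), simulates
#' `runs_per_session` runs and reduces them to condition PSCs and crowding
#' indices with [analyze_bold_session()].
#'
#' @param observers an `observer_params` frame from [sample_observers()].
#' @param config a [bold_config()].
#' @param seed master seed (default `config$seed`).
#' @return data frame, one row per observer x session: the four condition
#'   PSCs, `c_bold_rad`, `c_bold_tan`, `a_bold`.
#' @export
bold_study_indices <- function(observers, config = bold_config(),
                               seed = config$seed) {
  rows <- list()
  for (i in seq_len(nrow(observers))) {
    for (session in c("pre", "post")) {
      sess_seed <- child_seed(seed, 1000L * i +
                                ifelse(session == "pre", 0L, 500L))
      runs <- simulate_bold_session(observers[i, ], config, session,
                                    seed = sess_seed)
      res <- analyze_bold_session(runs, config$hrf)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = observers$subject_id[i], session = session,
        radial_present = res$psc[["radial_present"]],
        radial_absent = res$psc[["radial_absent"]],
        tangential_present = res$psc[["tangential_present"]],
        tangential_absent = res$psc[["tangential_absent"]],
        c_bold_rad = res$indices$c_bold_rad,
        c_bold_tan = res$indices$c_bold_tan,
        a_bold = res$indices$a_bold, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
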