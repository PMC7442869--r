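#' Hemodynamic response function parameters
#'
#' Gamma-variate impulse response with onset delay `delta`, dispersion `tau`
#' and shape exponent `alpha`:
#' `h(t) = ((t - delta)/tau)^alpha * exp(-(t - delta)/tau)` for `t >= delta`,
#' 0 before. The defaults (`delta` = 2.25 s, `tau` = 1.25 s, `alpha` = 2)
#' are the FsFast-convention parameters; the kernel peaks at
#' `t = delta + alpha * tau` = 4.75 s. (These parameters are often described
#' as a "cumulative gamma" in that toolkit's terminology; the impulse
#' response itself is the gamma variate above -- an actually cumulative
#' distribution function would never return to baseline and could not serve
#' as an HRF.)
#'
#' @param delta onset delay (seconds), `>= 0`.
#' @param tau dispersion (seconds), `> 0`.
#' @param alpha shape exponent, `>= 0`.
#' @return object of class `hrf_params`.
#' @export
hrf_params <- function(delta = 2.25, tau = 1.25, alpha = 2) {
  if (tau <= 0 || alpha < 0 || delta < 0)
    stop("require tau > 0, alpha >= 0, delta >= 0")
  structure(list(delta = delta, tau = tau, alpha = alpha),
            class = "hrf_params")
}

#' Sample the HRF kernel at the scan repetition time
#'
#' Evaluates the gamma-variate response on `t = 0, tr, 2 tr, ...` up to
#' `duration` seconds and normalises the sampled kernel to unit peak.
#'
#' @param params an [hrf_params()].
#' @param tr sampling interval (seconds).
#' @param duration kernel support to cover (seconds, default 32).
#' @return numeric vector of kernel samples (unit peak).
#' @export
#' @examples
#' h <- hrf_kernel(hrf_params(), tr = 2)
#' which.max(h)  # near delta + alpha * tau = 4.75 s
hrf_kernel <- function(params = hrf_params(), tr, duration = 32) {
  stopifnot(inherits(params, "hrf_params"), tr > 0)
  if (duration < params$delta)
    stop("duration must cover the kernel onset (duration >= delta)")
  t <- seq(0, duration, by = tr)
  u <- (t - params$delta) / params$tau
  h <- ifelse(t >= params$delta, u^params$alpha * exp(-pmax(u, 0)), 0)
  if (max(h) <= 0) stop("kernel has empty support on this grid")
  h / max(h)
}

# convolved, unit-peak condition regressors shared by the generator and the
# design builder: the generative model for condition responses IS the GLM model
condition_regressors <- function(schedule, volumes, tr, hrf = hrf_params(),
                                 hrf_duration = 32) {
  stopifnot(all(c("onset_vol", "duration_vol", "condition") %in%
                  names(schedule)))
  if (nrow(schedule) > 0) {
    occ <- unlist(lapply(seq_len(nrow(schedule)), function(i)
      schedule$onset_vol[i] + seq_len(schedule$duration_vol[i]) - 1L))
    if (anyDuplicated(occ)) stop("schedule error: overlapping blocks")
    if (any(occ < 1) || any(occ > volumes))
      stop("schedule error: block outside run")
  }
  kern <- hrf_kernel(hrf, tr, hrf_duration)
  conds <- sort(unique(as.character(schedule$condition)))
  reg <- matrix(0, volumes, length(conds), dimnames = list(NULL, conds))
  for (cc in conds) {
    box <- numeric(volumes)
    sel <- schedule$condition == cc
    for (i in which(sel)) {
      v <- schedule$onset_vol[i] + seq_len(schedule$duration_vol[i]) - 1L
      box[v] <- 1
    }
    full <- stats::convolve(box, rev(kern), type = "open")[seq_len(volumes)]
    if (max(full) > 0) full <- full / max(full)
    reg[, cc] <- full
  }
  reg
}

#' Build the block-design GLM design matrix
#'
#' One HRF-convolved boxcar regressor per condition (normalised to unit peak
#' so that betas are in signal units and percent signal change is
#' `100 * beta / intercept`), plus an intercept and a mean-centred linear
#' drift term.
#'
#' @param schedule data frame with `onset_vol` (1-based volume index),
#'   `duration_vol`, `condition` for each stimulation block.
#' @param volumes run length in volumes.
#' @param tr repetition time (seconds).
#' @param hrf an [hrf_params()].
#' @param hrf_duration kernel support (seconds).
#' @return numeric matrix of class `design_matrix`, columns `intercept`,
#'   `drift`, then one per condition label (sorted).
#' @export
build_design <- function(schedule, volumes, tr, hrf = hrf_params(),
                         hrf_duration = 32) {
  reg <- condition_regressors(schedule, volumes, tr, hrf, hrf_duration)
  drift <- seq_len(volumes) - (volumes + 1) / 2
  X <- cbind(intercept = rep(1, volumes), drift = drift, reg)
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit the run-level GLM by ordinary least squares
#'
#' @param run a `bold_run` (see [simulate_bold_run()]) or a numeric signal
#'   vector.
#' @param design a [build_design()] matrix with matching row count.
#' @return object of class `bold_glm_fit`: named `beta`, `residual_variance`
#'   (RSS / dof), `dof`, `fitted`, `residuals`.
#' @export
fit_glm <- function(run, design) {
  y <- if (is.list(run)) run$signal else run
  X <- unclass(design)
  if (length(y) != nrow(X))
    stop("signal length does not match design rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  dof <- length(y) - ncol(X)
  if (dof <= 0) stop("no residual degrees of freedom")
  structure(list(beta = beta, residual_variance = sum(res^2) / dof,
                 dof = dof, fitted = fitted, residuals = res),
            class = "bold_glm_fit")
}

#' Percent signal change per condition
#'
#' With unit-peak condition regressors, the peak evoked response of condition
#' `c` as a percentage of baseline is `PSC_c = 100 * beta_c / beta_intercept`.
#'
#' @param fit a `bold_glm_fit` (or a list with a named `beta` vector).
#' @return named numeric vector of PSCs, one per condition column.
#' @export
percent_signal_change <- function(fit) {
  beta <- fit$beta
  b0 <- beta[["intercept"]]
  if (!is.finite(b0) || b0 <= 0)
    stop("baseline (intercept) estimate must be positive")
  cond <- setdiff(names(beta), c("intercept", "drift"))
  100 * beta[cond] / b0
}

#' BOLD crowding and anisotropy indices from condition PSCs
#'
#' The BOLD crowding index per flanker axis is the target-present minus
#' target-absent percent signal change,
#' `C_BOLD = R_Tp - R_Ta`; negative values indicate response suppression by
#' crowding. The BOLD anisotropy index normalises the radial-minus-tangential
#' difference of crowding indices by the summed target-absent responses:
#' `A_BOLD = (C_BOLD_rad - C_BOLD_tan) / (R_Ta_rad + R_Ta_tang)`.
#' A zero denominator yields `a_bold = NA` with `a_bold_defined = FALSE`
#' (propagated as missing, not an error).
#'
#' @param psc named numeric vector with elements `radial_present`,
#'   `radial_absent`, `tangential_present`, `tangential_absent`.
#' @return object of class `crowding_indices_bold`: list with `psc`,
#'   `c_bold_rad`, `c_bold_tan`, `a_bold`, `a_bold_defined`.
#' @export
#' @examples
#' crowding_indices(c(radial_present = 0.5, radial_absent = 0.8,
#'                    tangential_present = 0.9, tangential_absent = 0.7))
crowding_indices <- function(psc) {
  need <- c("radial_present", "radial_absent",
            "tangential_present", "tangential_absent")
  if (!all(need %in% names(psc)))
    stop("psc must contain all four conditions: ",
         paste(setdiff(need, names(psc)), collapse = ", "))
  psc <- psc[need]
  c_rad <- psc[["radial_present"]] - psc[["radial_absent"]]
  c_tan <- psc[["tangential_present"]] - psc[["tangential_absent"]]
  denom <- psc[["radial_absent"]] + psc[["tangential_absent"]]
  defined <- denom != 0
  structure(list(psc = psc, c_bold_rad = c_rad, c_bold_tan = c_tan,
                 a_bold = if (defined) (c_rad - c_tan) / denom else NA_real_,
                 a_bold_defined = defined),
            class = "crowding_indices_bold")
}

#' @export
print.crowding_indices_bold <- function(x, ...) {
  cat(sprintf("C_BOLD radial = %.4f, tangential = %.4f, A_BOLD = %s\n",
              x$c_bold_rad, x$c_bold_tan,
              if (x$a_bold_defined) sprintf("%.4f", x$a_bold) else "undefined"))
  invisible(x)
}

#' Session-level condition PSCs and indices from a set of runs
#'
#' Fits the GLM to each run separately and averages the betas across runs
#' per column (the default), or concatenates the runs with per-run intercept
#' and drift columns and fits once (`concatenate = TRUE`). PSCs are computed
#' from the (averaged) betas and summarised with [crowding_indices()].
#'
#' @param runs list of `bold_run` objects from one session.
#' @param hrf an [hrf_params()].
#' @param concatenate fit one GLM to the concatenated session instead of
#'   averaging run-level betas.
#' @return list with `psc`, `indices` (a `crowding_indices_bold`), and the
#'   per-run beta matrix (`beta_runs`, averaging mode only).
#' @export
analyze_bold_session <- function(runs, hrf = hrf_params(),
                                 concatenate = FALSE) {
  stopifnot(length(runs) >= 1)
  if (!concatenate) {
    betas <- lapply(runs, function(r) {
      X <- build_design(r$schedule, length(r$signal), r$tr, hrf)
      fit_glm(r, X)$beta
    })
    cols <- names(betas[[1]])
    B <- do.call(rbind, lapply(betas, function(b) b[cols]))
    beta_bar <- colMeans(B)
    psc <- percent_signal_change(list(beta = beta_bar))
    list(psc = psc, indices = crowding_indices(psc), beta_runs = B)
  } else {
    nruns <- length(runs)
    Xs <- lapply(runs, function(r)
      build_design(r$schedule, length(r$signal), r$tr, hrf))
    conds <- sort(unique(unlist(lapply(Xs, function(X)
      setdiff(colnames(X), c("intercept", "drift"))))))
    blocks <- lapply(seq_len(nruns), function(i) {
      X <- Xs[[i]]
      nv <- nrow(X)
      nuis <- matrix(0, nv, 2 * nruns)
      colnames(nuis) <- paste0(rep(c("intercept_run", "drift_run"), nruns),
                               rep(seq_len(nruns), each = 2))
      nuis[, 2 * i - 1] <- 1
      nuis[, 2 * i] <- X[, "drift"]
      cond_part <- matrix(0, nv, length(conds),
                          dimnames = list(NULL, conds))
      shared <- intersect(conds, colnames(X))
      cond_part[, shared] <- X[, shared]
      cbind(nuis, cond_part)
    })
    X <- do.call(rbind, blocks)
    y <- unlist(lapply(runs, `[[`, "signal"))
    fit <- fit_glm(y, X)
    b0 <- mean(fit$beta[grep("^intercept_run", names(fit$beta))])
    psc <- 100 * fit$beta[conds] / b0
    list(psc = psc, indices = crowding_indices(psc), fit = fit)
  }
}
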