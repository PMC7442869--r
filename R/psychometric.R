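#' Predicted 4AFC accuracy under the cumulative-normal psychometric model
#'
#' Probability of a correct response at target--flanker spacing `s`:
#' `P(correct | s) = guess + (1 - guess - lapse) * pnorm((s - mu) / sigma)`.
#' Identification improves as the flankers move away from the target, so the
#' curve rises from the 4AFC guess rate (0.25) towards `1 - lapse`.
#'
#' @param spacing numeric vector of target--flanker spacings (degrees).
#' @param mu location parameter (degrees).
#' @param sigma spread parameter (degrees), must be positive.
#' @param guess guess rate; 0.25 for a 4AFC task.
#' @param lapse lapse rate in `[0, 0.06]`.
#' @return numeric vector of predicted proportion correct.
#' @export
#' @examples
#' psy_prob(c(1, 2, 3), mu = 1.8, sigma = 0.4)
psy_prob <- function(spacing, mu, sigma, guess = 0.25, lapse = 0) {
  stopifnot(sigma > 0, guess >= 0, lapse >= 0, guess + lapse < 1)
  guess + (1 - guess - lapse) * stats::pnorm((spacing - mu) / sigma)
}

#' Fit the 4AFC cumulative-normal psychometric function by maximum likelihood
#'
#' Estimates `(mu, sigma, lapse)` with the guess rate fixed at 0.25, by
#' maximising the binomial log-likelihood of per-level correct counts.
#' Trials are aggregated per spacing level first (equivalent to the per-trial
#' Bernoulli likelihood). Optimisation is box-constrained (`lapse` in
#' `[0, 0.06]`, `sigma > 0`) and multi-started from a coarse grid of
#' `(mu, sigma)` values spanning the data; ties are broken by highest
#' log-likelihood, then smallest `sigma`.
#'
#' Degenerate data (all correct, all incorrect, or accuracy at chance at every
#' level) carry no threshold information: the fit is returned with
#' `converged = FALSE` and boundary estimates rather than failing silently.
#'
#' @param spacing numeric vector: per-trial spacings, or per-level spacings
#'   when `n_trials` is given.
#' @param correct logical/0-1 vector of trial outcomes, or per-level numbers
#'   of correct responses when `n_trials` is given. Non-integer counts are
#'   accepted (useful for fitting exact model proportions).
#' @param n_trials optional numeric vector of per-level trial counts; when
#'   supplied, `spacing`/`correct` are interpreted as aggregated data.
#' @param guess fixed guess rate (0.25, 4AFC).
#' @param lapse_max upper bound for the lapse estimate.
#' @return an object of class `psychometric_fit`: list with `mu`, `sigma`,
#'   `lapse`, `guess`, `loglik`, `converged`, `n_trials`.
#' @export
#' @examples
#' s <- c(0.75, 1.25, 1.75, 2.25, 2.75)
#' p <- psy_prob(s, mu = 1.8, sigma = 0.4)
#' fit <- fit_psychometric(s, p * 400, n_trials = rep(400, 5))
#' fit$mu
fit_psychometric <- function(spacing, correct, n_trials = NULL,
                             guess = 0.25, lapse_max = 0.06) {
  if (is.null(n_trials)) {
    stopifnot(length(spacing) == length(correct))
    agg <- tapply(as.numeric(correct), spacing, sum)
    lev <- as.numeric(names(agg))
    k <- as.numeric(agg)
    n <- as.numeric(tapply(rep(1, length(spacing)), spacing, sum))
  } else {
    stopifnot(length(spacing) == length(correct),
              length(spacing) == length(n_trials))
    lev <- as.numeric(spacing)
    k <- as.numeric(correct)
    n <- as.numeric(n_trials)
  }
  ord <- order(lev)
  lev <- lev[ord]; k <- k[ord]; n <- n[ord]
  keep <- n > 0
  lev <- lev[keep]; k <- k[keep]; n <- n[keep]
  if (length(lev) < 2)
    stop("need at least 2 distinct spacing levels with trials")
  if (any(k < 0) || any(k > n))
    stop("correct counts must lie in [0, n_trials]")
  ntot <- sum(n)

  boundary_fit <- function(mu, sigma, lapse, why) {
    structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = guess,
                   loglik = loglik(c(mu, log(sigma), lapse)),
                   converged = FALSE, reason = why, n_trials = ntot,
                   levels = data.frame(spacing = lev, n_correct = k,
                                       n_trials = n)),
              class = "psychometric_fit")
  }

  # work with log(sigma) so the optimiser cannot propose sigma <= 0
  loglik <- function(par) {
    p <- guess + (1 - guess - par[3]) * stats::pnorm((lev - par[1]) / exp(par[2]))
    q <- 1 - p                       # p >= guess > 0; only 1 - p can underflow
    q[q < 1e-12] <- 1e-12
    sum(k * log(p) + (n - k) * log(q))
  }

  rng <- range(lev)
  span <- diff(rng)
  pooled <- sum(k) / ntot
  if (pooled <= guess + 1e-8)
    return(boundary_fit(rng[2] + 2 * span, 4 * span, 0, "at or below chance"))
  if (pooled >= 1 - 1e-8)
    return(boundary_fit(rng[1] - 2 * span, span / 100, 0, "all trials correct"))

  # score a coarse grid first (cheap, vectorised in the data), then run the
  # optimiser only from the most promising grid points
  mu_grid <- seq(rng[1] - span / 2, rng[2] + span / 2, length.out = 13)
  sig_grid <- span * c(0.05, 0.1, 0.2, 0.35, 0.6, 1)
  grid <- expand.grid(mu = mu_grid, lsig = log(sig_grid))
  grid$ll <- vapply(seq_len(nrow(grid)), function(i)
    loglik(c(grid$mu[i], grid$lsig[i], 0.01)), numeric(1))
  starts <- grid[order(-grid$ll)[seq_len(3)], c("mu", "lsig")]
  best <- NULL
  lo <- c(rng[1] - 4 * span, log(span) - 7, 0)
  hi <- c(rng[2] + 4 * span, log(4 * span), lapse_max)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$value > b$value + 1e-9) return(TRUE)
    if (a$value < b$value - 1e-9) return(FALSE)
    if ((a$convergence == 0) != (b$convergence == 0))
      return(a$convergence == 0)
    a$par[2] < b$par[2]
  }
  run_start <- function(par) {
    o <- try(stats::nlminb(par, function(p) -loglik(p),
                           lower = lo, upper = hi,
                           control = list(iter.max = 500)), silent = TRUE)
    if (inherits(o, "try-error")) return(NULL)
    list(par = o$par, value = -o$objective, convergence = o$convergence)
  }
  for (i in seq_len(nrow(starts))) {
    o <- run_start(c(starts$mu[i], starts$lsig[i], 0.01))
    if (!is.null(o) && better(o, best)) best <- o
  }
  if (is.null(best))
    return(boundary_fit(mean(rng), span, 0, "optimisation failed"))
  if (best$convergence != 0) {
    o <- run_start(best$par)  # polish: restart once from the best point
    if (!is.null(o) && better(o, best)) best <- o
  }

  par <- best$par
  at_bound <- par[1] <= lo[1] + 1e-6 || par[1] >= hi[1] - 1e-6 ||
    par[2] >= hi[2] - 1e-6
  structure(list(mu = par[1], sigma = exp(par[2]), lapse = par[3],
                 guess = guess, loglik = best$value,
                 converged = best$convergence == 0 && !at_bound,
                 reason = if (at_bound) "estimate at parameter bound"
                          else if (best$convergence != 0) "optimiser did not converge"
                          else NA_character_,
                 n_trials = ntot,
                 levels = data.frame(spacing = lev, n_correct = k,
                                     n_trials = n)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "4AFC psychometric fit: mu = %.4f deg, sigma = %.4f deg, lapse = %.4f\n",
    x$mu, x$sigma, x$lapse))
  cat(sprintf("  guess = %.2f (fixed), logLik = %.2f, n = %d, converged: %s\n",
              x$guess, x$loglik, x$n_trials, x$converged))
  invisible(x)
}

#' Predicted accuracy of a fitted psychometric function
#'
#' @param object a `psychometric_fit`.
#' @param spacing numeric vector of spacings (degrees).
#' @param ... unused.
#' @return predicted proportion correct.
#' @export
predict.psychometric_fit <- function(object, spacing, ...) {
  psy_prob(spacing, object$mu, object$sigma, object$guess, object$lapse)
}

#' Critical spacing at a criterion accuracy
#'
#' Inverts the fitted psychometric function analytically:
#' `s* = mu + sigma * qnorm((criterion - guess) / (1 - guess - lapse))`.
#' The default criterion of 68% correct defines the critical spacing (the
#' extent of the crowding zone along the flanker axis).
#'
#' @param fit a `psychometric_fit` (or any list with `mu`, `sigma`, `guess`,
#'   `lapse`).
#' @param criterion target proportion correct, strictly between `guess` and
#'   `1 - lapse`.
#' @return spacing in degrees at which predicted accuracy equals `criterion`.
#' @export
#' @examples
#' fit <- list(mu = 2, sigma = 0.5, guess = 0.25, lapse = 0)
#' threshold_at(fit, 0.68)
threshold_at <- function(fit, criterion = 0.68) {
  if (criterion <= fit$guess || criterion >= 1 - fit$lapse)
    stop(sprintf(
      "criterion %.3f outside attainable range (%.3f, %.3f)",
      criterion, fit$guess, 1 - fit$lapse))
  fit$mu + fit$sigma *
    stats::qnorm((criterion - fit$guess) / (1 - fit$guess - fit$lapse))
}

#' Behavioural radial-tangential anisotropy index
#'
#' `A_psy = (C_r - C_t) / (C_r + C_t)` where `C_r`, `C_t` are the radial and
#' tangential critical spacings. Positive values indicate a radially
#' elongated crowding zone.
#'
#' @param c_r radial critical spacing (degrees), positive.
#' @param c_t tangential critical spacing (degrees), positive.
#' @return dimensionless index in `(-1, 1)`.
#' @export
#' @examples
#' anisotropy_psy(2.16, 1.61)
anisotropy_psy <- function(c_r, c_t) {
  if (any(c_r <= 0) || any(c_t <= 0))
    stop("critical spacings must be positive")
  (c_r - c_t) / (c_r + c_t)
}

#' Crowding-zone summary for one observer and session
#'
#' Packages the radial and tangential critical spacings with the derived
#' radial/tangential ratio and anisotropy index. The crowding zone is
#' summarised as an ellipse with semi-axes `(C_r, C_t)` for reporting.
#'
#' @inheritParams anisotropy_psy
#' @return object of class `crowding_zone`: list with `c_r`, `c_t`, `ratio`,
#'   `a_psy`.
#' @export
crowding_zone <- function(c_r, c_t) {
  structure(list(c_r = c_r, c_t = c_t, ratio = c_r / c_t,
                 a_psy = anisotropy_psy(c_r, c_t)),
            class = "crowding_zone")
}

#' @export
print.crowding_zone <- function(x, ...) {
  cat(sprintf(
    "crowding zone: C_r = %.3f deg, C_t = %.3f deg, ratio = %.3f, A_psy = %.4f\n",
    x$c_r, x$c_t, x$ratio, x$a_psy))
  invisible(x)
}

#' Weber contrast
#'
#' `|L_stim - L_background| / L_background`, the luminance contrast measure
#' used to specify the stimuli.
#'
#' @param stim_luminance stimulus luminance (cd/m^2).
#' @param background_luminance background luminance (cd/m^2), positive.
#' @return dimensionless contrast.
#' @export
#' @examples
#' weber_contrast(0.19, 171.5)
weber_contrast <- function(stim_luminance, background_luminance) {
  if (any(background_luminance <= 0))
    stop("background luminance must be positive")
  abs(stim_luminance - background_luminance) / background_luminance
}

#' Fit psychometric functions for every subject x axis x day cell
#'
#' Convenience wrapper over [fit_psychometric()] and [threshold_at()] for a
#' full trial table.
#'
#' @param trials data frame with columns `subject_id`, `day`, `axis`,
#'   `spacing_deg`, `correct` (the trial-table schema written by
#'   [simulate_study()]).
#' @param criterion accuracy criterion for the critical spacing.
#' @return data frame with one row per subject x axis x day: fitted
#'   parameters, convergence flag, and `critical_spacing` (degrees).
#' @export
fit_study <- function(trials, criterion = 0.68) {
  req <- c("subject_id", "day", "axis", "spacing_deg", "correct")
  if (!all(req %in% names(trials)))
    stop("trials must have columns: ", paste(req, collapse = ", "))
  cells <- unique(trials[, c("subject_id", "day", "axis")])
  cells <- cells[order(cells$subject_id, cells$axis, cells$day), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- trials$subject_id == cells$subject_id[i] &
      trials$day == cells$day[i] & trials$axis == cells$axis[i]
    fit <- fit_psychometric(trials$spacing_deg[sel], trials$correct[sel])
    thr <- if (fit$converged) threshold_at(fit, criterion) else NA_real_
    # a non-positive spacing is physically meaningless (the observer's true
    # threshold lies far below the tested range); flag as missing
    if (!is.na(thr) && thr <= 0) thr <- NA_real_
    out[[i]] <- data.frame(
      subject_id = cells$subject_id[i], day = cells$day[i],
      axis = cells$axis[i], mu = fit$mu, sigma = fit$sigma,
      lapse = fit$lapse, loglik = fit$loglik, converged = fit$converged,
      n_trials = fit$n_trials, critical_spacing = thr)
  }
  do.call(rbind, out)
}
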