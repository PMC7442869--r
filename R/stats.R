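#' Paired t-test
#'
#' Classical paired-sample t: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' differences `d = x - y`, `df = n - 1`, two-sided p from the t
#' distribution. When the differences have zero variance the statistic is
#' undefined and flagged rather than raised.
#'
#' @param x,y numeric vectors of equal length (>= 3), paired by subject.
#' @return list with `t`, `df`, `p`, `mean_diff`, `undefined`.
#' @export
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1))
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = 0, df = n - 1, p = NA_real_, mean_diff = mean(d),
                undefined = TRUE))
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1),
       mean_diff = mean(d), undefined = FALSE)
}

# uncorrected sum for a margin defined by a subset of grouping columns
.uterm <- function(y, data, cols) {
  if (length(cols) == 0) return(sum(y)^2 / length(y))
  g <- interaction(data[cols], drop = FALSE)
  tot <- tapply(y, g, sum)
  tot[is.na(tot)] <- 0
  per_cell <- length(y) / nlevels(g)
  sum(tot^2) / per_cell
}

# inclusion-exclusion sum of squares for the factorial term `cols`
.term_ss <- function(y, data, cols) {
  ss <- 0
  k <- length(cols)
  for (m in 0:k) {
    subs <- if (m == 0) list(character(0)) else
      utils::combn(cols, m, simplify = FALSE)
    for (T in subs) ss <- ss + (-1)^(k - m) * .uterm(y, data, T)
  }
  ss
}

#' Repeated-measures ANOVA (within-subject factors, classical decomposition)
#'
#' Balanced fully within-subject designs with 1--3 factors and one
#' observation per subject x cell. Each effect (main effects and all
#' interactions among the treatment factors) is tested against its own
#' effect-by-subject interaction mean square, the classical univariate
#' repeated-measures decomposition. No sphericity correction is applied by
#' default (`gg_correction = TRUE` applies Greenhouse-Geisser to effects
#' with more than 1 numerator df).
#'
#' @param data data frame in long format.
#' @param value name of the numeric response column.
#' @param subject name of the subject identifier column.
#' @param factors character vector of 1--3 within-subject factor columns.
#' @param gg_correction apply the Greenhouse-Geisser epsilon correction.
#' @return object of class `rm_anova`: data frame with one row per effect:
#'   `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`, `p`, `undefined`.
#' @export
#' @examples
#' d <- expand.grid(subject_id = paste0("S", 1:6), cond = c("a", "b"))
#' d$value <- rnorm(nrow(d))
#' rm_anova(d, "value", "subject_id", "cond")
rm_anova <- function(data, value, subject, factors, gg_correction = FALSE) {
  stopifnot(length(factors) >= 1, length(factors) <= 3)
  cols <- c(subject, factors)
  if (!all(c(value, cols) %in% names(data)))
    stop("missing columns in data")
  for (cc in cols) data[[cc]] <- factor(data[[cc]])
  y <- data[[value]]
  if (anyNA(y)) stop("missing values in response")

  counts <- table(data[cols])
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    lab <- apply(bad, 1, function(ix)
      paste(mapply(function(d, i) dimnames(counts)[[d]][i],
                   seq_along(ix), ix), collapse = ":"))
    stop("incomplete within-subject crossing; cells without exactly one ",
         "observation: ", paste(utils::head(lab, 10), collapse = ", "))
  }
  n_subj <- nlevels(data[[subject]])
  if (n_subj < 2) stop("need at least 2 subjects")

  effects <- unlist(lapply(seq_along(factors), function(m)
    utils::combn(factors, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(E) {
    ss <- .term_ss(y, data, E)
    ss_err <- .term_ss(y, data, c(subject, E))
    df_num <- prod(vapply(E, function(f) nlevels(data[[f]]) - 1L, 1L))
    df_den <- df_num * (n_subj - 1L)
    undef <- ss_err <= .Machine$double.eps * sum(y^2) || df_den <= 0
    Fval <- if (undef) NA_real_ else (ss / df_num) / (ss_err / df_den)
    p <- if (undef) NA_real_ else stats::pf(Fval, df_num, df_den,
                                            lower.tail = FALSE)
    eps <- 1
    if (gg_correction && !undef && df_num > 1) {
      eps <- .gg_epsilon(data, y, subject, E)
      p <- stats::pf(Fval, eps * df_num, eps * df_den, lower.tail = FALSE)
    }
    data.frame(effect = paste(E, collapse = ":"), df_num = df_num,
               df_den = df_den, ss = ss, ss_error = ss_err, F = Fval,
               p = p, gg_epsilon = eps, undefined = undef,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the subject x cell covariance of the
# effect's cell means (collapsed over the other factors)
.gg_epsilon <- function(data, y, subject, E) {
  cell <- interaction(data[E], drop = FALSE)
  M <- tapply(y, list(data[[subject]], cell), mean)
  S <- stats::cov(M)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  sum(diag(SC))^2 / ((k - 1) * sum(SC^2))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subject)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  print(df[, c("effect", "df_num", "df_den", "F", "p")], row.names = FALSE)
  invisible(x)
}

# all permutations of 1..n as an n!-row matrix (exact Spearman p for small n)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(rep(i, nrow(q)), q)
  }))
}

#' Spearman rank correlation with an honest p-value
#'
#' `rs` is the Pearson correlation of midranks (average ranks for ties).
#' The two-sided p-value is computed exactly by enumerating all `n!`
#' permutations for `n < 8`, by Monte-Carlo permutation for `n` in 8--9
#' (`nperm` draws, uses the current RNG state), and by the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` for `n >= 10`.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param nperm Monte-Carlo permutations for the mid-size regime.
#' @return object of class `correlation_result`: list with `rs`, `n`, `p`,
#'   `method`, `undefined`.
#' @export
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_cor <- function(x, y, nperm = 20000) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(rs = NA_real_, n = n, p = NA_real_,
                          method = "undefined", undefined = TRUE),
                     class = "correlation_result"))
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n < 8) {
    perms <- .permutations(n)
    rs_null <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rs_null) >= abs(rs) - 1e-12)
    method <- "exact permutation"
  } else if (n < 10) {
    rs_null <- replicate(nperm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(rs_null) >= abs(rs) - 1e-12)) / (nperm + 1)
    method <- "Monte-Carlo permutation"
  } else {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), n - 2)
    }
    method <- "t approximation"
  }
  structure(list(rs = rs, n = n, p = p, method = method, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$undefined) cat("Spearman correlation undefined (constant input)\n")
  else cat(sprintf("Spearman rs = %.3f (n = %d), p = %.4g [%s]\n",
                   x$rs, x$n, x$p, x$method))
  invisible(x)
}

#' Correlation between behavioural and BOLD anisotropy-index changes
#'
#' Joins the per-subject post-minus-pre changes in the behavioural
#' anisotropy index (`A_psy`) and the BOLD anisotropy index (`A_BOLD`) and
#' computes their Spearman rank correlation. Changes are z-standardised for
#' the returned scatter table (rank correlation itself is invariant to
#' this).
#'
#' @param behavioral data frame with columns `subject_id`, `delta`
#'   (post - pre change in `A_psy`).
#' @param bold data frame with columns `subject_id`, `delta`
#'   (post - pre change in `A_BOLD`).
#' @return list with `cor` (a `correlation_result`) and `data` (joined,
#'   standardised per-subject changes).
#' @export
anisotropy_change_correlation <- function(behavioral, bold) {
  for (d in list(behavioral, bold))
    if (!all(c("subject_id", "delta") %in% names(d)))
      stop("inputs need columns subject_id, delta")
  if (!setequal(behavioral$subject_id, bold$subject_id) ||
      anyDuplicated(behavioral$subject_id) || anyDuplicated(bold$subject_id))
    stop("subject mismatch between behavioural and BOLD tables")
  m <- merge(behavioral, bold, by = "subject_id",
             suffixes = c("_psy", "_bold"))
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  m$z_psy <- zs(m$delta_psy)
  m$z_bold <- zs(m$delta_bold)
  list(cor = spearman_cor(m$delta_psy, m$delta_bold), data = m)
}
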