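# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# direct-summation convolution (vs the FFT-based build_design route)
oracle_convolve <- function(box, kern) {
  n <- length(box)
  out <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0
    for (m in seq_along(kern)) {
      i <- t - m + 1
      if (i >= 1 && i <= n) s <- s + box[i] * kern[m]
    }
    out[t] <- s
  }
  out
}

# within-subject ANOVA by explicit projection matrices (vs the margin-totals
# inclusion-exclusion route in rm_anova)
oracle_rm_anova <- function(data, value, subject, factors) {
  y <- data[[value]]
  cols_all <- c(subject, factors)
  for (cc in cols_all) data[[cc]] <- factor(data[[cc]])
  proj <- function(cols) {
    X <- if (length(cols) == 0) matrix(1, length(y), 1) else
      stats::model.matrix(~ 0 + g,
                          data.frame(g = interaction(data[cols], drop = FALSE)))
    X %*% solve(crossprod(X)) %*% t(X)
  }
  ss_term <- function(cols) {
    k <- length(cols)
    ss <- 0
    for (m in 0:k) {
      subs <- if (m == 0) list(character(0)) else
        utils::combn(cols, m, simplify = FALSE)
      for (T in subs)
        ss <- ss + (-1)^(k - m) * drop(t(y) %*% proj(T) %*% y)
    }
    ss
  }
  n_subj <- nlevels(data[[subject]])
  effects <- unlist(lapply(seq_along(factors), function(m)
    utils::combn(factors, m, simplify = FALSE)), recursive = FALSE)
  do.call(rbind, lapply(effects, function(E) {
    ss <- ss_term(E)
    ss_err <- ss_term(c(subject, E))
    df_num <- prod(vapply(E, function(f) nlevels(data[[f]]) - 1L, 1L))
    df_den <- df_num * (n_subj - 1L)
    data.frame(effect = paste(E, collapse = ":"),
               F = (ss / df_num) / (ss_err / df_den),
               df_num = df_num, df_den = df_den)
  }))
}

# brute-force permutation enumeration by grid filtering (vs the package's
# recursive-insertion enumerator)
oracle_all_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# exact two-sided permutation p for Spearman on midranks
oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  perms <- oracle_all_perms(length(x))
  rs_null <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
  mean(abs(rs_null) >= abs(rs) - 1e-12)
}

# small study worlds used by several files
tiny_study <- function(seed = 1, n_subjects = 2, trials = 25)
  study_config(n_subjects = n_subjects,
               trials_per_condition_per_day = trials, seed = seed)

frozen_group <- function(...) observer_group(...)

# degenerate group: zero between-subject variance everywhere
degenerate_group <- function()
  observer_group(c_rad_pre = list(mean = 2.16, sd = 0),
                 c_tan_pre = list(mean = 1.61, sd = 0),
                 c_rad_post = list(mean = 1.46, sd = 0),
                 c_tan_post = list(mean = 1.05, sd = 0),
                 learn_tau = list(mean = 1, sd = 0),
                 sigma_psy = list(mean = 0.4, sd = 0),
                 lapse = list(mean = 0.02, sd = 0),
                 gain_sd = 0, coupling_kappa = 1, tan_gain_noise = 0)
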