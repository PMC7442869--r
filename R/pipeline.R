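#' @keywords internal
.log_line <- function(level, stage, msg, threshold = "info") {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[level]] <= ranks[[threshold]])
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  invisible(NULL)
}

.file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

.write_manifest <- function(outdir, config, seed, outputs) {
  manifest <- list(
    package = "crowdaniso",
    version = as.character(utils::packageVersion("crowdaniso")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(study = unclass(config$study),
                  group = unclass(config$group),
                  bold = local({
                    b <- unclass(config$bold); b$hrf <- unclass(b$hrf); b
                  })),
    outputs = as.list(.file_hashes(outputs)))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

# derive stage seeds from the master seed so each stage is independently
# reproducible
.stage_seeds <- function(seed) {
  list(observers = child_seed(seed, 11L),
       trials = child_seed(seed, 12L),
       bold = child_seed(seed, 13L))
}

#' Simulate the study and write all raw data files
#'
#' Writes `observers.csv`, `trials.csv`, one CSV + JSON sidecar per BOLD run
#' under `bold/`, and a `manifest.json` recording the configuration, seed,
#' and an MD5 hash of every output. Re-running with the same configuration
#' and seed reproduces byte-identical data files.
#'
#' @param config configuration list from [default_config()],
#'   [read_config()], or `NULL` for defaults.
#' @param seed master integer seed (overrides the seeds inside `config`).
#' @param outdir output directory (created if needed).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return path of the manifest file, invisibly.
#' @export
run_simulate <- function(config = NULL, seed = 1L, outdir = "crowdaniso-out",
                         log_level = "info") {
  config <- if (is.null(config)) validate_config(list()) else
    validate_config(lapply(config, unclass))
  seeds <- .stage_seeds(seed)
  config$study$seed <- seeds$observers
  config$bold$seed <- seeds$bold
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "bold"), showWarnings = FALSE)
  outputs <- character(0)

  .log_line("info", "simulate", sprintf("seed = %d", seed), log_level)
  observers <- sample_observers(config$study, config$group)
  p <- file.path(outdir, "observers.csv")
  utils::write.csv(as.data.frame(observers), p, row.names = FALSE,
                   quote = FALSE)
  outputs <- c(outputs, p)

  set.seed(seeds$trials)
  trials <- do.call(rbind, lapply(seq_len(nrow(observers)), function(i)
    simulate_training(observers[i, ], config$study)))
  p <- file.path(outdir, "trials.csv")
  write_trials(trials, p)
  outputs <- c(outputs, p)
  .log_line("info", "simulate",
            sprintf("%d trials for %d observers", nrow(trials),
                    nrow(observers)), log_level)

  for (i in seq_len(nrow(observers))) {
    for (session in c("pre", "post")) {
      sess_seed <- child_seed(seeds$bold, 1000L * i +
                                ifelse(session == "pre", 0L, 500L))
      runs <- simulate_bold_session(observers[i, ], config$bold, session,
                                    seed = sess_seed)
      for (r in seq_along(runs)) {
        stem <- file.path(outdir, "bold",
                          sprintf("%s_%s_run%02d",
                                  observers$subject_id[i], session, r))
        write_bold_run(runs[[r]], stem,
                       meta = list(subject_id = observers$subject_id[i],
                                   session = session, run = r))
        outputs <- c(outputs, paste0(stem, c(".csv", ".json")))
      }
    }
  }
  .log_line("info", "simulate",
            sprintf("%d BOLD runs written", 2L * nrow(observers) *
                      config$bold$runs_per_session), log_level)
  mp <- .write_manifest(outdir, config, seed, outputs)
  .log_line("info", "simulate", paste("manifest:", mp), log_level)
  invisible(mp)
}

#' Run the full replication pipeline and write the report
#'
#' Simulates the behavioural and fMRI arms, fits the psychometric functions,
#' extracts critical spacings and crowding zones, runs the BOLD GLM and
#' index extraction, and computes the group-level statistics: the 2 (axis) x
#' 4 (day) repeated-measures ANOVA on critical spacing with pre/post paired
#' t-tests; the 2 (axis) x 2 (target) x 2 (session) ANOVA on condition
#' PSCs; paired t-tests and a 2 x 2 ANOVA on the BOLD crowding index;
#' paired t-tests on both anisotropy indices; and the Spearman correlation
#' between per-subject changes in `A_psy` and `A_BOLD`.
#'
#' Any stage failure aborts with the stage named; outputs written by earlier
#' stages are preserved.
#'
#' @inheritParams run_simulate
#' @return the report, an object of class `replication_report` (also written
#'   to `report.json` and `report.md` in `outdir`).
#' @export
run_replicate <- function(config = NULL, seed = 1L,
                          outdir = "crowdaniso-out", log_level = "info") {
  config <- if (is.null(config)) validate_config(list()) else
    validate_config(lapply(config, unclass))
  seeds <- .stage_seeds(seed)
  config$study$seed <- seeds$observers
  config$bold$seed <- seeds$bold
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, expr) {
    .log_line("info", name, "start", log_level)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate-behaviour", {
    observers <- sample_observers(config$study, config$group)
    set.seed(seeds$trials)
    trials <- do.call(rbind, lapply(seq_len(nrow(observers)), function(i)
      simulate_training(observers[i, ], config$study)))
    list(observers = observers, trials = trials)
  })
  p <- file.path(outdir, "trials.csv"); write_trials(sim$trials, p)
  outputs <- c(outputs, p)

  fits <- stage("fit-psychometric", fit_study(sim$trials))
  p <- file.path(outdir, "psychometric_fits.csv")
  utils::write.csv(fits, p, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, p)
  ok_subj <- stage("screen-fits", {
    bad <- unique(fits$subject_id[!fits$converged |
                                    !is.finite(fits$critical_spacing)])
    if (length(bad))
      warning("dropping subjects with non-converged fits: ",
              paste(bad, collapse = ", "))
    setdiff(unique(fits$subject_id), bad)
  })
  fits_ok <- fits[fits$subject_id %in% ok_subj, ]

  behav <- stage("behavioural-summary", {
    day_means <- stats::aggregate(critical_spacing ~ axis + day, fits_ok,
                                  mean)
    wide <- stats::reshape(
      fits_ok[, c("subject_id", "day", "axis", "critical_spacing")],
      direction = "wide", idvar = c("subject_id", "day"),
      timevar = "axis")
    names(wide) <- sub("critical_spacing.", "", names(wide))
    zones <- do.call(rbind, lapply(split(wide, wide$subject_id), function(w) {
      pre <- w[w$day == 1, ]; post <- w[w$day == max(w$day), ]
      data.frame(subject_id = pre$subject_id,
                 c_r_pre = pre$radial, c_t_pre = pre$tangential,
                 c_r_post = post$radial, c_t_post = post$tangential,
                 ratio_pre = pre$radial / pre$tangential,
                 ratio_post = post$radial / post$tangential,
                 a_psy_pre = anisotropy_psy(pre$radial, pre$tangential),
                 a_psy_post = anisotropy_psy(post$radial, post$tangential))
    }))
    rownames(zones) <- NULL
    anova_psy <- rm_anova(fits_ok, "critical_spacing", "subject_id",
                          c("axis", "day"))
    t_rad <- paired_t(wide$radial[wide$day == 1],
                      wide$radial[wide$day == max(wide$day)])
    t_tan <- paired_t(wide$tangential[wide$day == 1],
                      wide$tangential[wide$day == max(wide$day)])
    t_ratio <- paired_t(zones$ratio_pre, zones$ratio_post)
    t_apsy <- paired_t(zones$a_psy_pre, zones$a_psy_post)
    list(day_means = day_means, zones = zones, anova = anova_psy,
         t_radial = t_rad, t_tangential = t_tan, t_ratio = t_ratio,
         t_a_psy = t_apsy)
  })

  bold <- stage("bold-pipeline", {
    idx <- bold_study_indices(sim$observers, config$bold, seed = seeds$bold)
    idx[idx$subject_id %in% ok_subj, ]
  })
  p <- file.path(outdir, "bold_indices.csv")
  utils::write.csv(bold, p, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, p)

  bold_stats <- stage("bold-stats", {
    long <- do.call(rbind, lapply(
      c("radial_present", "radial_absent", "tangential_present",
        "tangential_absent"),
      function(cond) data.frame(
        subject_id = bold$subject_id, session = bold$session,
        axis = sub("_.*", "", cond), target = sub(".*_", "", cond),
        psc = bold[[cond]], stringsAsFactors = FALSE)))
    anova_psc <- rm_anova(long, "psc", "subject_id",
                          c("axis", "target", "session"))
    cb <- rbind(
      data.frame(subject_id = bold$subject_id, session = bold$session,
                 axis = "radial", c_bold = bold$c_bold_rad),
      data.frame(subject_id = bold$subject_id, session = bold$session,
                 axis = "tangential", c_bold = bold$c_bold_tan))
    anova_cbold <- rm_anova(cb, "c_bold", "subject_id",
                            c("axis", "session"))
    pre <- bold[bold$session == "pre", ]
    post <- bold[bold$session == "post", ]
    post <- post[match(pre$subject_id, post$subject_id), ]
    list(anova_psc = anova_psc, anova_cbold = anova_cbold,
         t_cbold_rad = paired_t(post$c_bold_rad, pre$c_bold_rad),
         t_cbold_tan = paired_t(post$c_bold_tan, pre$c_bold_tan),
         t_a_bold = paired_t(post$a_bold, pre$a_bold),
         mean_psc = stats::aggregate(
           psc ~ session + axis + target, long, mean))
  })

  corr <- stage("anisotropy-correlation", {
    zones <- behav$zones
    pre <- bold[bold$session == "pre", ]
    post <- bold[bold$session == "post", ]
    post <- post[match(pre$subject_id, post$subject_id), ]
    anisotropy_change_correlation(
      data.frame(subject_id = zones$subject_id,
                 delta = zones$a_psy_post - zones$a_psy_pre),
      data.frame(subject_id = pre$subject_id,
                 delta = post$a_bold - pre$a_bold))
  })

  report <- structure(list(
    seed = seed, n_subjects = length(ok_subj),
    behavioural = behav, bold = bold_stats, correlation = corr),
    class = "replication_report")
  p <- file.path(outdir, "report.json")
  jsonlite::write_json(.report_to_list(report), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "report.md")
  writeLines(format_report(report), p)
  outputs <- c(outputs, p)
  .write_manifest(outdir, config, seed, outputs)
  .log_line("info", "replicate", "done", log_level)
  report
}

.report_to_list <- function(report) {
  b <- report$behavioural; f <- report$bold; corr <- report$correlation
  list(seed = report$seed, n_subjects = report$n_subjects,
       day_means = b$day_means, crowding_zones = b$zones,
       anova_critical_spacing = as.data.frame(b$anova),
       t_pre_post = list(radial = b$t_radial, tangential = b$t_tangential,
                         ratio = b$t_ratio, a_psy = b$t_a_psy),
       mean_psc = f$mean_psc,
       anova_psc = as.data.frame(f$anova_psc),
       anova_c_bold = as.data.frame(f$anova_cbold),
       t_c_bold = list(radial = f$t_cbold_rad, tangential = f$t_cbold_tan,
                       a_bold = f$t_a_bold),
       spearman = list(rs = corr$cor$rs, n = corr$cor$n, p = corr$cor$p),
       anisotropy_changes = corr$data)
}

#' Render a replication report as Markdown lines
#' @param report a `replication_report` from [run_replicate()].
#' @return character vector of Markdown lines.
#' @export
format_report <- function(report) {
  b <- report$behavioural; f <- report$bold; corr <- report$correlation
  fm <- function(x, d = 3) formatC(x, digits = d, format = "f")
  tline <- function(lbl, t)
    sprintf("- %s: t(%d) = %s, p = %s, mean diff = %s", lbl, t$df,
            fm(t$t, 2), format.pval(t$p, digits = 3), fm(t$mean_diff))
  anova_md <- function(a) c(
    "| effect | df | F | p |", "|---|---|---|---|",
    sprintf("| %s | (%d, %d) | %s | %s |", a$effect, a$df_num, a$df_den,
            fm(a$F, 2), format.pval(a$p, digits = 3)))
  dm <- stats::reshape(b$day_means, direction = "wide", idvar = "axis",
                       timevar = "day")
  c(sprintf("# Crowding anisotropy replication report (seed %d)",
            report$seed),
    sprintf("Subjects analysed: %d", report$n_subjects),
    "", "## Behaviour: day-by-day mean critical spacing (deg)",
    "| axis | day 1 | day 2 | day 3 | day 4 |", "|---|---|---|---|---|",
    sprintf("| %s | %s |", dm$axis,
            apply(dm[, -1, drop = FALSE], 1, function(r)
              paste(fm(as.numeric(r)), collapse = " | "))),
    "",
    sprintf("Mean radial/tangential ratio: pre %s, post %s",
            fm(mean(b$zones$ratio_pre)), fm(mean(b$zones$ratio_post))),
    sprintf("Mean A_psy: pre %s, post %s",
            fm(mean(b$zones$a_psy_pre)), fm(mean(b$zones$a_psy_post))),
    "", "### 2 (axis) x 4 (day) repeated-measures ANOVA on critical spacing",
    anova_md(b$anova),
    "", "### Pre vs post paired t-tests",
    tline("radial day1 - day4", b$t_radial),
    tline("tangential day1 - day4", b$t_tangential),
    tline("ratio pre - post", b$t_ratio),
    tline("A_psy pre - post", b$t_a_psy),
    "", "## BOLD: mean percent signal change",
    "| session | axis | target | PSC |", "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", f$mean_psc$session, f$mean_psc$axis,
            f$mean_psc$target, fm(f$mean_psc$psc)),
    "", "### 2 x 2 x 2 repeated-measures ANOVA on PSC",
    anova_md(f$anova_psc),
    "", "### 2 (axis) x 2 (session) ANOVA on C_BOLD",
    anova_md(f$anova_cbold),
    "", "### C_BOLD and A_BOLD paired t-tests (post - pre)",
    tline("C_BOLD radial", f$t_cbold_rad),
    tline("C_BOLD tangential", f$t_cbold_tan),
    tline("A_BOLD", f$t_a_bold),
    "", "## Behaviour-BOLD coupling",
    sprintf(
      "Spearman correlation of anisotropy-index changes: rs = %s, n = %d, p = %s",
      fm(corr$cor$rs), corr$cor$n, format.pval(corr$cor$p, digits = 3)))
}

#' @export
print.replication_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
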