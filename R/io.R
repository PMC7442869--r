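#' Write / read a trial table as CSV
#'
#' Schema: `subject_id, day, axis, spacing_deg, gap_direction, response,
#' correct` -- the 4AFC trial record written one row per trial.
#'
#' @param trials trial data frame (see [simulate_training()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  req <- c("subject_id", "day", "axis", "spacing_deg", "gap_direction",
           "response", "correct")
  if (!all(req %in% names(trials)))
    stop("trial table must have columns: ", paste(req, collapse = ", "))
  utils::write.csv(trials[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "day", "axis", "spacing_deg", "gap_direction",
           "response", "correct")
  if (!all(req %in% names(tr)))
    stop("file is not a trial table (missing columns: ",
         paste(setdiff(req, names(tr)), collapse = ", "), ")")
  tr$correct <- as.logical(tr$correct)
  tr
}

#' Write / read a BOLD run (CSV signal + JSON schedule sidecar)
#'
#' The time series goes to `<path>.csv` (`volume`, `signal`); the block
#' schedule, TR and any extra metadata go to `<path>.json`.
#'
#' @param run a `bold_run`.
#' @param path stem path (no extension).
#' @param meta optional named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path, meta = list()) {
  utils::write.csv(
    data.frame(volume = seq_along(run$signal), signal = run$signal),
    paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  side <- c(list(tr = run$tr,
                 schedule = run$schedule,
                 n_volumes = length(run$signal)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(path) {
  sig <- utils::read.csv(paste0(path, ".csv"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- as.data.frame(side$schedule, stringsAsFactors = FALSE)
  structure(list(signal = sig$signal, schedule = sched, tr = side$tr),
            class = "bold_run")
}

#' Default pipeline configuration
#'
#' Nested list with the three configuration blocks (`study`, `group`,
#' `bold`) at their default values; serialisable to/from YAML with
#' [write_config()] / [read_config()].
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(study = unclass(study_config()),
       group = unclass(observer_group()),
       bold = local({
         b <- unclass(bold_config())
         b$hrf <- unclass(b$hrf)
         b
       }))
}

#' Write / read the pipeline configuration as YAML
#'
#' @param config nested configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a validated
#'   configuration list whose blocks have been rebuilt through
#'   [study_config()], [observer_group()] and [bold_config()] (so schema
#'   violations surface as errors naming the offending block).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Validate and normalise a raw configuration list
#'
#' Unknown fields are rejected; each block is rebuilt through its
#' constructor so invariants are enforced.
#'
#' @param raw nested list (e.g. parsed YAML).
#' @return list with classed `study`, `group`, `bold` components.
#' @export
validate_config <- function(raw) {
  defaults <- default_config()
  for (block in names(raw)) {
    if (!block %in% names(defaults))
      stop("unknown configuration block: ", block)
    extra <- setdiff(names(raw[[block]]), names(defaults[[block]]))
    if (length(extra))
      stop("unknown field(s) in '", block, "': ",
           paste(paste0(block, ".", extra), collapse = ", "))
  }
  merged <- utils::modifyList(defaults, raw)
  study <- tryCatch(do.call(study_config, merged$study),
                    error = function(e) stop("study: ", conditionMessage(e),
                                             call. = FALSE))
  group <- tryCatch(do.call(observer_group, merged$group),
                    error = function(e) stop("group: ", conditionMessage(e),
                                             call. = FALSE))
  bold_args <- merged$bold
  bold_args$amplitudes <- as.data.frame(bold_args$amplitudes,
                                        stringsAsFactors = FALSE)
  bold_args$hrf <- do.call(hrf_params, as.list(bold_args$hrf))
  bold <- tryCatch(do.call(bold_config, bold_args),
                   error = function(e) stop("bold: ", conditionMessage(e),
                                            call. = FALSE))
  list(study = study, group = group, bold = bold)
}
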