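#' Read a trial table from CSV
#'
#' The expected schema is
#' `participant,session,trial,isi_s,delay_s,face1,face2,postcue,response,rt_s`
#' with `postcue` empty for Experiment 1. Stimulus and response columns hold
#' wheel indices; by default these are 0-based (matching the package's
#' internal indexing), set `index_base = 1` for tables that use 1-based
#' image IDs. Unknown extra columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @param index_base 0 or 1; base of the `face1`, `face2`, `response`
#'   columns in the file.
#' @return a data.frame of trial records.
#' @export
read_trials <- function(path, index_base = 0L) {
  stopifnot(index_base %in% c(0L, 1L))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "session", "trial", "isi_s", "delay_s",
            "face1", "face2", "postcue", "response", "rt_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trial CSV is missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    df <- df[need]
  }
  if (index_base == 1L) {
    for (col in c("face1", "face2", "response")) df[[col]] <- df[[col]] - 1L
  }
  df
}

#' Write a trial table (raw or derived) to CSV
#'
#' @param trials data.frame of trial records or derived trials.
#' @param path output path.
#' @param index_base 0 or 1; base for position columns in the file.
#' @export
write_trials <- function(trials, path, index_base = 0L) {
  stopifnot(index_base %in% c(0L, 1L))
  out <- trials
  if (index_base == 1L) {
    for (col in intersect(c("face1", "face2", "response", "target", "inducer"),
                          names(out)))
      out[[col]] <- out[[col]] + 1L
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

exp1_isi_levels   <- c(1, 3, 6, 10)
exp1_delay_levels <- c(0, 1, 3, 6, 10)
exp2_delay_levels <- c(1, 3, 6)

#' Canonical condition keys for an experiment
#'
#' Experiment 1 crosses ISI (1, 3, 6, 10 s) with response delay
#' (0, 1, 3, 6, 10 s) for 20 conditions; Experiment 2 crosses the postcued
#' target (Face 1 vs Face 2) with response delay (1, 3, 6 s) for 6.
#'
#' @param experiment 1 or 2.
#' @return character vector of condition keys in canonical order.
#' @export
condition_keys <- function(experiment) {
  experiment <- match_experiment(experiment)
  if (experiment == 1L) {
    as.vector(outer(exp1_isi_levels, exp1_delay_levels,
                    function(i, d) sprintf("isi%g_delay%g", i, d)))
  } else {
    as.vector(outer(1:2, exp2_delay_levels,
                    function(p, d) sprintf("postcue%d_delay%g", p, d)))
  }
}

match_experiment <- function(experiment) {
  if (!length(experiment) == 1L || !experiment %in% c(1, 2))
    stop("`experiment` must be 1 or 2")
  as.integer(experiment)
}

#' Derive per-trial analysis quantities
#'
#' Resolves the target and inducer faces, computes the signed adjustment
#' error (target to response), the signed inducer-target difference
#' (target to inducer), the condition key, and the exclusion flag.
#'
#' Target resolution: in Experiment 1 the reported face is always Face 2
#' (Face 1 is the inducer). In Experiment 2 the postcue decides: postcue 2
#' means target = Face 2, inducer = Face 1; postcue 1 swaps the roles.
#'
#' A trial is flagged excluded when its response time exceeds 15 s or the
#' absolute adjustment error exceeds 60 morph steps; both thresholds are
#' strict, so a trial at exactly 15.0 s or exactly 60 steps is kept.
#'
#' @param records data.frame of trial records (see [read_trials()]).
#' @param wheel a [morph_wheel()].
#' @param experiment 1 or 2.
#' @return the input with added columns `target`, `inducer`, `error`,
#'   `delta`, `condition`, `excluded`, `exclude_reason`.
#' @export
derive_trials <- function(records, wheel, experiment) {
  experiment <- match_experiment(experiment)
  df <- as.data.frame(records)
  if (nrow(df) == 0L) stop("no trial records supplied")
  if (!"postcue" %in% names(df)) df$postcue <- NA_integer_
  has_cue <- !is.na(df$postcue)
  if (experiment == 1L && any(has_cue))
    stop("Experiment 1 records must not carry a postcue")
  if (experiment == 2L && !all(df$postcue %in% c(1L, 2L)))
    stop("Experiment 2 records need a postcue of 1 or 2 on every trial")
  lvl_ok <- if (experiment == 1L)
    df$isi_s %in% exp1_isi_levels & df$delay_s %in% exp1_delay_levels
  else
    df$isi_s == 1 & df$delay_s %in% exp2_delay_levels
  if (!all(lvl_ok))
    stop("ISI/delay values outside the experiment's level sets")
  check_positions(df$face1, wheel, "`face1`")
  check_positions(df$face2, wheel, "`face2`")
  check_positions(df$response, wheel, "`response`")
  if (any(!is.finite(df$rt_s)) || any(df$rt_s <= 0))
    stop("`rt_s` must be positive")

  swap <- experiment == 2L & df$postcue == 1L
  df$target  <- ifelse(swap, df$face1, df$face2)
  df$inducer <- ifelse(swap, df$face2, df$face1)
  df$error <- signed_distance(df$target, df$response, wheel)
  df$delta <- signed_distance(df$target, df$inducer, wheel)
  df$condition <- if (experiment == 1L)
    sprintf("isi%g_delay%g", df$isi_s, df$delay_s)
  else
    sprintf("postcue%d_delay%g", df$postcue, df$delay_s)

  rt_bad  <- df$rt_s > 15
  err_bad <- abs(df$error) > 60
  df$excluded <- rt_bad | err_bad
  df$exclude_reason <- ""
  df$exclude_reason[rt_bad]  <- "rt>15s"
  df$exclude_reason[err_bad] <- "error>60"
  df$exclude_reason[rt_bad & err_bad] <- "rt>15s;error>60"
  df
}

#' Apply the lapse filter
#'
#' Removes trials flagged by [derive_trials()] (response time > 15 s or
#' absolute adjustment error > 60 morph steps) and reports the fraction
#' removed. Each trial is counted once even if it fails both criteria.
#'
#' @param trials derived trials.
#' @return list with `kept` (data.frame) and `removal_fraction`.
#' @export
filter_trials <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials to filter")
  if (!"excluded" %in% names(trials))
    stop("trials must come from derive_trials()")
  keep <- !trials$excluded
  list(kept = trials[keep, , drop = FALSE],
       removal_fraction = mean(!keep))
}

#' Group trials by analysis condition
#'
#' Splits trials into the experiment's condition cells (20 for
#' Experiment 1, 6 for Experiment 2). Conditions with no trials are
#' retained as empty data.frames so downstream reporting stays complete.
#'
#' @param trials derived (usually filtered) trials.
#' @param experiment 1 or 2.
#' @return named list of data.frames, one per condition key, in canonical
#'   order.
#' @export
group_by_condition <- function(trials, experiment) {
  keys <- condition_keys(experiment)
  out <- lapply(keys, function(k)
    trials[trials$condition == k, , drop = FALSE])
  names(out) <- keys
  out
}
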