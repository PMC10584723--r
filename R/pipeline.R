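#' Moving average of adjustment error over stimulus difference
#'
#' Diagnostic smoother plotted alongside the DoG fit: the mean of `y`
#' within a centred window of `window` morph steps at each distinct `x`.
#' Windows are truncated at the ends of the range.
#'
#' @param x stimulus differences (morph steps).
#' @param y adjustment errors.
#' @param window window width in morph steps; odd, at least 3.
#' @return data.frame with columns `x` (sorted distinct values) and `y`
#'   (window means).
#' @export
moving_average <- function(x, y, window = 15) {
  if (length(x) == 0L) stop("empty input")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  half <- (window - 1) / 2
  xs <- sort(unique(x))
  ys <- vapply(xs, function(x0) mean(y[abs(x - x0) <= half]), numeric(1))
  data.frame(x = xs, y = ys)
}

non_estimable_fit_row <- function(condition, variant, n) {
  data.frame(condition = condition, variant = variant, n = n,
             mu = NA_real_, sigma = NA_real_, alpha = NA_real_,
             half_amplitude = NA_real_, rss = NA_real_, converged = FALSE,
             ci_low = NA_real_, ci_high = NA_real_, significant = NA,
             estimable = FALSE, stringsAsFactors = FALSE)
}

#' Run the full serial-dependence analysis
#'
#' Composes the whole pipeline on a trial table: derive per-trial
#' quantities, apply the lapse filter (response time > 15 s or absolute
#' error > 60 steps), group into the experiment's conditions, fit the DoG
#' bias curve with a trial-level bootstrap CI for the half-amplitude in
#' every condition — for the within-trial predictor and, optionally, the
#' three across-trial predictors (previous Face 2 / Face 1 / response) —
#' and compute the categorical classification-error index and accuracy
#' per condition. Conditions with fewer than `min_n` usable pairs are
#' reported as non-estimable rather than failing the run.
#'
#' @param trials raw trial records (see [read_trials()]) or a path to a
#'   trial CSV.
#' @param experiment 1 or 2.
#' @param wheel a [morph_wheel()].
#' @param n_boot bootstrap iterations per condition (default 10000).
#' @param seed integer master seed; per-condition bootstrap seeds are
#'   derived deterministically from it.
#' @param variants predictor variants to fit (default all four).
#' @param ci_method_dog CI type for half-amplitudes (default percentile).
#' @param ci_method_index CI type for the categorical index (default BCa).
#' @param min_n minimum pairs per fit (default 10).
#' @param include_categorical compute the categorical index and accuracy
#'   per condition (default `TRUE`).
#' @param out_dir optional directory; when given, writes `dog_fits.csv`,
#'   `across_trial.csv`, `categorical.csv`, and `run.log` there.
#' @return an object of class `"sd_analysis"`: `dog_fits` (data.frame over
#'   conditions x variants), `categorical` (data.frame over conditions),
#'   `removal_fraction`, `experiment`, `n_trials`, `seed`, `n_boot`,
#'   `fits` (the within-trial `"dog_fit"` objects), `timestamp`.
#' @export
run_analysis <- function(trials, experiment, wheel = morph_wheel(),
                         n_boot = 10000L, seed = 1L,
                         variants = predictor_variants,
                         ci_method_dog = "percentile",
                         ci_method_index = "bca",
                         min_n = 10L, include_categorical = TRUE,
                         out_dir = NULL) {
  if (is.character(trials) && length(trials) == 1L)
    trials <- read_trials(trials)
  variants <- match.arg(variants, predictor_variants, several.ok = TRUE)
  derived <- derive_trials(trials, wheel, experiment)
  filt <- filter_trials(derived)
  keys <- condition_keys(experiment)
  log_lines <- sprintf(
    "filtered %d of %d trials (%.2f%%): %s",
    nrow(derived) - nrow(filt$kept), nrow(derived),
    100 * filt$removal_fraction,
    paste(utils::head(which(derived$excluded), 20), collapse = ","))

  fit_rows <- list()
  fits <- list()
  i_seed <- 0L
  for (v in variants) {
    pairs <- build_predictor(derived, v, wheel)
    by_cond <- split(pairs, factor(pairs$condition, levels = keys))
    for (key in keys) {
      i_seed <- i_seed + 1L
      d <- by_cond[[key]]
      if (is.null(d) || nrow(d) < min_n ||
          length(unique(d$x)) < 2L) {
        fit_rows[[length(fit_rows) + 1L]] <-
          non_estimable_fit_row(key, v, if (is.null(d)) 0L else nrow(d))
        log_lines <- c(log_lines,
                       sprintf("%s/%s: non-estimable (n=%d)", key, v,
                               if (is.null(d)) 0L else nrow(d)))
        next
      }
      res <- bootstrap_half_amplitude(
        d$x, d$y, n_boot = n_boot, seed = child_seed(seed, i_seed),
        method = ci_method_dog, min_n = min_n)
      cf <- coef(res$fit)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        condition = key, variant = v, n = res$fit$n,
        mu = unname(cf["mu"]), sigma = unname(cf["sigma"]),
        alpha = unname(cf["alpha"]),
        half_amplitude = res$fit$half_amplitude, rss = res$fit$rss,
        converged = res$fit$converged,
        ci_low = res$boot$ci_low, ci_high = res$boot$ci_high,
        significant = res$boot$significant, estimable = TRUE,
        stringsAsFactors = FALSE)
      if (v == "within_trial") fits[[key]] <- res$fit
    }
  }
  dog_fits <- do.call(rbind, fit_rows)

  cat_rows <- list()
  grouped <- group_by_condition(filt$kept, experiment)
  for (key in if (include_categorical) keys else character(0)) {
    i_seed <- i_seed + 1L
    d <- grouped[[key]]
    if (nrow(d) == 0L) {
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        condition = key, n = 0L, n_errors = 0L,
        ratio_cat1 = NA_real_, ratio_cat2 = NA_real_,
        ratio_cat3 = NA_real_, index_pct = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, significant = NA,
        accuracy_pct = NA_real_, accuracy_sd = NA_real_,
        estimable = FALSE, stringsAsFactors = FALSE)
      log_lines <- c(log_lines, sprintf("%s/categorical: empty", key))
      next
    }
    ci <- withCallingHandlers(
      categorical_index(d, wheel, n_boot = n_boot,
                        method = ci_method_index,
                        seed = child_seed(seed, i_seed)),
      warning = function(wrn) {
        log_lines <<- c(log_lines, sprintf("%s/categorical: %s", key,
                                           conditionMessage(wrn)))
        invokeRestart("muffleWarning")
      })
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      condition = key, n = ci$n, n_errors = ci$n_errors,
      ratio_cat1 = ci$per_category_ratio[1],
      ratio_cat2 = ci$per_category_ratio[2],
      ratio_cat3 = ci$per_category_ratio[3],
      index_pct = ci$index_pct, ci_low = ci$ci_low,
      ci_high = ci$ci_high, significant = ci$significant,
      accuracy_pct = ci$accuracy_pct, accuracy_sd = ci$accuracy_sd,
      estimable = ci$estimable, stringsAsFactors = FALSE)
  }
  categorical <- if (length(cat_rows)) do.call(rbind, cat_rows) else NULL

  report <- structure(
    list(dog_fits = dog_fits, categorical = categorical,
         removal_fraction = filt$removal_fraction,
         experiment = match_experiment(experiment),
         n_trials = nrow(derived), n_kept = nrow(filt$kept),
         seed = seed, n_boot = n_boot, variants = variants,
         fits = fits, log = log_lines,
         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    class = "sd_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    within <- dog_fits[dog_fits$variant == "within_trial", , drop = FALSE]
    across <- dog_fits[dog_fits$variant != "within_trial", , drop = FALSE]
    utils::write.csv(within, file.path(out_dir, "dog_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(across, file.path(out_dir, "across_trial.csv"),
                     row.names = FALSE)
    if (!is.null(categorical))
      utils::write.csv(categorical, file.path(out_dir, "categorical.csv"),
                       row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

#' @export
print.sd_analysis <- function(x, ...) {
  cat(sprintf(
    "Serial-dependence analysis, Experiment %d: %d trials (%d kept, %.1f%% removed), %d conditions\n",
    x$experiment, x$n_trials, x$n_kept, 100 * x$removal_fraction,
    length(condition_keys(x$experiment))))
  within <- x$dog_fits[x$dog_fits$variant == "within_trial", , drop = FALSE]
  sig <- within$condition[isTRUE_v(within$significant)]
  cat("Within-trial conditions with significant half-amplitude:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
summary.sd_analysis <- function(object, ...) {
  cat0 <- object$categorical
  within <- object$dog_fits[object$dog_fits$variant == "within_trial", ,
                            drop = FALSE]
  out <- within[c("condition", "n", "half_amplitude", "ci_low",
                  "ci_high", "significant")]
  if (!is.null(cat0))
    out <- merge(out, cat0[c("condition", "index_pct", "accuracy_pct")],
                 by = "condition", sort = FALSE)
  structure(list(table = out, report = object),
            class = "summary.sd_analysis")
}

#' @export
print.summary.sd_analysis <- function(x, digits = 3, ...) {
  print(x$report)
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) round(z, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
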