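cat_index_core <- function(cat_t, cat_i, cat_r, denominator = "partition") {
  err <- cat_r != cat_t
  ratios <- rep(NA_real_, 3)
  n_err_by_cat <- integer(3)
  for (k in 1:3) {
    in_part <- err & cat_i == k
    n_err_by_cat[k] <- sum(in_part)
    if (n_err_by_cat[k] > 0)
      ratios[k] <- if (denominator == "partition")
        sum(in_part & cat_r == k) / n_err_by_cat[k]
      else
        sum(in_part & cat_r == k) / sum(err)
  }
  list(ratios = ratios, n_errors = sum(err), n_err_by_cat = n_err_by_cat)
}

#' Categorical classification-error index of serial dependence
#'
#' A nonparametric complement to the DoG fit. Responses, targets, and
#' inducers are assigned to the three prototype categories of the wheel.
#' A trial counts as a classification error when the response category
#' differs from the target category. Errors are partitioned by the
#' inducer's category; within each partition the ratio of errors landing
#' in the inducer's own category is computed, the three ratios are
#' averaged, expressed in percent, and the 33.33% chance baseline is
#' subtracted. A positive index means error responses are drawn toward
#' the inducer's category (attraction); the index ranges from -33.33 to
#' +66.67.
#'
#' The per-partition denominator is used because it is the reading under
#' which independence of response and inducer yields exactly the 1/3
#' chance baseline; a grand-total denominator is available for
#' sensitivity analysis (its null value depends on the error mix).
#'
#' @param trials derived, filtered trials (need `target`, `inducer`,
#'   `response` columns).
#' @param wheel a [morph_wheel()].
#' @param denominator `"partition"` (default) or `"grand"`.
#' @param baseline chance level subtracted, in percent (default 100/3).
#' @param n_boot bootstrap iterations for the CI and the accuracy SD
#'   (default 10000); `0` skips the bootstrap.
#' @param method CI type, `"bca"` (default) or `"percentile"`.
#' @param seed integer seed for the bootstrap.
#' @return an object of class `"categorical_index"`: `per_category_ratio`
#'   (length-3, `NA` where a partition has no errors), `mean_ratio_pct`,
#'   `index_pct`, `ci_low`, `ci_high`, `significant`, `n`, `n_errors`,
#'   `accuracy_pct`, `accuracy_sd`, `estimable`.
#' @export
categorical_index <- function(trials, wheel,
                              denominator = c("partition", "grand"),
                              baseline = 100 / 3, n_boot = 10000L,
                              method = c("bca", "percentile"),
                              seed = 1L) {
  denominator <- match.arg(denominator)
  method <- match.arg(method)
  if (nrow(trials) == 0L) stop("no trials")
  cats <- data.frame(t = category_of(trials$target, wheel),
                     i = category_of(trials$inducer, wheel),
                     r = category_of(trials$response, wheel))
  core <- cat_index_core(cats$t, cats$i, cats$r, denominator)
  estimable <- core$n_errors > 0 && any(!is.na(core$ratios))
  if (any(is.na(core$ratios)) && estimable)
    warning("inducer-category partition(s) with zero errors; ",
            "index averages the remaining categories")
  mean_ratio_pct <- if (estimable) 100 * mean(core$ratios, na.rm = TRUE)
  else NA_real_
  index_pct <- mean_ratio_pct - baseline
  acc_pct <- 100 * mean(cats$r == cats$t)

  ci_low <- ci_high <- acc_sd <- NA_real_
  significant <- NA
  if (n_boot > 0 && estimable) {
    stat <- function(d)
      100 * mean(cat_index_core(d$t, d$i, d$r, denominator)$ratios,
                 na.rm = TRUE) - baseline
    b <- bootstrap_statistic(cats, stat, n_boot = n_boot,
                             method = method, seed = seed)
    ci_low <- b$ci_low; ci_high <- b$ci_high
    significant <- b$significant
    acc_sd <- with_seed(child_seed(seed, 1L), {
      accs <- vapply(seq_len(min(n_boot, 2000L)), function(i) {
        idx <- sample.int(nrow(cats), nrow(cats), replace = TRUE)
        100 * mean(cats$r[idx] == cats$t[idx])
      }, numeric(1))
      stats::sd(accs)
    })
  }
  structure(
    list(per_category_ratio = core$ratios,
         mean_ratio_pct = mean_ratio_pct,
         index_pct = index_pct,
         ci_low = ci_low, ci_high = ci_high,
         significant = significant,
         n = nrow(trials), n_errors = core$n_errors,
         accuracy_pct = acc_pct, accuracy_sd = acc_sd,
         estimable = estimable,
         denominator = denominator, baseline = baseline),
    class = "categorical_index")
}

#' @export
print.categorical_index <- function(x, digits = 3, ...) {
  if (!x$estimable) {
    cat(sprintf(
      "Categorical index: non-estimable (no classification errors); accuracy %.1f%% (n = %d)\n",
      x$accuracy_pct, x$n))
    return(invisible(x))
  }
  cat(sprintf("Categorical classification-error index: %s%%",
              format(x$index_pct, digits = digits)))
  if (!is.na(x$ci_low))
    cat(sprintf(" , 95%% CI [%s, %s]%s",
                format(x$ci_low, digits = digits),
                format(x$ci_high, digits = digits),
                if (isTRUE(x$significant)) " *" else ""))
  cat(sprintf("\n(%d errors in %d trials; accuracy %.1f%%%s)\n",
              x$n_errors, x$n, x$accuracy_pct,
              if (!is.na(x$accuracy_sd))
                sprintf(" +/- %.1f", x$accuracy_sd) else ""))
  invisible(x)
}

#' Categorical classification accuracy
#'
#' Percent of trials whose response falls in the target's prototype
#' category, with a dispersion estimated as the SD of the accuracy across
#' bootstrap resamples of trials.
#'
#' @param trials derived, filtered trials.
#' @param wheel a [morph_wheel()].
#' @param n_boot bootstrap resamples for the SD (default 1000; `0` skips).
#' @param seed integer seed.
#' @return list with `accuracy_pct` and `sd`.
#' @export
classification_accuracy <- function(trials, wheel, n_boot = 1000L,
                                    seed = 1L) {
  if (nrow(trials) == 0L) stop("no trials")
  correct <- category_of(trials$response, wheel) ==
    category_of(trials$target, wheel)
  sd_out <- NA_real_
  if (n_boot > 0) {
    sd_out <- with_seed(seed, {
      stats::sd(vapply(seq_len(n_boot), function(i)
        100 * mean(sample(correct, replace = TRUE)), numeric(1)))
    })
  }
  list(accuracy_pct = 100 * mean(correct), sd = sd_out)
}
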