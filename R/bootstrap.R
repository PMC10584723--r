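#' Trial-level bootstrap for an arbitrary statistic
#'
#' Resamples trials (rows of `data`) with replacement at the original
#' sample size, recomputes `statistic` on each resample, and forms a 95%
#' (by default) confidence interval from the empirical distribution —
#' percentile quantiles or bias-corrected-and-accelerated (BCa). A
#' statistic that errors or returns `NA` on a resample counts as a failed
#' fit and is excluded from the quantiles; more than 20% failures aborts
#' with a diagnostic. The estimate is flagged significant when the
#' interval excludes zero.
#'
#' @param data a data.frame (rows are resampled) or an atomic vector.
#' @param statistic function mapping a resampled `data` to one number.
#' @param n_boot number of bootstrap iterations (default 10000; >= 100).
#' @param method `"percentile"` or `"bca"`.
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the result is reproducible given the seed.
#' @return an object of class `"bootstrap_result"`: `point_estimate`,
#'   `ci_low`, `ci_high`, `n_boot`, `method`, `level`, `significant`,
#'   `seed`, `n_failed_fits`, and the vector of bootstrap `replicates`.
#' @examples
#' b <- bootstrap_statistic(rnorm(50, mean = 2), mean,
#'                          n_boot = 500, seed = 1)
#' b$significant
#' @export
bootstrap_statistic <- function(data, statistic, n_boot = 10000L,
                                method = c("percentile", "bca"),
                                level = 0.95, seed = 1L) {
  method <- match.arg(method)
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("`n_boot` must be at least 100")
  is_df <- is.data.frame(data)
  n <- if (is_df) nrow(data) else length(data)
  if (n == 0L) stop("no data to resample")
  take <- if (is_df) function(idx) data[idx, , drop = FALSE]
  else function(idx) data[idx]
  safe_stat <- function(d)
    tryCatch(as.numeric(statistic(d)), error = function(e) NA_real_)

  theta <- safe_stat(data)
  if (is.na(theta)) stop("statistic failed on the full dataset")

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) safe_stat(take(sample.int(n, n, replace = TRUE))),
           numeric(1))
  })
  failed <- sum(is.na(reps))
  if (failed > 0.2 * n_boot)
    stop("statistic failed on ", failed, "/", n_boot,
         " bootstrap resamples (> 20%)")
  good <- reps[!is.na(reps)]
  a <- (1 - level) / 2
  ci <- if (method == "percentile") {
    unname(stats::quantile(good, c(a, 1 - a)))
  } else {
    bca_interval(data, take, safe_stat, theta, good, level)
  }

  structure(
    list(point_estimate = theta,
         ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, method = method, level = level,
         significant = ci[1] > 0 || ci[2] < 0,
         seed = seed, n_failed_fits = failed,
         replicates = good),
    class = "bootstrap_result")
}

# Standard BCa interval: bias correction z0 from the fraction of
# replicates below the point estimate, acceleration from the jackknife
# skewness of the statistic.
bca_interval <- function(data, take, safe_stat, theta, reps, level) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  prop <- mean(reps < theta)
  # degenerate distributions (all replicates identical) fall back to
  # percentile, which is exact there
  if (prop <= 0 || prop >= 1 || stats::sd(reps) == 0) {
    a <- (1 - level) / 2
    return(unname(stats::quantile(reps, c(a, 1 - a))))
  }
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n),
                 function(i) safe_stat(take(seq_len(n)[-i])),
                 numeric(1))
  jack <- jack[!is.na(jack)]
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  acc <- if (denom == 0) 0 else sum(u^3) / (6 * denom)
  zlo <- stats::qnorm((1 - level) / 2)
  zhi <- -zlo
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - acc * (z0 + z)))
  unname(stats::quantile(reps, c(adj(zlo), adj(zhi))))
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap (%s, %d iterations%s): %s, %d%% CI [%s, %s]%s\n",
              x$method, x$n_boot,
              if (x$n_failed_fits) paste0(", ", x$n_failed_fits, " failed")
              else "",
              format(x$point_estimate, digits = digits),
              round(100 * x$level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Bootstrap confidence interval for a DoG half-amplitude
#'
#' Fits the DoG curve to the full (x, y) trial set with the standard
#' multi-start search, then bootstraps the half-amplitude by resampling
#' trial pairs with replacement; each resample is refitted warm-started
#' from the full-sample solution (plus two spread starts to guard against
#' a resample shifting the optimum basin).
#'
#' @param x,y predictor and adjustment-error pairs (morph steps).
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param method interval type, `"percentile"` (default) or `"bca"`.
#' @param mu,bounds,min_n passed to [fit_dog()].
#' @return list with `fit` (the full-sample `"dog_fit"`) and `boot`
#'   (a `"bootstrap_result"` for the half-amplitude).
#' @export
bootstrap_half_amplitude <- function(x, y, n_boot = 10000L, seed = 1L,
                                     method = "percentile", mu = NULL,
                                     bounds = default_dog_bounds(),
                                     min_n = 10L) {
  fit <- fit_dog(x, y, mu = mu, bounds = bounds, min_n = min_n)
  cf <- coef(fit)
  warm <- rbind(c(cf["mu"], cf["sigma"]),
                c(0, max(bounds$sigma[1], 8)),
                c(0, min(bounds$sigma[2], 35)))
  dat <- data.frame(x = fit$data$x, y = fit$data$y)
  boot <- bootstrap_statistic(
    dat,
    function(d) fit_dog(d$x, d$y, mu = mu, bounds = bounds,
                        starts = warm, min_n = min_n)$half_amplitude,
    n_boot = n_boot, method = method, seed = seed)
  list(fit = fit, boot = boot)
}
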