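#' Derivative-of-Gaussian bias curve
#'
#' The serial-dependence bias curve relating the inducer-target difference
#' `x` (morph steps) to the predicted adjustment error (morph steps):
#'
#' \deqn{y(x) = \alpha \, \frac{x - \mu}{\sigma^2} \, N(x;\, \mu, \sigma)}
#'
#' where `N` is the normal density. Up to the sign of `alpha` this is the
#' first derivative of a Gaussian; the sign here is chosen so that positive
#' `alpha` produces errors of the same sign as `x`, i.e. attraction toward
#' the inducer, and negative `alpha` repulsion. With `mu = 0` the curve is
#' odd in `x`, vanishes at 0, and peaks at `x = ±sigma` with magnitude
#' `|alpha| e^{-1/2} / (sigma^2 sqrt(2 pi))`.
#'
#' @param x inducer-target difference in morph steps (vectorised).
#' @param mu centre of the underlying Gaussian (morph steps).
#' @param sigma width of the underlying Gaussian (morph steps, > 0).
#' @param alpha curve-height scale; sign encodes attraction (+) vs
#'   repulsion (-).
#' @return predicted adjustment error, same length as `x`.
#' @seealso [fit_dog()], [dog_half_amplitude()]
#' @export
dog_value <- function(x, mu = 0, sigma, alpha) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  dog_value_cpp(as.numeric(x), mu, sigma, alpha)
}

#' Peak height of a unit-alpha DoG with mu = 0
#' @noRd
dog_peak_coef <- function(sigma) {
  exp(-0.5) / (sigma^2 * sqrt(2 * pi))
}

#' Half-amplitude of a DoG bias curve
#'
#' The half-amplitude — the height of the curve from its peak to zero — is
#' the standard scalar summary of serial-dependence magnitude. It is
#' computed numerically as the largest absolute curve value over the
#' stimulus-difference domain, signed by `alpha` so that positive values
#' mean attraction. The numeric route stays correct when `mu != 0`; for
#' `mu = 0` it agrees with the closed form
#' `alpha * exp(-1/2) / (sigma^2 * sqrt(2*pi))` to high precision.
#'
#' @param mu,sigma,alpha DoG parameters (see [dog_value()]).
#' @param domain_half half-width of the stimulus-difference domain in morph
#'   steps (default 70, the 141-position wheel).
#' @return signed half-amplitude in morph steps.
#' @export
dog_half_amplitude <- function(mu = 0, sigma, alpha, domain_half = 70) {
  if (domain_half <= 0) stop("`domain_half` must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (alpha == 0) return(0)
  grid <- seq(-domain_half, domain_half, length.out = 2001L)
  av <- abs(dog_value(grid, mu, sigma, alpha))
  i <- which.max(av)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(z) abs(dog_value(z, mu, sigma, alpha)),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  sign(alpha) * max(opt$objective, av[i])
}

default_dog_bounds <- function() {
  list(mu = c(-20, 20), sigma = c(3, 70), alpha = c(-1e6, 1e6))
}

#' Fit the DoG bias curve by constrained least squares
#'
#' Fits `y = dog_value(x; mu, sigma, alpha)` by minimising the residual sum
#' of squares under box constraints, using multiple deterministic starting
#' points (the DoG least-squares surface is multimodal in `sigma`). For a
#' given `(mu, sigma)` the optimal `alpha` is linear and is profiled out,
#' so the search runs over `(mu, sigma)` only (over `sigma` alone when `mu`
#' is fixed). The best-RSS solution wins; RSS ties are broken toward the
#' smaller `sigma`.
#'
#' @param x inducer-target differences (morph steps).
#' @param y adjustment errors (morph steps).
#' @param mu `NULL` (default) to estimate `mu`, or a number to fix it
#'   (e.g. `mu = 0` for the odd-symmetric curve).
#' @param bounds list with elements `mu`, `sigma`, `alpha`, each a
#'   `c(lower, upper)` pair. Defaults: `mu` in \[-20, 20\], `sigma` in
#'   \[3, 70\] morph steps, `alpha` in \[-1e6, 1e6\].
#' @param n_starts number of multi-start points (default 12).
#' @param starts optional numeric matrix with columns `mu`, `sigma` giving
#'   explicit starting points (overrides the default grid; used internally
#'   for warm-started bootstrap refits).
#' @param min_n minimum number of (x, y) pairs (default 10); fewer is an
#'   error (the condition is non-estimable).
#' @param domain_half domain half-width for the half-amplitude (default 70).
#' @return an object of class `"dog_fit"` with components `coefficients`
#'   (`mu`, `sigma`, `alpha`), `half_amplitude`, `rss`, `n`, `converged`,
#'   `n_starts_used`, `fitted.values`, `residuals`, and the data.
#' @examples
#' x <- rep(-70:70, 4)
#' y <- dog_value(x, 0, 20, 500) + rnorm(length(x), sd = 2)
#' fit <- fit_dog(x, y)
#' coef(fit)
#' fit$half_amplitude
#' @export
fit_dog <- function(x, y, mu = NULL, bounds = default_dog_bounds(),
                    n_starts = 12L, starts = NULL, min_n = 10L,
                    domain_half = 70) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) stop("too few pairs to fit (", n, " < ", min_n, ")")
  if (diff(range(x)) == 0) stop("degenerate predictor: all x equal")
  b <- default_dog_bounds()
  b[names(bounds)] <- bounds
  fix_mu <- !is.null(mu)
  if (fix_mu && (mu < b$mu[1] || mu > b$mu[2]))
    b$mu <- range(c(b$mu, mu))

  obj <- if (fix_mu)
    function(p) dog_profile_rss(mu, p[1], x, y, b$alpha[1], b$alpha[2])[1]
  else
    function(p) dog_profile_rss(p[1], p[2], x, y, b$alpha[1], b$alpha[2])[1]

  if (is.null(starts)) {
    n_sig <- max(2L, ceiling(n_starts / if (fix_mu) 1L else 3L))
    sig0 <- exp(seq(log(max(b$sigma[1], 3)), log(min(b$sigma[2], 60)),
                    length.out = n_sig))
    mu0 <- if (fix_mu) mu else
      pmin(pmax(c(-10, 0, 10), b$mu[1]), b$mu[2])
    starts <- as.matrix(expand.grid(mu = mu0, sigma = sig0))
    starts <- starts[seq_len(min(nrow(starts), max(n_starts, 1L))), ,
                     drop = FALSE]
  } else {
    starts <- as.matrix(starts)
    colnames(starts) <- c("mu", "sigma")
  }

  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    p0 <- if (fix_mu) starts[s, "sigma"] else starts[s, c("mu", "sigma")]
    lower <- if (fix_mu) b$sigma[1] else c(b$mu[1], b$sigma[1])
    upper <- if (fix_mu) b$sigma[2] else c(b$mu[2], b$sigma[2])
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$convergence == 0
    any_conv <- any_conv || conv
    cand_sigma <- if (fix_mu) res$par[1] else res$par[2]
    if (is.null(best) ||
        res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && cand_sigma < best$sigma)) {
      best <- list(value = res$value,
                   mu = unname(if (fix_mu) mu else res$par[1]),
                   sigma = unname(cand_sigma))
    }
  }
  if (is.null(best)) stop("all optimisation starts failed")

  pr <- dog_profile_rss(best$mu, best$sigma, x, y, b$alpha[1], b$alpha[2])
  cf <- c(mu = best$mu, sigma = best$sigma, alpha = pr[2])
  fitted <- dog_value(x, cf["mu"], cf["sigma"], cf["alpha"])
  ha <- if (any_conv)
    dog_half_amplitude(cf["mu"], cf["sigma"], cf["alpha"], domain_half)
  else NA_real_

  structure(
    list(coefficients = cf,
         half_amplitude = unname(ha),
         rss = pr[1],
         n = n,
         converged = any_conv,
         n_starts_used = nrow(starts),
         fitted.values = fitted,
         residuals = y - fitted,
         data = list(x = x, y = y),
         bounds = b,
         mu_fixed = fix_mu,
         domain_half = domain_half),
    class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, digits = 4, ...) {
  cat("Derivative-of-Gaussian bias fit (", x$n, " trials)\n", sep = "")
  print(round(x$coefficients, digits))
  cat("Half-amplitude:", format(x$half_amplitude, digits = digits),
      "morph steps",
      if (!is.na(x$half_amplitude) && x$half_amplitude > 0) "(attraction)"
      else if (!is.na(x$half_amplitude) && x$half_amplitude < 0) "(repulsion)"
      else "", "\n")
  cat("RSS:", format(x$rss, digits = digits),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.dog_fit <- function(object, ...) {
  s <- object
  s$sigma_resid <- sqrt(s$rss / max(1, s$n - 3))
  class(s) <- c("summary.dog_fit", "dog_fit")
  s
}

#' @export
print.summary.dog_fit <- function(x, digits = 4, ...) {
  print.dog_fit(x, digits = digits)
  cat("Residual SD:", format(x$sigma_resid, digits = digits),
      "morph steps on", x$n - 3, "residual df\n")
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) object$coefficients

#' @export
fitted.dog_fit <- function(object, ...) object$fitted.values

#' @export
residuals.dog_fit <- function(object, ...) object$residuals

#' Predict adjustment error from a fitted DoG curve
#'
#' @param object a `"dog_fit"`.
#' @param newdata numeric vector of stimulus differences, or a data.frame
#'   with an `x` column; defaults to the fitting data.
#' @param ... unused.
#' @export
predict.dog_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.data.frame(newdata)) newdata$x
  else as.numeric(newdata)
  cf <- object$coefficients
  dog_value(x, cf["mu"], cf["sigma"], cf["alpha"])
}

#' Simulate responses from a fitted DoG curve
#'
#' Draws new adjustment errors at the fitted stimulus differences as the
#' fitted curve plus Gaussian residual noise at the fit's residual SD.
#'
#' @param object a `"dog_fit"`.
#' @param nsim number of simulated replicates.
#' @param seed optional seed, as in [stats::simulate()].
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated errors.
#' @export
simulate.dog_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  sd <- sqrt(object$rss / max(1, object$n - 3))
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(object$n, sd = sd),
    simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a DoG fit with the raw trials and a moving average
#'
#' @param x a `"dog_fit"`.
#' @param window moving-average window in morph steps (odd, default 15);
#'   `NULL` suppresses the moving average.
#' @param ... passed to [plot()].
#' @export
plot.dog_fit <- function(x, window = 15, ...) {
  dat <- x$data
  plot(dat$x, dat$y, pch = 16, cex = 0.4, col = "grey60",
       xlab = "Inducer - target difference (morph steps)",
       ylab = "Adjustment error (morph steps)", ...)
  graphics::abline(h = 0, col = "grey80")
  xs <- seq(min(dat$x), max(dat$x), length.out = 400)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  if (!is.null(window)) {
    ma <- moving_average(dat$x, dat$y, window = window)
    graphics::lines(ma$x, ma$y, lty = 3, col = "blue", lwd = 2)
  }
  invisible(x)
}

predictor_variants <- c("within_trial", "prev_face2", "prev_face1",
                        "prev_response")

#' Build (x, y) predictor pairs for within- or across-trial analyses
#'
#' For the within-trial analysis every kept trial contributes the pair
#' (inducer-target difference, adjustment error). For the across-trial
#' variants the predictor is the signed distance from the current trial's
#' target to, respectively, the previous trial's Face 2, Face 1, or
#' response; the first trial of each session has no predecessor and is
#' dropped, as is any pair whose current or previous trial was excluded by
#' the lapse filter.
#'
#' @param trials derived trials (from [derive_trials()]; may contain
#'   excluded trials, which are handled as above).
#' @param variant one of `"within_trial"`, `"prev_face2"`, `"prev_face1"`,
#'   `"prev_response"`.
#' @param wheel a [morph_wheel()].
#' @return data.frame with columns `x`, `y`, `condition` (the current
#'   trial's condition key).
#' @export
build_predictor <- function(trials, variant, wheel) {
  variant <- match.arg(variant, predictor_variants)
  df <- trials[order(trials$participant, trials$session, trials$trial), ,
               drop = FALSE]
  if (variant == "within_trial") {
    keep <- !df$excluded
    return(data.frame(x = df$delta[keep], y = df$error[keep],
                      condition = df$condition[keep],
                      stringsAsFactors = FALSE))
  }
  prev_col <- switch(variant, prev_face2 = "face2", prev_face1 = "face1",
                     prev_response = "response")
  sess <- interaction(df$participant, df$session, drop = TRUE)
  same_sess <- c(FALSE, sess[-1] == sess[-length(sess)])
  prev_val <- c(NA, df[[prev_col]][-nrow(df)])
  prev_excl <- c(TRUE, df$excluded[-nrow(df)])
  keep <- same_sess & !df$excluded & !prev_excl
  data.frame(
    x = signed_distance(df$target[keep], prev_val[keep], wheel),
    y = df$error[keep],
    condition = df$condition[keep],
    stringsAsFactors = FALSE)
}
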