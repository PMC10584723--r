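test_that("dog_value has the DoG shape: zero at mu, odd about mu", {
  expect_equal(dog_value(7, mu = 7, sigma = 12, alpha = 300), 0)
  x <- seq(0.5, 70, by = 0.5)
  expect_equal(dog_value(-x, 0, 15, 200), -dog_value(x, 0, 15, 200))
  # attraction sign convention: positive alpha pulls errors toward +x
  expect_true(all(dog_value(x, 0, 15, 200) > 0))
  expect_error(dog_value(1, 0, -1, 10), "sigma")
})

test_that("curve extremum sits at mu +/- sigma with the closed-form height", {
  # dense grid search as the independent oracle for the calculus result
  for (sigma in c(5, 20, 40)) {
    grid <- seq(-70, 70, by = 1e-3)
    v <- dog_value(grid, 0, sigma, 1000)
    expect_equal(grid[which.max(v)], sigma, tolerance = 1e-2)
    expect_equal(max(v), 1000 * exp(-0.5) / (sigma^2 * sqrt(2 * pi)),
                 tolerance = 1e-6)
  }
})

test_that("numeric half-amplitude matches the analytic extremum", {
  expect_equal(dog_half_amplitude(0, 10, 0), 0)
  for (sigma in c(3, 5, 10, 20, 40, 70)) {
    for (alpha in c(-1000, -1, 1, 500)) {
      closed <- alpha * exp(-0.5) / (sigma^2 * sqrt(2 * pi))
      expect_equal(dog_half_amplitude(0, sigma, alpha), closed,
                   tolerance = 1e-9)
    }
  }
  # exact linearity in alpha
  h1 <- dog_half_amplitude(0, 17, 250)
  expect_equal(dog_half_amplitude(0, 17, 500), 2 * h1, tolerance = 1e-12)
  # sign equals sign(alpha) also for shifted curves
  expect_gt(dog_half_amplitude(5, 12, 100), 0)
  expect_lt(dog_half_amplitude(5, 12, -100), 0)
})

test_that("fit_dog recovers noiseless parameters and handles degenerate y", {
  x <- rep(-70:70, 6)
  y <- dog_value(x, 0, 20, 500)
  fit <- fit_dog(x, y)
  expect_s3_class(fit, "dog_fit")
  expect_equal(unname(coef(fit)), c(0, 20, 500), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$half_amplitude, dog_half_amplitude(0, 20, 500),
               tolerance = 1e-6)
  expect_true(fit$converged)

  flat <- fit_dog(x, rep(0, length(x)))
  expect_equal(flat$half_amplitude, 0, tolerance = 1e-8)

  expect_error(fit_dog(1:5, 1:5), "too few")
  expect_error(fit_dog(rep(3, 20), rnorm(20)), "degenerate")
})

test_that("fit is deterministic and reflection-equivariant", {
  set.seed(41)
  x <- sample(-70:70, 800, replace = TRUE)
  y <- dog_value(x, 3, 15, 4000) + rnorm(800, sd = 8)
  f1 <- fit_dog(x, y)
  f2 <- fit_dog(x, y)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$half_amplitude, f2$half_amplitude)

  # mirroring the stimulus axis flips attraction and the curve centre
  fx <- fit_dog(-x, y)
  expect_equal(fx$half_amplitude, -f1$half_amplitude, tolerance = 1e-4)
  expect_equal(unname(coef(fx)["mu"]), -unname(coef(f1)["mu"]),
               tolerance = 1e-4)
  expect_equal(fx$rss, f1$rss, tolerance = 1e-6)
  # mirroring both axes is a pure relabelling: attraction is preserved
  fxy <- fit_dog(-x, -y)
  expect_equal(fxy$half_amplitude, f1$half_amplitude, tolerance = 1e-4)
  expect_equal(unname(coef(fxy)["mu"]), -unname(coef(f1)["mu"]),
               tolerance = 1e-4)
})

test_that("noisy data recover the true half-amplitude within its CI", {
  true_ha <- 4
  sigma <- 20
  alpha <- true_ha / (exp(-0.5) / (sigma^2 * sqrt(2 * pi)))
  set.seed(7)
  x <- sample(-70:70, 1800, replace = TRUE)
  y <- dog_value(x, 0, sigma, alpha) + rnorm(1800, sd = 10)
  res <- bootstrap_half_amplitude(x, y, n_boot = 300, seed = 11)
  expect_lt(res$boot$ci_low, true_ha)
  expect_gt(res$boot$ci_high, true_ha)
  expect_lt(abs(res$fit$half_amplitude - true_ha), 1.5)
})

test_that("mu can be fixed at zero", {
  set.seed(13)
  x <- sample(-70:70, 2000, replace = TRUE)
  y <- dog_value(x, 0, 18, 3000) + rnorm(2000, sd = 3)
  f <- fit_dog(x, y, mu = 0)
  expect_equal(unname(coef(f)["mu"]), 0)
  expect_equal(unname(coef(f)["sigma"]), 18, tolerance = 0.05)
  expect_equal(f$half_amplitude, dog_half_amplitude(0, 18, 3000),
               tolerance = 0.05)
})

test_that("predictor construction follows the session structure", {
  w <- morph_wheel()
  rec <- make_records(face1 = c(10, 100, 50), face2 = c(0, 30, 120),
                      response = c(3, 28, 125))
  d <- derive_trials(rec, w, 1)

  within <- build_predictor(d, "within_trial", w)
  expect_equal(nrow(within), 3L)
  expect_equal(within$x, d$delta)
  expect_equal(within$y, d$error)

  # hand-computed pairs for the across-trial variants (first trial dropped)
  pf2 <- build_predictor(d, "prev_face2", w)
  expect_equal(nrow(pf2), 2L)
  expect_equal(pf2$x, c(oracle_signed_distance(30, 0, 141),
                        oracle_signed_distance(120, 30, 141)))
  pf1 <- build_predictor(d, "prev_face1", w)
  expect_equal(pf1$x, c(oracle_signed_distance(30, 10, 141),
                        oracle_signed_distance(120, 100, 141)))
  pr <- build_predictor(d, "prev_response", w)
  expect_equal(pr$x, c(oracle_signed_distance(30, 3, 141),
                       oracle_signed_distance(120, 28, 141)))
  expect_equal(pr$y, d$error[2:3])

  # two-trial session: exactly one across-trial pair
  two <- derive_trials(make_records(c(5, 9), c(1, 2), c(3, 4)), w, 1)
  expect_equal(nrow(build_predictor(two, "prev_response", w)), 1L)

  # an excluded middle trial removes both pairs it touches
  rec$rt_s[2] <- 20
  d_ex <- derive_trials(rec, w, 1)
  expect_equal(nrow(build_predictor(d_ex, "prev_face2", w)), 0L)
  expect_equal(nrow(build_predictor(d_ex, "within_trial", w)), 2L)
})

test_that("dog_fit methods are coherent", {
  set.seed(5)
  x <- sample(-70:70, 400, replace = TRUE)
  y <- dog_value(x, 0, 20, 3000) + rnorm(400, sd = 6)
  f <- fit_dog(x, y)
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(predict(f, data.frame(x = c(0, 20))),
               dog_value(c(0, 20), coef(f)["mu"], coef(f)["sigma"],
                         coef(f)["alpha"]))
  s <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(s), c(400L, 2L))
  expect_output(print(summary(f)), "Residual SD")
})
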