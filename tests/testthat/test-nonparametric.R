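w <- morph_wheel()

# direct data.frame with resolved roles; categorical_index only needs
# target / inducer / response columns
cat_trials <- function(target, inducer, response) {
  data.frame(target = target, inducer = inducer, response = response)
}

test_that("an all-attracted error set hits the 66.67 ceiling", {
  # targets in category 1 (anchor 0), inducers spread over all three
  # categories, every response landing in the inducer's category
  anchors <- c(0L, 47L, 94L)
  tr <- cat_trials(target = rep(0L, 30),
                   inducer = rep(anchors, each = 10),
                   response = rep(anchors, each = 10))
  tr <- tr[tr$inducer != 0L, ]  # keep only genuine errors
  expect_warning(ci <- categorical_index(tr, w, n_boot = 0),
                 "zero errors")
  expect_equal(ci$index_pct, 100 - 100 / 3, tolerance = 1e-10)
  expect_equal(ci$n_errors, 20L)
  # ... except the inducer-category-1 partition, which has no errors
  expect_true(is.na(ci$per_category_ratio[1]))
})

test_that("error-free data are flagged non-estimable with 100% accuracy", {
  tr <- cat_trials(target = 0:20, inducer = 60:80, response = 0:20)
  expect_warning(ci <- categorical_index(tr, w, n_boot = 0), NA)
  expect_false(ci$estimable)
  expect_equal(ci$accuracy_pct, 100)
  expect_true(is.na(ci$index_pct))
})

test_that("independent uniform responses sit at the 33.33% chance level", {
  n <- 30000
  tr <- with_seed_local(99, cat_trials(
    target = sample(0:140, n, TRUE),
    inducer = sample(0:140, n, TRUE),
    response = sample(0:140, n, TRUE)))
  ci <- categorical_index(tr, w, n_boot = 0)
  expect_lt(abs(ci$index_pct), 1.0)
  expect_equal(ci$mean_ratio_pct, 100 / 3, tolerance = 0.03)
  acc <- classification_accuracy(tr, w, n_boot = 0)
  expect_equal(acc$accuracy_pct, 100 / 3, tolerance = 0.03)
})

test_that("index is invariant under the wheel's rotation symmetry", {
  n <- 4000
  tr <- with_seed_local(17, cat_trials(
    target = sample(0:140, n, TRUE),
    inducer = sample(0:140, n, TRUE),
    response = sample(0:140, n, TRUE)))
  rot <- as.data.frame(lapply(tr, function(p) (p + 47L) %% 141L))
  i1 <- categorical_index(tr, w, n_boot = 0)
  i2 <- categorical_index(rot, w, n_boot = 0)
  expect_equal(i2$index_pct, i1$index_pct)
  expect_equal(i2$per_category_ratio, i1$per_category_ratio[c(3, 1, 2)])
})

test_that("shared-category trials never feed their own numerator", {
  # inducer and target in the same category: an error response cannot be
  # in the target (= inducer) category by definition of an error
  tr <- cat_trials(target = rep(0L, 12), inducer = rep(5L, 12),
                   response = c(rep(50L, 6), rep(100L, 6)))
  expect_warning(ci <- categorical_index(tr, w, n_boot = 0),
                 "zero errors")
  expect_equal(ci$per_category_ratio[1], 0)
  expect_equal(ci$n_errors, 12L)
})

test_that("zero-error partitions average over the defined categories", {
  # only inducer categories 2 and 3 produce errors
  tr <- cat_trials(target = rep(0L, 20),
                   inducer = rep(c(47L, 94L), each = 10),
                   response = rep(c(47L, 94L), each = 10))
  expect_warning(ci <- categorical_index(tr, w, n_boot = 0),
                 "zero errors")
  expect_equal(ci$mean_ratio_pct, 100)
})

test_that("accuracy tracks the response-noise level and gains a bootstrap SD", {
  # zero-noise observer: response equals target
  tr0 <- cat_trials(target = 0:140, inducer = 70L, response = 0:140)
  expect_equal(classification_accuracy(tr0, w, n_boot = 0)$accuracy_pct, 100)

  cfg <- sim_config(n_participants = 4, seed = 2)
  d <- filter_trials(derive_trials(simulate_experiment(cfg),
                                   w, 1))$kept
  acc <- classification_accuracy(d, w, n_boot = 400, seed = 1)
  expect_gt(acc$accuracy_pct, 66)
  expect_lt(acc$accuracy_pct, 78)
  expect_gt(acc$sd, 0)

  ci <- categorical_index(d, w, n_boot = 300, seed = 4)
  expect_lte(ci$ci_low, ci$ci_high)
  expect_equal(ci$accuracy_pct, acc$accuracy_pct)
})

test_that("grand-total denominator variant stays available and bounded", {
  n <- 5000
  tr <- with_seed_local(3, cat_trials(
    target = sample(0:140, n, TRUE),
    inducer = sample(0:140, n, TRUE),
    response = sample(0:140, n, TRUE)))
  g <- categorical_index(tr, w, denominator = "grand", n_boot = 0)
  p <- categorical_index(tr, w, denominator = "partition", n_boot = 0)
  expect_false(isTRUE(all.equal(g$index_pct, p$index_pct)))
  expect_true(all(g$per_category_ratio >= 0 & g$per_category_ratio <= 1))
})
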