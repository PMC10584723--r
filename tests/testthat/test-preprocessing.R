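w <- morph_wheel()

test_that("derive_trials resolves targets and signed quantities", {
  d <- derive_trials(make_records(10, 0, 3), w, 1)
  expect_equal(d$target, 0)
  expect_equal(d$inducer, 10)
  expect_equal(d$error, 3L)
  expect_equal(d$delta, 10L)

  # wrap-around case, checked against the walking oracle
  d2 <- derive_trials(make_records(0, 130, 135), w, 1)
  expect_equal(d2$error, oracle_signed_distance(130, 135, 141))
  expect_equal(d2$error, 5L)
  expect_equal(d2$delta, oracle_signed_distance(130, 0, 141))
  expect_equal(d2$delta, 11L)

  # Experiment 2, postcue 1: roles swap to target = Face 1
  d3 <- derive_trials(make_records(20, 60, 25, postcue = 1L), w, 2)
  expect_equal(d3$target, 20)
  expect_equal(d3$inducer, 60)
  expect_equal(d3$error, 5L)
  expect_equal(d3$delta, 40L)

  # postcue 2 keeps Face 2 as target
  d4 <- derive_trials(make_records(20, 60, 25, postcue = 2L), w, 2)
  expect_equal(d4$target, 60)
  expect_equal(d4$delta, -40L)
})

test_that("experiment/postcue mismatches are rejected", {
  expect_error(derive_trials(make_records(1, 2, 3, postcue = 1L), w, 1),
               "postcue")
  expect_error(derive_trials(make_records(1, 2, 3), w, 2), "postcue")
  expect_error(derive_trials(make_records(1, 2, 3, isi = 2), w, 1),
               "level sets")
})

test_that("lapse filter uses strict thresholds and counts removals once", {
  rec <- make_records(face1 = rep(0, 10), face2 = rep(0, 10),
                      response = c(3, 61, rep(3, 8)),
                      rt = c(16, rep(5, 9)))
  d <- derive_trials(rec, w, 1)
  f <- filter_trials(d)
  expect_equal(nrow(f$kept), 8L)
  expect_equal(f$removal_fraction, 0.20)

  # boundary trials are kept: RT exactly 15 s, |error| exactly 60
  b <- derive_trials(make_records(0, 0, 60, rt = 15.0), w, 1)
  expect_false(b$excluded)
  expect_equal(filter_trials(b)$removal_fraction, 0)

  # a trial failing both criteria is one removal with both reasons
  both <- derive_trials(make_records(0, 0, 65, rt = 20), w, 1)
  expect_equal(both$exclude_reason, "rt>15s;error>60")
  expect_equal(filter_trials(both)$removal_fraction, 1)

  clean <- derive_trials(make_records(0:4, 5, 6), w, 1)
  expect_equal(filter_trials(clean)$removal_fraction, 0)
})

test_that("round trip: error re-derives from target and response", {
  cfg <- sim_config(n_participants = 2, seed = 3)
  d <- derive_trials(simulate_experiment(cfg), w, 1)
  expect_equal(d$error, signed_distance(d$target, d$response, w))
  # derivation is order-invariant over session concatenation
  d_rev <- derive_trials(simulate_experiment(cfg)[360:1, ], w, 1)
  expect_equal(d_rev$error[360:1], d$error)
})

test_that("condition grouping is complete with empties retained", {
  cfg <- sim_config(n_participants = 1, lapse_rate = 0, seed = 5)
  d <- derive_trials(simulate_experiment(cfg), w, 1)
  g <- group_by_condition(d, 1)
  expect_equal(names(g), condition_keys(1))
  expect_equal(unname(sapply(g, nrow)), rep(9L, 20))

  cfg2 <- sim_config(experiment = 2, n_participants = 1, lapse_rate = 0,
                     seed = 5)
  g2 <- group_by_condition(derive_trials(simulate_experiment(cfg2), w, 2), 2)
  expect_equal(unname(sapply(g2, nrow)), rep(50L, 6))

  one <- derive_trials(make_records(1, 2, 3, isi = 3, delay = 6), w, 1)
  g1 <- group_by_condition(one, 1)
  expect_equal(sum(sapply(g1, nrow) > 0), 1L)
  expect_equal(nrow(g1[["isi3_delay6"]]), 1L)
  # pooling preserves the trial count
  expect_equal(sum(sapply(g, nrow)), 180L)
})

test_that("trial CSV round-trips, including 1-based image IDs", {
  cfg <- sim_config(n_participants = 1, seed = 9)
  tr <- simulate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$face1, tr$face1)
  expect_equal(back$response, tr$response)

  write_trials(tr, path, index_base = 1L)
  raw <- utils::read.csv(path)
  expect_equal(raw$face1, tr$face1 + 1L)
  back1 <- read_trials(path, index_base = 1L)
  expect_equal(back1$face2, tr$face2)

  extra <- cbind(tr, junk = 1)
  write_trials(extra, path)
  expect_warning(read_trials(path), "unknown columns")
})
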