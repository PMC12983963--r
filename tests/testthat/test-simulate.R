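test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulate_cohort(n_per_group = 3, n_days = 15, seed = 42)
  b <- simulate_cohort(n_per_group = 3, n_days = 15, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_cohort(n_per_group = 3, n_days = 15, seed = 43)
  expect_false(identical(a, c2))
})

test_that("cohort structure matches the record schema and time budget", {
  rec <- simulate_cohort(n_per_group = 4, n_days = 12, seed = 5)
  expect_equal(nrow(rec), 2 * 4 * 12)
  expect_true(all(c(
    "calf_id", "date", "group", "temperature_c", "humidity_pct", "wind",
    "weight_kg", "height_cm", "diagonal_cm", "chest_cm", "lying_min",
    "standing_min", "rr_per_min", "urination_n", "defecation_n"
  ) %in% names(rec)))
  # lying + standing fills the day exactly
  expect_equal(rec$lying_min + rec$standing_min, rep(1440, nrow(rec)))
  expect_true(all(rec$urination_n >= 0 & rec$urination_n == round(rec$urination_n)))
  expect_error(simulate_cohort(n_per_group = 0), class = "coldstress_error_configuration")
})

test_that("outdoor weather stays inside the configured envelope across seeds", {
  for (s in 1:20) {
    rec <- simulate_cohort(n_per_group = 1, n_days = 20, seed = s)
    out <- rec[rec$group == "outdoor", ]
    expect_true(all(out$temperature_c >= -26 & out$temperature_c <= 1.21))
    expect_true(all(out$humidity_pct >= 71 & out$humidity_pct <= 75))
    expect_true(all(out$wind >= 8.46 & out$wind <= 9.34))
    ind <- rec[rec$group == "indoor", ]
    expect_true(all(ind$temperature_c == 5 & ind$humidity_pct == 75))
  }
})

test_that("seed-averaged behavior means track the configured targets", {
  lying_out <- vapply(1:12, function(s) {
    rec <- simulate_cohort(n_per_group = 6, n_days = 20, seed = s)
    mean(rec$lying_min[rec$group == "outdoor"])
  }, numeric(1))
  expect_lt(abs(mean(lying_out) - 1027.12) / 1027.12, 0.02)
})

test_that("weights grow in expectation with the configured phase ADGs", {
  rec <- simulate_cohort(n_per_group = 5, n_days = 60, seed = 77)
  gains <- tapply(rec$weight_kg, rec$calf_id, function(w) diff(range(w)))
  # 30 days at each phase ADG, modulated by a tight frailty
  expected_outdoor <- 29 * 0.66 + 30 * 1.22
  expected_indoor <- 29 * 0.76 + 30 * 0.71
  expect_equal(mean(gains[grep("outdoor", names(gains))]), expected_outdoor, tolerance = 0.1)
  expect_equal(mean(gains[grep("indoor", names(gains))]), expected_indoor, tolerance = 0.1)
  # within-calf weights never decrease (growth is cumulative)
  mono <- tapply(rec$weight_kg, rec$calf_id, function(w) all(diff(w) > 0))
  expect_true(all(mono))
})

test_that("metabolome generation is deterministic and spikes where it says", {
  a <- simulate_metabolome(n_per_group = 4, n_features = 20, n_differential = 4, seed = 1)
  b <- simulate_metabolome(n_per_group = 4, n_features = 20, n_differential = 4, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 4L)
  expect_true(all(a$truth$fold_change != 1))

  # realized group mean ratios approximate the spiked fold changes
  sm <- simulate_metabolome(
    n_per_group = 40, n_features = 30, n_differential = 6,
    noise_sd = 0.2, seed = 31
  )
  x <- as.matrix(sm$table[, sm$truth$feature])
  out <- sm$table$group == "outdoor"
  realized <- colMeans(x[out, ]) / colMeans(x[!out, ])
  expect_equal(unname(log2(realized)), log2(sm$truth$fold_change), tolerance = 0.25)

  expect_error(
    simulate_metabolome(n_features = 5, n_differential = 6),
    class = "coldstress_error_configuration"
  )
})

test_that("generated tables round-trip through CSV without loss", {
  rec <- simulate_cohort(n_per_group = 2, n_days = 6, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
})
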