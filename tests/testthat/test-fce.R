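test_that("weighted-average composition reproduces the published group vectors", {
  wx <- worked_example()
  b1 <- fce_compose(wx$w1, wx$e1)
  expect_equal(unname(b1), c(0.05, 0.489, 0.011, 0, 0), tolerance = 1e-12)
  expect_equal(round(unname(b1), 2), c(0.05, 0.49, 0.01, 0, 0))

  b2 <- fce_compose(wx$w2, wx$e2)
  expect_equal(unname(b2), c(0.331, 0.019, 0, 0, 0), tolerance = 1e-12)
  expect_equal(round(unname(b2), 2), c(0.33, 0.02, 0, 0, 0))

  # hand vector-matrix multiplication for the behavioral group
  b3 <- fce_compose(wx$w3, wx$e3)
  expect_equal(unname(b3), c(0.097, 0.023, 0, 0, 0), tolerance = 1e-12)
})

test_that("composition operators behave as selection under one-hot weights", {
  e <- worked_example()$e2
  one_hot <- c(1, 0, 0, 0)
  expect_equal(unname(fce_compose(one_hot, e)), unname(e[1, ]))
  expect_equal(unname(fce_compose(one_hot, e, operator = "max_min")), unname(e[1, ]))
  expect_error(fce_compose(c(0.5, 0.5), e), class = "coldstress_error_shape")
})

test_that("aggregation reproduces the published comprehensive vector", {
  wx <- worked_example()
  b <- rbind(
    fce_compose(wx$w1, wx$e1), fce_compose(wx$w2, wx$e2), fce_compose(wx$w3, wx$e3)
  )
  v <- fce_aggregate(wx$w_first, b)
  expect_equal(unname(v), c(0.15352, 0.27324, 0.00594, 0, 0), tolerance = 1e-9)
  expect_equal(round(unname(v), 2), c(0.15, 0.27, 0.01, 0, 0))

  expect_equal(unname(fce_aggregate(c(1, 0, 0), b)), unname(b[1, ]))
  # convexity fixed point: identical group vectors pass through any sum-1 W
  same <- rbind(b[1, ], b[1, ], b[1, ])
  expect_equal(unname(fce_aggregate(c(0.2, 0.5, 0.3), same)), unname(b[1, ]))
})

test_that("normalization and maximum-membership classification", {
  v <- c(0.15352, 0.27324, 0.00594, 0, 0)
  vn <- fce_normalize(v)
  expect_equal(sum(vn), 1)
  expect_equal(round(vn[1], 2), 0.35)
  expect_equal(fce_normalize(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fce_normalize(rep(0, 5)), class = "coldstress_error_degenerate")

  expect_equal(fce_classify(vn)$level_index, 2L)
  expect_equal(fce_classify(c(0, 0, 0, 0, 1))$level, "extreme")
  # severity-biased tie-break
  expect_equal(fce_classify(c(0.4, 0.4, 0.2, 0, 0))$level_index, 2L)
  # classification is invariant to positive scaling before normalization
  expect_equal(fce_classify(fce_normalize(10 * v))$level_index, 2L)
})

test_that("row-stochastic membership with sum-1 weights keeps mass 1", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    e <- t(apply(matrix(stats::runif(n * 5), n, 5), 1, function(r) r / sum(r)))
    w <- stats::runif(n)
    w <- w / sum(w)
    expect_lt(abs(sum(fce_compose(w, membership_matrix(e))) - 1), 1e-9)
  }
})

test_that("trapezoidal memberships partition unity and respect direction", {
  spec <- default_membership_spec()
  # plateau center of the mild band for lying time
  r <- list(
    temperature_c = 5, humidity_pct = 72, wind = 9, weight_kg = 36.7,
    height_cm = 76, diagonal_cm = 55, chest_cm = 80,
    lying_min = 950, standing_min = 490, rr_per_min = 42, urination_n = 1.5
  )
  e <- membership_from_record(r, spec, "behavioral")
  expect_equal(unname(e["lying_min", ]), c(0, 1, 0, 0, 0))
  # symmetric overlap midpoint: lying cutpoint 1000, overlap 30
  r$lying_min <- 1000
  e <- membership_from_record(r, spec, "behavioral")
  expect_equal(unname(e["lying_min", ]), c(0, 0.5, 0.5, 0, 0))

  # property sweep: rows sum to 1 across a grid of in-domain values
  for (x in seq(-40, 30, length.out = 41)) {
    r$lying_min <- 950
    r2 <- r
    r2$temperature_c <- x
    e2 <- membership_from_record(r2, spec, "environmental")
    expect_equal(rowSums(e2), c(temperature_c = 1, humidity_pct = 1, wind = 1))
  }
  # colder is more severe: severity index grows as temperature drops
  sev <- vapply(c(12, 5, -5, -15, -25), function(tmp) {
    r2 <- r
    r2$temperature_c <- tmp
    which.max(membership_from_record(r2, spec, "environmental")["temperature_c", ])
  }, integer(1))
  expect_true(all(diff(sev) >= 0))
})

test_that("membership evaluation rejects out-of-domain and missing indicators", {
  spec <- default_membership_spec()
  r <- list(temperature_c = -100, humidity_pct = 70, wind = 9)
  expect_error(membership_from_record(r, spec, "environmental"),
    class = "coldstress_error_domain"
  )
  expect_error(membership_from_record(list(temperature_c = 0), spec, "environmental"),
    class = "coldstress_error_schema"
  )
})

test_that("membership matrices are validated", {
  expect_error(membership_matrix(rbind(c(0.5, 0.4, 0, 0, 0))),
    class = "coldstress_error_validation"
  )
  expect_error(membership_matrix(rbind(c(1.2, -0.2, 0, 0, 0))),
    class = "coldstress_error_validation"
  )
  expect_error(membership_matrix(matrix(0.25, 2, 4)), class = "coldstress_error_shape")
})
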