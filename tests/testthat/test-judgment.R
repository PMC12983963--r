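test_that("reciprocal completion builds exact reciprocal matrices", {
  m <- judgment_matrix(c(2, 5, 3))
  expect_equal(unclass(m), rbind(c(1, 2, 5), c(1 / 2, 1, 3), c(1 / 5, 1 / 3, 1)),
    ignore_attr = TRUE
  )

  expect_equal(unclass(judgment_matrix(rep(1, 3))), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(unclass(judgment_matrix(9, n = 2)), rbind(c(1, 9), c(1 / 9, 1)),
    ignore_attr = TRUE
  )

  # fraction strings parse to exact values, not their rounded displays
  m2 <- judgment_matrix(c("1/3", "1/5", "2"))
  expect_equal(m2[1, 2], 1 / 3)
  expect_equal(m2[2, 1], 3)
})

test_that("reciprocity and unit diagonal hold for random upper triangles", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    m <- judgment_matrix(random_saaty_upper(n), n = n)
    expect_equal(diag(m), rep(1, n))
    expect_true(all(abs(unclass(m) * t(unclass(m)) - 1) < 1e-12))
  }
})

test_that("invalid judgments are rejected with informative errors", {
  expect_error(judgment_matrix(c(2, 5)), class = "coldstress_error_configuration")
  expect_error(judgment_matrix(c(1.5, 2, 3)), class = "coldstress_error_validation")
  expect_error(judgment_matrix(c(10, 2, 3)), class = "coldstress_error_validation")
  expect_error(judgment_matrix(rep(2, 45), n = 10 + 1), class = "coldstress_error_unsupported_order")
  expect_error(random_index(11), class = "coldstress_error_unsupported_order")
  # full-matrix path catches broken reciprocity
  bad <- rbind(c(1, 2, 5), c(0.4, 1, 3), c(0.2, 1 / 3, 1))
  expect_error(as_judgment_matrix(bad), class = "coldstress_error_validation")
})

test_that("column-normalization weights match the published expert panel", {
  em <- expert_matrices()
  expect_equal(round(local_weights(em$first_level)$weight, 2), c(0.62, 0.22, 0.16))
  expect_equal(local_weights(judgment_matrix(rep(1, 6), n = 4))$weight, rep(0.25, 4))
})

test_that("consistent matrices built from weights are recovered exactly", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:9, 1)
    w <- stats::runif(n, 0.05, 1)
    w <- w / sum(w)
    m <- consistent_matrix(w)
    expect_lt(max(abs(local_weights(m)$weight - w)), 1e-9)
    expect_lt(abs(lambda_max(m) - n), 1e-9)
    cons <- consistency(m)
    expect_lt(abs(cons$cr), 1e-9)
    expect_true(cons$acceptable)
  }
})

test_that("lambda_max matches a hand evaluation of (Aw)_i / w_i", {
  em <- expert_matrices()
  # independent hand oracle: recompute with bare linear algebra
  hand <- function(m) {
    w <- rowSums(apply(unclass(m), 2, function(col) col / sum(col)))
    w <- w / sum(w)
    mean((unclass(m) %*% w) / w)
  }
  expect_equal(lambda_max(em$environmental), hand(em$environmental), tolerance = 1e-12)
  expect_equal(lambda_max(em$environmental), 3.0037, tolerance = 1e-4)
  expect_equal(lambda_max(em$behavioral), 4.2419, tolerance = 1e-4)
})

test_that("consistency ratios reproduce the published quartet at 3 dp", {
  em <- expert_matrices()
  crs <- vapply(
    em[c("environmental", "physiological", "behavioral", "first_level")],
    function(m) consistency(m)$cr, numeric(1)
  )
  expect_equal(round(unname(crs), 3), c(0.003, 0.026, 0.090, 0.094))
  expect_true(all(vapply(em, function(m) consistency(m)$acceptable, logical(1))))
})

test_that("CR threshold is strict and low orders are always acceptable", {
  expect_equal(consistency(judgment_matrix(7, n = 2))$cr, 0)
  expect_true(consistency(judgment_matrix(7, n = 2))$acceptable)
  # a deliberately contradictory 3x3 matrix fails the check
  bad <- judgment_matrix(c(9, "1/9", 9))
  expect_false(consistency(bad)$acceptable)
})

test_that("principal-eigenvector weights agree closely for near-consistent matrices", {
  em <- expert_matrices()
  expect_equal(
    principal_weights(em$environmental)$weight,
    local_weights(em$environmental)$weight,
    tolerance = 0.01
  )
})
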