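test_that("the worked example classifies as mild cold stress end-to-end", {
  model <- worked_example_model()
  rec <- read_records(system.file("extdata", "example_records.csv", package = "coldstress"))
  res <- fce_evaluate(rec, model)
  expect_equal(res$level_index, 2L)
  expect_equal(res$level, "mild")
  expect_equal(round(res$none, 2), 0.35)
  v <- res$detail[[1]]$v
  expect_equal(round(unname(v), 2), c(0.15, 0.27, 0.01, 0, 0))
})

test_that("one-hot expert scoring forces the classified level", {
  for (k in 1:5) {
    one_hot <- function(n) {
      e <- matrix(0, n, 5)
      e[, k] <- 1
      e
    }
    model <- fce_model(
      c(0.5, 0.3, 0.2),
      list(environmental = c(0.5, 0.3, 0.2), physiological = rep(0.25, 4), behavioral = rep(0.25, 4)),
      membership = list(
        environmental = one_hot(3), physiological = one_hot(4), behavioral = one_hot(4)
      ),
      mode = "standard"
    )
    res <- fce_evaluate(data.frame(calf_id = "x"), model)
    expect_equal(res$level_index, as.integer(k))
  }
})

test_that("paper and standard weight modes agree on the classification", {
  wx <- worked_example()
  memb <- list(environmental = wx$e1, physiological = wx$e2, behavioral = wx$e3)
  paper <- fce_model(
    wx$w_first,
    list(environmental = wx$w1, physiological = wx$w2, behavioral = wx$w3),
    membership = memb, mode = "global"
  )
  # standard mode: within-group weights renormalized to sum 1
  standard <- fce_model(
    wx$w_first,
    list(
      environmental = wx$w1 / sum(wx$w1),
      physiological = wx$w2 / sum(wx$w2),
      behavioral = wx$w3 / sum(wx$w3)
    ),
    membership = memb, mode = "standard"
  )
  rec <- data.frame(calf_id = "nov09")
  r1 <- fce_evaluate(rec, paper)
  r2 <- fce_evaluate(rec, standard)
  expect_equal(r1$level_index, r2$level_index)
  # standard mode yields an aggregate already summing to 1
  expect_lt(abs(sum(r2$detail[[1]]$v) - 1), 1e-9)
})

test_that("evaluation is deterministic and audit intermediates are returned", {
  model <- worked_example_model()
  rec <- read_records(system.file("extdata", "example_records.csv", package = "coldstress"))
  r1 <- fce_evaluate(rec, model)
  r2 <- fce_evaluate(rec, model)
  expect_identical(r1, r2)
  d <- r1$detail[[1]]
  expect_named(d, c("b", "v", "v_norm"))
  expect_equal(dim(d$b), c(3L, 5L))
  expect_s3_class(plot_fce_results(r1), "ggplot")
})

test_that("hierarchy-derived models evaluate generated cohorts without error", {
  h <- expert_hierarchy()
  model <- fce_model_from_hierarchy(h, mode = "global")
  rec <- simulate_cohort(n_per_group = 2, n_days = 10, seed = 99)
  res <- fce_evaluate(rec, model)
  expect_equal(nrow(res), nrow(rec))
  expect_true(all(res$level_index %in% 1:5))

  # colder configured winters raise mean severity (seed-averaged)
  sev_at <- function(range) {
    mean(vapply(1:5, function(s) {
      rec <- simulate_cohort(
        n_per_group = 2, n_days = 8, seed = s,
        config = cohort_config(temp_outdoor_range = range)
      )
      mean(fce_evaluate(rec[rec$group == "outdoor", ], model)$level_index)
    }, numeric(1)))
  }
  expect_gt(sev_at(c(-26, -14)), sev_at(c(-7, 1.21)))
})

test_that("monotonicity: shifting membership mass toward severe levels never lowers the verdict", {
  wx <- worked_example()
  model0 <- worked_example_model()
  rec <- data.frame(calf_id = "x")
  base_idx <- fce_evaluate(rec, model0)$level_index
  # move the temperature row's mass one level up in severity
  e1_shift <- wx$e1
  e1_shift[1, ] <- c(0, 0, 1, 0, 0)
  model1 <- fce_model(
    wx$w_first,
    list(environmental = wx$w1, physiological = wx$w2, behavioral = wx$w3),
    membership = list(environmental = e1_shift, physiological = wx$e2, behavioral = wx$e3),
    mode = "global"
  )
  expect_gte(fce_evaluate(rec, model1)$level_index, base_idx)
})
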