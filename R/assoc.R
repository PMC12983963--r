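# Association and group-comparison statistics: tie-corrected Kendall rank
# correlation (tau-b) and Table-style two-group summaries with a single
# pooled SEM column, the animal-science reporting convention.

#' Kendall's tau-b rank correlation with tie correction
#'
#' Computes `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where C and D count
#' concordant and discordant pairs, `n0 = n(n-1)/2`, and `n1`, `n2` are the
#' tied-pair counts in each series. The two-sided p-value uses the normal
#' approximation with the tie-corrected variance of C - D.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`, neither constant.
#' @return A one-row tibble: `tau`, `statistic` (C - D), `z`, `p`, `n`.
#' @examples
#' kendall_tau_b(1:5, c(2, 1, 4, 3, 5))
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.", class = "coldstress_error_shape")
  }
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 2) {
    rlang::abort("At least two complete pairs are required.",
      class = "coldstress_error_insufficient_data"
    )
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::abort("tau-b is undefined for a constant series.",
      class = "coldstress_error_degenerate"
    )
  }
  xs <- sign(outer(x, x, "-"))
  ys <- sign(outer(y, y, "-"))
  ut <- upper.tri(xs)
  s <- sum(xs[ut] * ys[ut]) # C - D

  tx <- table(x)
  ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - n1) * (n0 - n2))

  # tie-corrected variance of C - D (normal approximation)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else {
    0
  }
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- s / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))

  tibble::tibble(tau = tau, statistic = s, z = z, p = p, n = n)
}

#' Rank association of several variables with one reference column
#'
#' Convenience wrapper mapping [kendall_tau_b()] over columns of a record
#' table, e.g. behavior variables against a THI category.
#'
#' @param data A data frame.
#' @param vars Character vector of column names to correlate.
#' @param with Name of the reference column.
#' @return A tibble with one row per variable: `variable`, `tau`, `z`, `p`,
#'   `n`.
#' @export
associate <- function(data, vars, with) {
  missing <- setdiff(c(vars, with), names(data))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Columns not found: %s.", paste(missing, collapse = ", ")),
      class = "coldstress_error_schema"
    )
  }
  purrr::map_dfr(stats::setNames(vars, vars), function(v) {
    kendall_tau_b(data[[v]], data[[with]])[, c("tau", "z", "p", "n")]
  }, .id = "variable")
}

#' Two-group summary table with pooled SEM and significance letters
#'
#' For each variable, reports the group means, a single pooled standard
#' error of the mean, the two-sided t-test p-value, and a/b significance
#' letters (letters differ exactly when p < 0.05, the larger mean taking
#' "a"). The pooled SEM is `s_p * sqrt((1/n1 + 1/n2) / 2)` with `s_p` the
#' pooled standard deviation, i.e. `s_p / sqrt(n)` for balanced groups --
#' the single-SEM column convention of animal-science tables.
#'
#' @param data Data frame in wide per-observation format with a group
#'   column.
#' @param variables Character vector of numeric columns to summarize.
#' @param group_col Name of the two-level group column.
#' @param welch Use Welch's t-test instead of Student's pooled-variance
#'   test.
#' @param per_group_sem Also report each group's own SEM.
#' @return A tibble with one row per variable: `variable`,
#'   `mean_<group>` for each group, `sem`, `p`, `letter_<group>` for each
#'   group (and `sem_<group>` when `per_group_sem`).
#' @export
two_group_table <- function(data, variables, group_col = "group",
                            welch = FALSE, per_group_sem = FALSE) {
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) {
    rlang::abort("Exactly two group labels are required.", class = "coldstress_error_validation")
  }
  labs <- levels(g)
  purrr::map_dfr(stats::setNames(variables, variables), function(v) {
    x1 <- data[[v]][g == labs[1]]
    x2 <- data[[v]][g == labs[2]]
    n1 <- sum(!is.na(x1))
    n2 <- sum(!is.na(x2))
    if (n1 < 2 || n2 < 2) {
      rlang::abort(
        sprintf("Variable '%s' needs at least 2 observations per group.", v),
        class = "coldstress_error_insufficient_data"
      )
    }
    m1 <- mean(x1, na.rm = TRUE)
    m2 <- mean(x2, na.rm = TRUE)
    sp2 <- ((n1 - 1) * stats::var(x1, na.rm = TRUE) + (n2 - 1) * stats::var(x2, na.rm = TRUE)) /
      (n1 + n2 - 2)
    sem <- sqrt(sp2 * (1 / n1 + 1 / n2) / 2)
    p <- if (isTRUE(all.equal(c(x1, x2), rep(m1, n1 + n2), tolerance = 1e-12))) {
      1 # identical constant groups: no evidence of difference
    } else {
      stats::t.test(x1, x2, var.equal = !welch)$p.value
    }
    letters <- if (p < 0.05) {
      if (m1 >= m2) c("a", "b") else c("b", "a")
    } else {
      c("a", "a")
    }
    out <- tibble::tibble(m1, m2, sem = sem, p = p, l1 = letters[1], l2 = letters[2])
    names(out)[c(1, 2, 5, 6)] <- c(
      paste0("mean_", labs), paste0("letter_", labs)
    )
    if (per_group_sem) {
      out[[paste0("sem_", labs[1])]] <- stats::sd(x1, na.rm = TRUE) / sqrt(n1)
      out[[paste0("sem_", labs[2])]] <- stats::sd(x2, na.rm = TRUE) / sqrt(n2)
    }
    out
  }, .id = "variable")
}
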