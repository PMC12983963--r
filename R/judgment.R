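# Analytic-hierarchy-process core: positive reciprocal judgment matrices on
# Saaty's 1-9 scale, column-normalization weights, and the CI/CR consistency
# check against the tabulated random index.

# Random index for matrix orders 1..10; larger orders are unsupported.
.RI_TABLE <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Random consistency index
#'
#' Tabulated expectation of the consistency index for random reciprocal
#' matrices of a given order, used as the denominator of the consistency
#' ratio. Defined for orders 1 through 10.
#'
#' @param n Matrix order, an integer in `[1, 10]`.
#' @return A single number (0 for `n <= 2`).
#' @export
random_index <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n)) {
    rlang::abort("`n` must be a single integer.", class = "coldstress_error_validation")
  }
  if (n < 1 || n > 10) {
    rlang::abort(
      sprintf("Random index is tabulated only for orders 1..10 (got %d).", as.integer(n)),
      class = "coldstress_error_unsupported_order"
    )
  }
  .RI_TABLE[n]
}

# Parse one pairwise judgment: a number, or a string fraction like "1/3".
parse_judgment <- function(x) {
  if (is.character(x)) {
    x <- vapply(x, function(s) {
      s <- trimws(s)
      if (grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", s)) {
        parts <- as.numeric(strsplit(s, "/")[[1]])
        parts[1] / parts[2]
      } else {
        suppressWarnings(as.numeric(s))
      }
    }, numeric(1))
  }
  as.numeric(x)
}

# TRUE when v is (within tolerance) an integer 1..9 or the reciprocal of one.
on_saaty_scale <- function(v, tol = 1e-9) {
  ok_int <- vapply(v, function(x) any(abs(x - 1:9) < tol), logical(1))
  ok_rec <- vapply(v, function(x) any(abs(x - 1 / (1:9)) < tol), logical(1))
  ok_int | ok_rec
}

#' Build a judgment matrix from its upper triangle
#'
#' Completes a pairwise-comparison matrix from the above-diagonal judgments:
#' the diagonal is set to 1 and every below-diagonal entry to the exact
#' reciprocal of its mirror (`a_ji = 1/a_ij`). Rounded decimal displays of
#' reciprocals (0.33 for 1/3 and the like) are never used internally;
#' reciprocals are recomputed exactly from the upper triangle.
#'
#' @param upper Above-diagonal entries in row-major order, i.e.
#'   (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). Numeric, or strings such
#'   as `"1/3"` which are parsed as exact fractions. Each value must be an
#'   integer 1..9 or the reciprocal of one (Saaty's scale).
#' @param n Matrix order (2..10). Inferred from `length(upper)` when omitted.
#' @param labels Optional character vector of indicator identifiers.
#' @return A `judgment_matrix`: a numeric matrix with unit diagonal and exact
#'   reciprocal symmetry, carrying its labels as dimnames.
#' @examples
#' judgment_matrix(c(2, 5, 3), labels = c("temperature", "humidity", "wind"))
#' @export
judgment_matrix <- function(upper, n = NULL, labels = NULL) {
  upper <- parse_judgment(upper)
  if (anyNA(upper)) {
    rlang::abort("Judgment values must be numeric or fractions like \"1/3\".",
      class = "coldstress_error_validation"
    )
  }
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * length(upper))) / 2
    if (n != round(n)) {
      rlang::abort(
        sprintf("%d upper-triangle entries do not form a square matrix.", length(upper)),
        class = "coldstress_error_configuration"
      )
    }
    n <- as.integer(n)
  }
  if (n < 2 || n > 10) {
    rlang::abort("Matrix order must be in [2, 10].", class = "coldstress_error_unsupported_order")
  }
  need <- n * (n - 1L) / 2L
  if (length(upper) != need) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    missing_k <- if (length(upper) < need) seq(length(upper) + 1L, need) else integer()
    pairs <- paste(sprintf("(%d,%d)", idx[missing_k, 1], idx[missing_k, 2]), collapse = ", ")
    rlang::abort(
      sprintf(
        "Expected %d upper-triangle entries for order %d, got %d%s.",
        need, n, length(upper),
        if (nzchar(pairs)) paste0("; missing pairs ", pairs) else ""
      ),
      class = "coldstress_error_configuration"
    )
  }
  bad <- !on_saaty_scale(upper)
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "Judgment value(s) %s are not on the 1-9 scale or its reciprocals.",
        paste(format(upper[bad]), collapse = ", ")
      ),
      class = "coldstress_error_validation"
    )
  }
  m <- diag(n)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- upper[k]
      m[j, i] <- 1 / upper[k]
      k <- k + 1L
    }
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    dimnames(m) <- list(labels, labels)
  }
  class(m) <- c("judgment_matrix", class(m))
  m
}

#' Validate a full pairwise-comparison matrix
#'
#' Checks the defining properties (unit diagonal, `a_ij * a_ji = 1`, positive
#' entries) and returns the matrix re-completed from its upper triangle so
#' reciprocals are exact. Unlike [judgment_matrix()], which guards the
#' elicitation path, this accepts any positive reciprocal matrix -- e.g. a
#' perfectly consistent matrix `a_ij = w_i / w_j` whose ratios fall off the
#' discrete 1-9 scale.
#'
#' @param m A square numeric matrix.
#' @param labels Optional indicator identifiers (defaults to rownames).
#' @param tol Reciprocity tolerance for the supplied entries; entries are
#'   replaced by exact reciprocals on success.
#' @return A `judgment_matrix`.
#' @export
as_judgment_matrix <- function(m, labels = NULL, tol = 1e-6) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m)) {
    rlang::abort("Judgment matrix must be square.", class = "coldstress_error_validation")
  }
  if (any(m <= 0)) {
    rlang::abort("Judgment matrix entries must be positive.", class = "coldstress_error_validation")
  }
  if (any(abs(diag(m) - 1) > tol)) {
    rlang::abort("Judgment matrix diagonal must be 1.", class = "coldstress_error_validation")
  }
  recip <- m * t(m)
  if (any(abs(recip - 1) > tol)) {
    rlang::abort("Judgment matrix is not reciprocal (a_ij * a_ji != 1).",
      class = "coldstress_error_validation"
    )
  }
  if (is.null(labels)) labels <- rownames(m)
  out <- diag(n)
  ut <- upper.tri(out)
  out[ut] <- m[ut]
  out[lower.tri(out)] <- t(1 / out)[lower.tri(out)]
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    dimnames(out) <- list(labels, labels)
  }
  class(out) <- c("judgment_matrix", class(out))
  out
}

#' @export
print.judgment_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Judgment matrix (order %d)\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# Column-normalization weights as a bare numeric vector (internal fast path).
col_norm_weights <- function(m) {
  w <- rowSums(sweep(m, 2, colSums(m), "/"))
  w / sum(w)
}

#' Local priority weights of a judgment matrix
#'
#' Normalizes each column of the matrix to sum 1, sums the normalized columns
#' by row, and normalizes the resulting vector. This column-normalization
#' (arithmetic-mean) estimator is the default weighting method throughout the
#' package; [principal_weights()] offers the eigenvector alternative as a
#' cross-check.
#'
#' @param m A `judgment_matrix` (or any positive reciprocal matrix).
#' @return A tibble with columns `indicator` and `weight`; weights sum to 1.
#' @examples
#' local_weights(judgment_matrix(c(4, 3, 2), labels = c("B1", "B2", "B3")))
#' @export
local_weights <- function(m) {
  if (any(m <= 0)) {
    rlang::abort("Judgment matrix entries must be positive.", class = "coldstress_error_validation")
  }
  w <- col_norm_weights(m)
  tibble::tibble(
    indicator = if (!is.null(rownames(m))) rownames(m) else paste0("i", seq_along(w)),
    weight = unname(w)
  )
}

#' Principal-eigenvector weights (cross-check utility)
#'
#' Weights from the dominant eigenvector of the judgment matrix. Provided for
#' comparison with the default column-normalization method, not used by the
#' pipeline.
#'
#' @inheritParams local_weights
#' @return A tibble with columns `indicator` and `weight`.
#' @export
principal_weights <- function(m) {
  e <- eigen(unclass(m))
  k <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, k]))
  tibble::tibble(
    indicator = if (!is.null(rownames(m))) rownames(m) else paste0("i", seq_len(nrow(m))),
    weight = v / sum(v)
  )
}

#' Maximum-eigenvalue estimate for the consistency check
#'
#' The standard AHP estimator: the mean over rows of `(A w)_i / w_i`, with `w`
#' the column-normalization weights (or any supplied weight vector). Equal to
#' the true principal eigenvalue when the matrix is perfectly consistent.
#'
#' @param m A `judgment_matrix`.
#' @param w Optional weight vector; defaults to the column-normalization
#'   weights of `m`.
#' @return A single number, at least `nrow(m)` up to rounding error.
#' @export
lambda_max <- function(m, w = NULL) {
  if (is.null(w)) w <- col_norm_weights(m)
  if (is.data.frame(w)) w <- w$weight
  if (any(w <= 0)) {
    rlang::abort("Weights must be strictly positive.", class = "coldstress_error_arithmetic")
  }
  mean(as.vector(unclass(m) %*% w) / w)
}

#' Consistency check of a judgment matrix
#'
#' Computes `CI = (lambda_max - n) / (n - 1)` and the consistency ratio
#' `CR = CI / RI(n)`; the judgment matrix is acceptable when `CR < 0.10`
#' (strict). For orders 1 and 2 the random index is 0 and CR is defined as 0,
#' so such matrices are always acceptable.
#'
#' @param m A `judgment_matrix` of order at most 10.
#' @return A one-row tibble: `order`, `lambda_max`, `ci`, `ri`, `cr`,
#'   `acceptable`.
#' @examples
#' consistency(judgment_matrix(c(2, 5, 3)))
#' @export
consistency <- function(m) {
  n <- nrow(m)
  ri <- random_index(n)
  w <- col_norm_weights(m)
  lm <- lambda_max(m, w)
  ci <- (lm - n) / (n - 1)
  cr <- if (ri == 0) 0 else ci / ri
  tibble::tibble(
    order = as.integer(n),
    lambda_max = lm,
    ci = ci,
    ri = ri,
    cr = cr,
    acceptable = cr < 0.10
  )
}
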