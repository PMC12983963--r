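# Two-group PLS-DA fitted by NIPALS on autoscaled features, with R2Y,
# K-fold cross-validated Q2, and VIP (variable importance in projection)
# scores. Written in-house because VIP-based screening is the point of the
# downstream module; mixOmics serves only as an independent cross-check in
# the test suite.

# Core NIPALS PLS1 on a pre-scaled X and centered y.
pls1_nipals <- function(x, y, ncomp) {
  n <- nrow(x)
  p <- ncol(x)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp)
  b_vec <- numeric(ncomp)
  ssy <- numeric(ncomp)
  xa <- x
  ya <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(xa, ya)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      rlang::abort("Residual X carries no covariance with the response; reduce `ncomp`.",
        class = "coldstress_error_rank"
      )
    }
    w <- w / wn
    tt <- as.vector(xa %*% w)
    t2 <- sum(tt^2)
    pp <- crossprod(xa, tt) / t2
    bb <- sum(ya * tt) / t2
    xa <- xa - tcrossprod(tt, pp)
    ya <- ya - bb * tt
    w_mat[, a] <- w
    p_mat[, a] <- pp
    t_mat[, a] <- tt
    b_vec[a] <- bb
    ssy[a] <- bb^2 * t2 # response sum of squares explained by component a
  }
  list(w = w_mat, p = p_mat, t = t_mat, b = b_vec, ssy = ssy, y_res = ya)
}

# Regression coefficients of the fitted PLS1 model on the scaled X scale.
pls1_coef <- function(fit) {
  fit$w %*% solve(crossprod(fit$p, fit$w), fit$b)
}

scale_train <- function(x, center = TRUE, scale = TRUE) {
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  sdv <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  sdv[sdv < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, mu, "-"), 2, sdv, "/"), mu = mu, sd = sdv)
}

#' Fit a two-group PLS-DA model
#'
#' Partial least-squares discriminant analysis for a samples-by-features
#' table with a two-level group column. Features are autoscaled (centered,
#' unit variance), the response is the centered group indicator, and
#' components are extracted by NIPALS. `R2Y` is the cumulative fraction of
#' response variance explained; `Q2` is its cross-validated counterpart from
#' stratified K-fold prediction (refitting the scaling and the model inside
#' each fold). Fold assignment is random: set the RNG seed for reproducible
#' `Q2`.
#'
#' @param data Wide data frame: one row per sample, feature columns plus a
#'   group column.
#' @param group_col Name of the two-level group column.
#' @param ncomp Number of components (default 2, matching the usual 2-D
#'   score plot); must not exceed `n - 1` or the feature count.
#' @param scale Autoscale features (default `TRUE`).
#' @param cv_folds Folds for Q2 (default 7), capped at the sample count.
#' @return A `plsda` object: scores, loadings, weights, per-component
#'   explained response sums of squares, `r2y`, `q2`, group labels.
#' @export
plsda <- function(data, group_col = "group", ncomp = 2L, scale = TRUE, cv_folds = 7L) {
  data <- as.data.frame(data)
  if (!group_col %in% names(data)) {
    rlang::abort(sprintf("Group column '%s' not found.", group_col),
      class = "coldstress_error_schema"
    )
  }
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) {
    rlang::abort("PLS-DA requires exactly two group labels.", class = "coldstress_error_label")
  }
  if (any(table(g) < 3L)) {
    rlang::abort("At least 3 samples per group are required.",
      class = "coldstress_error_insufficient_data"
    )
  }
  feat <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], group_col)
  if (length(feat) == 0L) {
    rlang::abort("No numeric feature columns found.", class = "coldstress_error_schema")
  }
  x <- as.matrix(data[, feat, drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (ncomp >= n || ncomp > ncol(x)) {
    rlang::abort(
      sprintf("ncomp = %d exceeds what %d samples x %d features support.", ncomp, n, ncol(x)),
      class = "coldstress_error_rank"
    )
  }
  y01 <- as.numeric(g) - 1
  y <- y01 - mean(y01)
  sc <- scale_train(x, scale = scale)
  fit <- pls1_nipals(sc$x, y, ncomp)
  ssy_tot <- sum(y^2)
  r2y_cum <- cumsum(fit$ssy) / ssy_tot

  # stratified K-fold cross-validated Q2
  k <- min(cv_folds, n)
  fold <- integer(n)
  for (lev in levels(g)) {
    idx <- sample(which(g == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  press <- 0
  tss <- 0
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test) || length(unique(g[!test])) < 2L) next
    sc_tr <- scale_train(x[!test, , drop = FALSE], scale = scale)
    y_tr01 <- y01[!test]
    y_tr <- y_tr01 - mean(y_tr01)
    nc <- min(ncomp, sum(!test) - 1L)
    fit_tr <- pls1_nipals(sc_tr$x, y_tr, nc)
    beta <- pls1_coef(fit_tr)
    x_te <- sweep(sweep(x[test, , drop = FALSE], 2, sc_tr$mu, "-"), 2, sc_tr$sd, "/")
    yhat <- as.vector(x_te %*% beta) + mean(y_tr01)
    press <- press + sum((y01[test] - yhat)^2)
    tss <- tss + sum((y01[test] - mean(y_tr01))^2)
  }
  q2 <- 1 - press / tss

  structure(
    list(
      features = feat,
      groups = levels(g),
      group = g,
      ncomp = as.integer(ncomp),
      scores = fit$t,
      weights = fit$w,
      loadings = fit$p,
      y_loadings = fit$b,
      ssy = fit$ssy,
      r2y_cum = r2y_cum,
      r2y = r2y_cum[ncomp],
      q2 = q2,
      n = n,
      scale = scale
    ),
    class = "plsda"
  )
}

#' Variable importance in projection
#'
#' The standard VIP score
#' `vip_j = sqrt(p * sum_a(ssy_a * w_aj^2) / sum_a(ssy_a))` with `p` the
#' number of features. Because each weight vector has unit norm, the mean
#' squared VIP is exactly 1 (`sum(vip^2) = p`); a single-feature model
#' therefore has VIP 1.
#'
#' @param fit A fitted `plsda` model.
#' @return Named numeric vector of VIP scores, one per feature.
#' @export
vip <- function(fit) {
  if (!inherits(fit, "plsda")) {
    rlang::abort("`fit` must be a fitted plsda model.", class = "coldstress_error_state")
  }
  p <- length(fit$features)
  num <- as.vector(fit$weights^2 %*% fit$ssy)
  stats::setNames(sqrt(p * num / sum(fit$ssy)), fit$features)
}

#' @rdname plsda
#' @param x,object A `plsda` object.
#' @param ... Unused.
#' @export
tidy.plsda <- function(x, ...) {
  out <- tibble::tibble(feature = x$features, vip = unname(vip(x)))
  for (a in seq_len(x$ncomp)) {
    out[[paste0("weight_", a)]] <- x$weights[, a]
    out[[paste0("loading_", a)]] <- x$loadings[, a]
  }
  out
}

#' @rdname plsda
#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp, r2y = x$r2y, q2 = x$q2,
    n = x$n, n_features = length(x$features)
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf(
    "PLS-DA: %d samples (%s), %d features, %d component(s)\n",
    x$n, paste(x$groups, collapse = " vs "), length(x$features), x$ncomp
  ))
  cat(sprintf("R2Y = %.4f, Q2 = %.4f\n", x$r2y, x$q2))
  invisible(x)
}

#' Score plot of a PLS-DA fit
#'
#' @param object A `plsda` object with at least 2 components.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plsda <- function(object, ...) {
  stopifnot(object$ncomp >= 2L)
  d <- tibble::tibble(
    t1 = object$scores[, 1], t2 = object$scores[, 2], group = object$group
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t1, y = .data$t2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
}
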