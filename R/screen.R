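# Differential-metabolite screening: a feature is called differential when
# it simultaneously satisfies VIP >= 1, fold-change ratio >= 1.5 or
# <= 1/1.5, and p <= 0.05 (all comparisons inclusive).

#' Apply the three screening criteria to precomputed statistics
#'
#' Pure decision rule, usable on statistics from any source (e.g. a
#' published differential-metabolite table): a feature passes when
#' `vip >= vip_min` AND (`ratio >= fc_min` OR `ratio <= 1/fc_min`) AND
#' `p <= p_max`, with regulation "up" for passing features with ratio > 1
#' and "down" for ratio < 1.
#'
#' @param ratio Treatment/control mean abundance ratio(s).
#' @param p Two-sided p-value(s).
#' @param vip VIP score(s).
#' @param vip_min,fc_min,p_max Inclusive thresholds (defaults 1, 1.5, 0.05).
#' @return A tibble `ratio`, `p`, `vip`, `passes`, `regulation`
#'   (up/down/none).
#' @examples
#' screen_calls(ratio = 0.29, p = 0.003, vip = 3.285)
#' @export
screen_calls <- function(ratio, p, vip, vip_min = 1, fc_min = 1.5, p_max = 0.05) {
  passes <- (vip >= vip_min) & (ratio >= fc_min | ratio <= 1 / fc_min) & (p <= p_max)
  regulation <- dplyr::case_when(
    passes & ratio > 1 ~ "up",
    passes & ratio < 1 ~ "down",
    TRUE ~ "none"
  )
  tibble::tibble(ratio = ratio, p = p, vip = vip, passes = passes, regulation = regulation)
}

#' Screen a metabolite table for differential features
#'
#' Fits a PLS-DA model to the full table for VIP scores, computes the
#' per-feature treatment/control mean ratio on the raw scale and a
#' per-feature two-sided Welch t-test (on log2 abundances by default), and
#' applies the three-criterion rule of [screen_calls()].
#'
#' @param data Wide data frame: one row per sample, non-negative feature
#'   columns plus a two-level group column.
#' @param group_col Name of the group column.
#' @param treatment The group label treated as numerator of the ratio;
#'   defaults to the last label in sort order (so "outdoor" over "indoor").
#' @param vip_min,fc_min,p_max Inclusive thresholds (defaults 1, 1.5, 0.05).
#' @param log_transform Run the t-test on log2 abundances (default) or on
#'   the raw scale.
#' @param ncomp Components for the PLS-DA VIP model (default 2).
#' @return A tibble with one row per feature -- `feature`, `ratio`, `p`,
#'   `vip`, `passes`, `regulation` -- ordered as in the input; the pass and
#'   up/down tallies are attached as attribute `"tally"`.
#' @export
screen_metabolites <- function(data, group_col = "group", treatment = NULL,
                               vip_min = 1, fc_min = 1.5, p_max = 0.05,
                               log_transform = TRUE, ncomp = 2L) {
  data <- as.data.frame(data)
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) {
    rlang::abort("Exactly two group labels are required.", class = "coldstress_error_label")
  }
  if (is.null(treatment)) treatment <- sort(levels(g))[2]
  if (!treatment %in% levels(g)) {
    rlang::abort(sprintf("Treatment label '%s' not present.", treatment),
      class = "coldstress_error_label"
    )
  }
  control <- setdiff(levels(g), treatment)
  feat <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], group_col)
  x <- as.matrix(data[, feat, drop = FALSE])
  if (any(x < 0)) {
    rlang::abort("Abundances must be non-negative.", class = "coldstress_error_validation")
  }

  fit <- plsda(data, group_col = group_col, ncomp = ncomp)
  vips <- vip(fit)

  trt <- g == treatment
  ratio <- colMeans(x[trt, , drop = FALSE]) / colMeans(x[!trt, , drop = FALSE])
  xt <- if (log_transform) {
    if (any(x <= 0)) {
      rlang::abort("log2 transform requires strictly positive abundances.",
        class = "coldstress_error_domain"
      )
    }
    log2(x)
  } else {
    x
  }
  p <- apply(xt, 2, function(col) stats::t.test(col[trt], col[!trt])$p.value)

  calls <- screen_calls(unname(ratio), unname(p), unname(vips),
    vip_min = vip_min, fc_min = fc_min, p_max = p_max
  )
  out <- dplyr::bind_cols(tibble::tibble(feature = feat), calls)
  attr(out, "tally") <- c(
    n_pass = sum(out$passes),
    n_up = sum(out$regulation == "up"),
    n_down = sum(out$regulation == "down")
  )
  attr(out, "groups") <- c(treatment = treatment, control = control)
  out
}

#' Volcano-style plot of a screening result
#'
#' @param object Tibble from [screen_metabolites()].
#' @param ... Unused.
#' @return A ggplot object (log2 ratio vs -log10 p, coloured by call).
#' @export
plot_screen <- function(object, ...) {
  d <- dplyr::mutate(object,
    log2_ratio = log2(.data$ratio),
    neglog_p = -log10(pmax(.data$p, 1e-300))
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$log2_ratio, y = .data$neglog_p, colour = .data$regulation)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log2 ratio (treatment/control)", y = "-log10 p", colour = "call") +
    ggplot2::theme_minimal()
}
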