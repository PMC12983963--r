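# Fuzzy comprehensive evaluation: membership matrices per factor group are
# composed with indicator weights, the three group vectors are aggregated
# with the first-level weights, and the normalized result is classified on
# the five-level cold-stress scale by the maximum-membership principle.

#' The five-level cold-stress evaluation set
#'
#' Severity-ordered labels for the evaluation set V1..V5.
#'
#' @return Character vector `none < mild < moderate < severe < extreme`.
#' @export
cold_stress_levels <- function() {
  c("none", "mild", "moderate", "severe", "extreme")
}

# Indicator membership of each factor group in the calf daily-record schema.
.GROUP_INDICATORS <- list(
  environmental = c("temperature_c", "humidity_pct", "wind"),
  physiological = c("weight_kg", "height_cm", "diagonal_cm", "chest_cm"),
  behavioral    = c("lying_min", "standing_min", "rr_per_min", "urination_n")
)

#' Indicators observed for each factor group
#'
#' @return Named list mapping the three factor groups (environmental,
#'   physiological, behavioral) to their daily-record column names.
#' @export
group_indicators <- function() .GROUP_INDICATORS

#' Validate a fuzzy membership matrix
#'
#' A membership matrix has one row per indicator of a factor group and five
#' columns (the evaluation levels); every entry lies in `[0, 1]` and every
#' row sums to 1.
#'
#' @param x Numeric matrix (or something coercible), rows = indicators,
#'   columns = 5 levels.
#' @param indicators Optional row labels.
#' @param tol Row-sum tolerance.
#' @return The validated matrix with level column names attached.
#' @export
membership_matrix <- function(x, indicators = NULL, tol = 1e-9) {
  x <- as.matrix(x)
  if (ncol(x) != 5L) {
    rlang::abort("Membership matrix must have 5 columns (evaluation levels).",
      class = "coldstress_error_shape"
    )
  }
  if (any(x < 0 | x > 1)) {
    rlang::abort("Membership degrees must lie in [0, 1].", class = "coldstress_error_validation")
  }
  rs <- rowSums(x)
  if (any(abs(rs - 1) > tol)) {
    rlang::abort(
      sprintf("Membership rows must sum to 1 (row sums: %s).", paste(format(rs), collapse = ", ")),
      class = "coldstress_error_validation"
    )
  }
  colnames(x) <- cold_stress_levels()
  if (!is.null(indicators)) rownames(x) <- indicators
  x
}

#' Trapezoidal membership degree
#'
#' Membership of `x` in a trapezoid with feet `lf`/`rf` and shoulders
#' `ls`/`rs` (plateau of height 1 between the shoulders, linear flanks,
#' 0 outside the feet). Infinite feet/shoulders give one-sided plateaus.
#'
#' @param x Numeric vector of indicator values.
#' @param lf,ls,rs,rf Left foot, left shoulder, right shoulder, right foot
#'   (`lf <= ls <= rs <= rf`).
#' @return Membership degrees in `[0, 1]`.
#' @export
trapezoid_membership <- function(x, lf, ls, rs, rf) {
  up <- dplyr::case_when(
    is.infinite(ls) & ls < 0 ~ 1,
    x <= lf ~ 0,
    x >= ls ~ 1,
    TRUE ~ (x - lf) / (ls - lf)
  )
  down <- dplyr::case_when(
    is.infinite(rs) & rs > 0 ~ 1,
    x >= rf ~ 0,
    x <= rs ~ 1,
    TRUE ~ (rf - x) / (rf - rs)
  )
  pmin(up, down)
}

#' Build a trapezoidal membership specification from severity cutpoints
#'
#' For one indicator, converts four cutpoints partitioning the indicator's
#' axis into five severity bands into five trapezoids that overlap linearly
#' over a crossfade window of width `2 * overlap` around each cutpoint, so
#' that memberships form a partition of unity (sum to 1 at every value).
#'
#' @param indicator Indicator (record column) name.
#' @param cutpoints Four increasing values separating none/mild/moderate/
#'   severe/extreme *in severity order along the axis direction given by*
#'   `direction`.
#' @param direction `"higher"` when larger values mean more severe cold
#'   stress (e.g. lying time), `"lower"` when smaller values do (e.g. air
#'   temperature).
#' @param overlap Half-width of the linear crossfade at each cutpoint; must
#'   be smaller than half the narrowest band.
#' @param domain Length-2 numeric; values outside it are rejected at
#'   evaluation time.
#' @return A tibble with columns `indicator`, `level`, `direction`, `lf`,
#'   `ls`, `rs`, `rf`, `domain_lo`, `domain_hi` (coordinates on the
#'   severity-increasing axis).
#' @export
membership_spec <- function(indicator, cutpoints, direction = c("higher", "lower"),
                            overlap = 0, domain = c(-Inf, Inf)) {
  direction <- match.arg(direction)
  if (length(cutpoints) != 4L || is.unsorted(cutpoints, strictly = TRUE)) {
    rlang::abort("`cutpoints` must be four strictly increasing values.",
      class = "coldstress_error_configuration"
    )
  }
  if (overlap < 0 || (overlap > 0 && 2 * overlap >= min(diff(cutpoints)))) {
    rlang::abort("`overlap` must be non-negative and below half the narrowest band.",
      class = "coldstress_error_configuration"
    )
  }
  lo <- c(-Inf, cutpoints)
  hi <- c(cutpoints, Inf)
  tibble::tibble(
    indicator = indicator,
    level = cold_stress_levels(),
    direction = direction,
    lf = ifelse(is.finite(lo), lo - overlap, -Inf),
    ls = ifelse(is.finite(lo), lo + overlap, -Inf),
    rs = ifelse(is.finite(hi), hi - overlap, Inf),
    rf = ifelse(is.finite(hi), hi + overlap, Inf),
    domain_lo = domain[1],
    domain_hi = domain[2]
  )
}

#' Illustrative membership functions for all eleven indicators
#'
#' A complete trapezoidal membership specification covering the full daily
#' record schema. The cutpoints are illustrative defaults chosen to span
#' plausible winter ranges for suckling calves; they are plumbing for
#' exercising the pipeline, not elicited expert knowledge, and real
#' deployments should replace them.
#'
#' @return A membership-specification tibble (see [membership_spec()]).
#' @export
default_membership_spec <- function() {
  dplyr::bind_rows(
    membership_spec("temperature_c", c(-20, -10, 0, 10), "lower", 2, c(-60, 45)),
    membership_spec("humidity_pct", c(60, 70, 80, 90), "higher", 4, c(0, 100)),
    membership_spec("wind", c(5, 10, 20, 30), "higher", 2, c(0, 120)),
    membership_spec("weight_kg", c(33, 37, 42, 50), "lower", 1.5, c(20, 150)),
    membership_spec("height_cm", c(72, 76, 80, 85), "lower", 1.5, c(50, 120)),
    membership_spec("diagonal_cm", c(50, 55, 62, 70), "lower", 1.5, c(30, 120)),
    membership_spec("chest_cm", c(78, 82, 90, 100), "lower", 1.5, c(50, 150)),
    membership_spec("lying_min", c(900, 1000, 1100, 1250), "higher", 30, c(0, 1440)),
    membership_spec("standing_min", c(190, 340, 440, 540), "lower", 30, c(0, 1440)),
    membership_spec("rr_per_min", c(30, 34, 40, 44), "lower", 1, c(5, 120)),
    membership_spec("urination_n", c(1, 2, 3, 4), "higher", 0.4, c(0, 50))
  )
}

#' Membership matrix of one record's factor group
#'
#' Evaluates the trapezoidal memberships of every indicator of a factor
#' group at the record's values, orienting the axis by each indicator's
#' direction flag, and renormalizes each row to sum 1.
#'
#' @param record A one-row data frame (or named list) holding the group's
#'   indicator columns.
#' @param spec A membership-specification tibble, e.g.
#'   [default_membership_spec()].
#' @param group `"environmental"`, `"physiological"` or `"behavioral"`.
#' @return A membership matrix (rows = the group's indicators).
#' @export
membership_from_record <- function(record, spec, group = names(group_indicators())) {
  group <- match.arg(group)
  record <- as.list(record)
  inds <- .GROUP_INDICATORS[[group]]
  missing <- setdiff(inds, names(record))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Record is missing indicator(s): %s.", paste(missing, collapse = ", ")),
      class = "coldstress_error_schema"
    )
  }
  rows <- purrr::map(inds, function(ind) {
    s <- dplyr::filter(spec, .data$indicator == ind)
    if (nrow(s) != 5L) {
      rlang::abort(sprintf("Membership spec has no 5-level entry for '%s'.", ind),
        class = "coldstress_error_configuration"
      )
    }
    x <- as.numeric(record[[ind]])
    if (is.na(x) || x < s$domain_lo[1] || x > s$domain_hi[1]) {
      rlang::abort(
        sprintf(
          "Value %s of '%s' is outside the membership domain [%s, %s].",
          format(x), ind, format(s$domain_lo[1]), format(s$domain_hi[1])
        ),
        class = "coldstress_error_domain"
      )
    }
    # severity-increasing axis: negate when lower values are more severe
    z <- if (s$direction[1] == "lower") -x else x
    mu <- trapezoid_membership(z, s$lf, s$ls, s$rs, s$rf)
    mu / sum(mu)
  })
  membership_matrix(do.call(rbind, rows), indicators = inds)
}

#' Compose indicator weights with a membership matrix
#'
#' The fuzzy composition `w * E`. The default weighted-average operator is
#' the ordinary vector-matrix product; the max-min operator
#' `max_i min(w_i, e_ik)` is available for comparison.
#'
#' @param weights Numeric weight vector, one entry per row of `e`.
#' @param e A membership matrix.
#' @param operator `"weighted_average"` (default) or `"max_min"`.
#' @return A length-5 membership vector over the evaluation levels.
#' @examples
#' e1 <- membership_matrix(rbind(
#'   c(0, 1, 0, 0, 0), c(0, 0.9, 0.1, 0, 0), c(1, 0, 0, 0, 0)
#' ))
#' fce_compose(c(0.39, 0.11, 0.05), e1)
#' @export
fce_compose <- function(weights, e, operator = c("weighted_average", "max_min")) {
  operator <- match.arg(operator)
  e <- as.matrix(e)
  if (length(weights) != nrow(e)) {
    rlang::abort(
      sprintf("Length of weights (%d) must equal rows of E (%d).", length(weights), nrow(e)),
      class = "coldstress_error_shape"
    )
  }
  out <- switch(operator,
    weighted_average = as.vector(weights %*% e),
    max_min = apply(e, 2, function(col) max(pmin(weights, col)))
  )
  stats::setNames(out, colnames(e))
}

#' Aggregate the three group vectors into the comprehensive judgment vector
#'
#' Stacks the group evaluation vectors (B1; B2; B3) as the fuzzy relation
#' matrix of the first-level judgment and composes it with the first-level
#' weights: `V = W * B`.
#'
#' @param first_level_weights Numeric vector, one weight per group row.
#' @param group_vectors Matrix with one 5-vector per row (or list of
#'   5-vectors) in first-level order.
#' @inheritParams fce_compose
#' @return A length-5 membership vector.
#' @export
fce_aggregate <- function(first_level_weights, group_vectors,
                          operator = c("weighted_average", "max_min")) {
  if (is.list(group_vectors)) group_vectors <- do.call(rbind, group_vectors)
  b <- as.matrix(group_vectors)
  if (ncol(b) != 5L) {
    rlang::abort("Group vectors must have 5 columns.", class = "coldstress_error_shape")
  }
  if (length(first_level_weights) != nrow(b)) {
    rlang::abort("One first-level weight per group vector is required.",
      class = "coldstress_error_shape"
    )
  }
  operator <- match.arg(operator)
  colnames(b) <- cold_stress_levels()
  out <- switch(operator,
    weighted_average = as.vector(first_level_weights %*% b),
    max_min = apply(b, 2, function(col) max(pmin(first_level_weights, col)))
  )
  stats::setNames(out, colnames(b))
}

#' Normalize a membership vector to sum 1
#'
#' @param v Non-negative numeric vector, not all zero.
#' @return `v / sum(v)`.
#' @export
fce_normalize <- function(v) {
  if (any(v < 0)) {
    rlang::abort("Membership vector must be non-negative.", class = "coldstress_error_validation")
  }
  s <- sum(v)
  if (s <= 0) {
    rlang::abort("Cannot normalize an all-zero membership vector.",
      class = "coldstress_error_degenerate"
    )
  }
  v / s
}

#' Classify a membership vector by the maximum-membership principle
#'
#' Returns the evaluation level with the largest membership; exact ties are
#' broken toward the more severe level (welfare-conservative).
#'
#' @param v_norm Normalized length-5 membership vector.
#' @return A one-row tibble `level_index`, `level`, `membership`.
#' @export
fce_classify <- function(v_norm) {
  if (length(v_norm) != 5L) {
    rlang::abort("Expected a length-5 membership vector.", class = "coldstress_error_shape")
  }
  idx <- max(which(v_norm >= max(v_norm) - 1e-12))
  tibble::tibble(
    level_index = as.integer(idx),
    level = cold_stress_levels()[idx],
    membership = unname(v_norm[idx])
  )
}
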