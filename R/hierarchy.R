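# The two-level evaluation hierarchy: one first-level judgment matrix over
# the factor groups (environmental, physiological, behavioral) and one
# second-level matrix per group. Global weights are synthesized top-down:
# global(second-level node) = local(node) * local(its group).

#' Assemble an evaluation hierarchy
#'
#' Builds the two-level AHP model from a first-level judgment matrix over the
#' factor groups and one second-level judgment matrix per group, computing
#' local weights, global (total-sorting) weights and a consistency report for
#' every matrix.
#'
#' @param first_level A `judgment_matrix` whose labels name the factor groups.
#' @param groups Named list of `judgment_matrix` objects, one per first-level
#'   label, in any order; names must match the first-level labels exactly.
#' @param force If `TRUE`, a matrix failing the CR < 0.10 check only raises a
#'   warning instead of an error. Needed e.g. for panels whose elicited
#'   judgments are not fully consistent.
#' @return A `hierarchy_model` with elements `first_level`, `groups`,
#'   `weights` (tibble: indicator, group, level, local_weight, global_weight)
#'   and `consistency` (tibble with one row per matrix).
#' @examples
#' h <- hierarchy_model(
#'   judgment_matrix(c(4, 3, 2), labels = c("B1", "B2", "B3")),
#'   list(
#'     B1 = judgment_matrix(c(2, 5, 3), labels = c("b11", "b12", "b13")),
#'     B2 = judgment_matrix(c(2, 3, 3, 2, 3, 2), labels = paste0("b2", 1:4)),
#'     B3 = judgment_matrix(c(2, 2, 2, 3, 4, 2), labels = paste0("b3", 1:4))
#'   )
#' )
#' tidy(h)
#' @export
hierarchy_model <- function(first_level, groups, force = FALSE) {
  group_names <- rownames(first_level)
  if (is.null(group_names)) {
    rlang::abort("First-level judgment matrix must carry group labels.",
      class = "coldstress_error_configuration"
    )
  }
  if (!setequal(names(groups), group_names) || length(groups) != length(group_names)) {
    rlang::abort(
      sprintf(
        "Group matrices (%s) must match first-level labels (%s).",
        paste(names(groups), collapse = ", "), paste(group_names, collapse = ", ")
      ),
      class = "coldstress_error_configuration"
    )
  }
  groups <- groups[group_names]

  mats <- c(list(first_level = first_level), groups)
  cons <- purrr::map_dfr(mats, consistency, .id = "matrix")
  bad <- dplyr::filter(cons, !.data$acceptable)
  if (nrow(bad) > 0) {
    msg <- sprintf(
      "Judgment matrix consistency check failed: %s.",
      paste(sprintf("%s (CR = %.3f)", bad$matrix, bad$cr), collapse = ", ")
    )
    if (force) {
      rlang::warn(msg, class = "coldstress_warning_consistency")
    } else {
      rlang::abort(paste(msg, "Use `force = TRUE` to proceed anyway."),
        class = "coldstress_error_consistency"
      )
    }
  }

  wf <- local_weights(first_level)
  second <- purrr::map2_dfr(groups, wf$weight, function(m, gw) {
    lw <- local_weights(m)
    tibble::tibble(
      indicator = lw$indicator,
      local_weight = lw$weight,
      global_weight = lw$weight * gw
    )
  }, .id = "group")

  weights <- dplyr::bind_rows(
    tibble::tibble(
      indicator = wf$indicator, group = wf$indicator, level = 1L,
      local_weight = wf$weight, global_weight = wf$weight
    ),
    tibble::tibble(
      indicator = second$indicator, group = second$group, level = 2L,
      local_weight = second$local_weight, global_weight = second$global_weight
    )
  )

  structure(
    list(
      first_level = first_level,
      groups = groups,
      weights = weights,
      consistency = cons
    ),
    class = "hierarchy_model"
  )
}

#' Global (total-sorting) weights of a hierarchy
#'
#' @param h A `hierarchy_model`.
#' @param level `2` (default) for the second-level indicators, `1` for the
#'   factor groups, or `NULL` for both.
#' @return A tibble `indicator`, `group`, `level`, `weight`. Second-level
#'   global weights sum to 1 for any valid hierarchy.
#' @export
global_weights <- function(h, level = 2L) {
  stopifnot(inherits(h, "hierarchy_model"))
  out <- dplyr::select(h$weights, "indicator", "group", "level", weight = "global_weight")
  if (!is.null(level)) out <- dplyr::filter(out, .data$level == !!level)
  out
}

#' @rdname hierarchy_model
#' @param x,object A `hierarchy_model`.
#' @param ... Unused.
#' @export
tidy.hierarchy_model <- function(x, ...) x$weights

#' @rdname hierarchy_model
#' @export
glance.hierarchy_model <- function(x, ...) x$consistency

#' @export
print.hierarchy_model <- function(x, digits = 2, ...) {
  cat("Two-level AHP evaluation hierarchy\n")
  cat("Consistency (CR, 3 dp):",
    paste(sprintf("%s %.3f", x$consistency$matrix, x$consistency$cr), collapse = ", "), "\n"
  )
  w <- dplyr::filter(x$weights, .data$level == 2L)
  cat("Global weights (2 dp):\n")
  print(data.frame(
    indicator = w$indicator, group = w$group,
    weight = round(w$global_weight, digits)
  ), row.names = FALSE)
  invisible(x)
}

#' Plot hierarchy weights
#'
#' Bar chart of the global second-level weights, filled by factor group.
#'
#' @param object A `hierarchy_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hierarchy_model <- function(object, ...) {
  w <- dplyr::filter(object$weights, .data$level == 2L)
  ggplot2::ggplot(
    w,
    ggplot2::aes(
      x = stats::reorder(.data$indicator, -.data$global_weight),
      y = .data$global_weight, fill = .data$group
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "indicator", y = "global weight", fill = "group") +
    ggplot2::theme_minimal()
}
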