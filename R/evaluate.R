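# End-to-end evaluation: records -> membership -> composition -> aggregation
# -> normalization -> maximum-membership classification.

#' Construct a cold-stress evaluation model
#'
#' Bundles everything [fce_evaluate()] needs: the first-level weights, the
#' per-group indicator weights, and a membership source (either explicit
#' membership matrices, as in an expert-scored evaluation, or a trapezoidal
#' membership specification applied to each record's values). Explicit
#' matrices take precedence over a specification when both are given.
#'
#' Two weight modes are supported. In `"global"` mode the group compositions
#' use *global* indicator weights and the first-level weights are applied
#' again at aggregation; the double weighting is absorbed by the final
#' normalization. In `"standard"` mode both stages use local (within-group,
#' sum-1) weights and the aggregate is already normalized up to rounding.
#' Both modes classify identically on proportional vectors.
#'
#' @param first_level_weights Numeric vector of group weights, in the order
#'   of `groups`.
#' @param group_weights Named list (one numeric vector per group) of
#'   indicator weights.
#' @param membership Named list of explicit membership matrices per group,
#'   or `NULL` to use `spec`.
#' @param spec Membership-specification tibble (see [membership_spec()]);
#'   defaults to [default_membership_spec()] when no explicit matrices are
#'   supplied.
#' @param mode `"global"` or `"standard"` (see Details).
#' @param operator Composition operator, see [fce_compose()].
#' @param groups Group names; default the three standard factor groups.
#' @return An `fce_model` object.
#' @export
fce_model <- function(first_level_weights, group_weights, membership = NULL,
                      spec = NULL, mode = c("global", "standard"),
                      operator = c("weighted_average", "max_min"),
                      groups = names(group_indicators())) {
  mode <- match.arg(mode)
  operator <- match.arg(operator)
  if (length(first_level_weights) != length(groups)) {
    rlang::abort("One first-level weight per group is required.",
      class = "coldstress_error_shape"
    )
  }
  if (!setequal(names(group_weights), groups)) {
    rlang::abort("`group_weights` must be named by the factor groups.",
      class = "coldstress_error_configuration"
    )
  }
  if (!is.null(membership)) {
    if (!setequal(names(membership), groups)) {
      rlang::abort("Explicit membership matrices must be named by the factor groups.",
        class = "coldstress_error_configuration"
      )
    }
    membership <- purrr::map(membership[groups], membership_matrix)
    for (g in groups) {
      if (nrow(membership[[g]]) != length(group_weights[[g]])) {
        rlang::abort(sprintf("Membership matrix of '%s' does not match its weights.", g),
          class = "coldstress_error_shape"
        )
      }
    }
  } else if (is.null(spec)) {
    spec <- default_membership_spec()
  }
  structure(
    list(
      groups = groups,
      first_level_weights = stats::setNames(as.numeric(first_level_weights), groups),
      group_weights = group_weights[groups],
      membership = membership,
      spec = spec,
      mode = mode,
      operator = operator
    ),
    class = "fce_model"
  )
}

#' Derive an evaluation model from an AHP hierarchy
#'
#' @param h A `hierarchy_model`.
#' @inheritParams fce_model
#' @return An `fce_model` using the hierarchy's first-level local weights
#'   and, depending on `mode`, its global (`"global"`) or local
#'   (`"standard"`) second-level weights.
#' @export
fce_model_from_hierarchy <- function(h, membership = NULL, spec = NULL,
                                     mode = c("global", "standard"),
                                     operator = c("weighted_average", "max_min")) {
  stopifnot(inherits(h, "hierarchy_model"))
  mode <- match.arg(mode)
  wcol <- if (mode == "global") "global_weight" else "local_weight"
  second <- dplyr::filter(h$weights, .data$level == 2L)
  gw <- purrr::map(
    split(second, factor(second$group, levels = rownames(h$first_level))),
    function(d) stats::setNames(d[[wcol]], d$indicator)
  )
  wf <- dplyr::filter(h$weights, .data$level == 1L)$local_weight
  fce_model(wf, gw,
    membership = membership, spec = spec, mode = mode,
    operator = operator, groups = rownames(h$first_level)
  )
}

#' @export
print.fce_model <- function(x, ...) {
  cat(sprintf(
    "Cold-stress FCE model (%s mode, %s operator)\n", x$mode, x$operator
  ))
  cat("First-level weights:", paste(sprintf("%s %.2f", x$groups, x$first_level_weights),
    collapse = ", "
  ), "\n")
  cat(
    "Membership source:",
    if (is.null(x$membership)) "trapezoidal specification" else "explicit matrices", "\n"
  )
  invisible(x)
}

evaluate_one <- function(record, model) {
  bs <- purrr::map(model$groups, function(g) {
    e <- if (!is.null(model$membership)) {
      model$membership[[g]]
    } else {
      membership_from_record(record, model$spec, g)
    }
    fce_compose(model$group_weights[[g]], e, operator = model$operator)
  })
  b <- do.call(rbind, bs)
  v <- fce_aggregate(model$first_level_weights, b, operator = model$operator)
  v_norm <- fce_normalize(v)
  cls <- fce_classify(v_norm)
  list(b = b, v = v, v_norm = v_norm, class = cls)
}

#' Evaluate cold stress for a table of calf daily records
#'
#' Runs the full fuzzy comprehensive evaluation for every row of a daily
#' record table and returns one classified row per record, with all
#' intermediate vectors retained for audit.
#'
#' @param records A data frame of calf daily records (see
#'   [read_records()] for the schema). With explicit membership matrices in
#'   the model, indicator columns are carried through but the memberships do
#'   not depend on them (expert scoring replaces the membership functions).
#' @param model An `fce_model`.
#' @return A tibble with the identifying columns of `records` (any of
#'   `calf_id`, `date`, `group` that are present), the five normalized
#'   membership degrees (one column per level), `level_index`, `level`, and
#'   a `detail` list-column holding the group vectors and raw `V` of each
#'   record.
#' @examples
#' model <- fce_model(
#'   c(0.54, 0.35, 0.11),
#'   list(
#'     environmental = c(0.39, 0.11, 0.05),
#'     physiological = c(0.14, 0.05, 0.03, 0.13),
#'     behavioral = c(0.06, 0.03, 0.02, 0.01)
#'   ),
#'   membership = list(
#'     environmental = rbind(c(0, 1, 0, 0, 0), c(0, 0.9, 0.1, 0, 0), c(1, 0, 0, 0, 0)),
#'     physiological = rbind(
#'       c(1, 0, 0, 0, 0), c(0.8, 0.2, 0, 0, 0),
#'       c(0.7, 0.3, 0, 0, 0), c(1, 0, 0, 0, 0)
#'     ),
#'     behavioral = rbind(
#'       c(0.8, 0.2, 0, 0, 0), c(0.9, 0.1, 0, 0, 0),
#'       c(0.6, 0.4, 0, 0, 0), c(1, 0, 0, 0, 0)
#'     )
#'   )
#' )
#' fce_evaluate(data.frame(calf_id = "example"), model)
#' @export
fce_evaluate <- function(records, model) {
  stopifnot(inherits(model, "fce_model"))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    rlang::abort("No records to evaluate.", class = "coldstress_error_degenerate")
  }
  res <- purrr::map(seq_len(nrow(records)), function(i) evaluate_one(records[i, ], model))
  id_cols <- intersect(c("calf_id", "date", "group"), names(records))
  memb <- purrr::map_dfr(res, function(r) tibble::as_tibble(as.list(r$v_norm)))
  cls <- purrr::map_dfr(res, "class")
  dplyr::bind_cols(
    records[, id_cols, drop = FALSE],
    memb,
    cls[, c("level_index", "level")],
    tibble::tibble(detail = purrr::map(res, function(r) r[c("b", "v", "v_norm")]))
  )
}

#' Plot a set of evaluation results
#'
#' Stacked membership profile per record, ordered by record, with the
#' classified level available in the data.
#'
#' @param object A tibble returned by [fce_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fce_results <- function(object, ...) {
  lv <- cold_stress_levels()
  d <- dplyr::mutate(object, .record = dplyr::row_number())
  d <- tidyr::pivot_longer(
    d[, c(".record", lv)],
    cols = dplyr::all_of(lv), names_to = "level", values_to = "membership"
  )
  d$level <- factor(d$level, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.record, y = .data$membership, fill = .data$level)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "record", y = "normalized membership", fill = "cold stress") +
    ggplot2::theme_minimal()
}
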