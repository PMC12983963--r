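# Configuration and file I/O: YAML model documents (judgment-matrix upper
# triangles per panel, optional explicit weights and membership matrices)
# and the daily-record CSV schema.

RECORD_COLUMNS <- c(
  "calf_id", "date", "temperature_c", "humidity_pct", "wind", "weight_kg",
  "height_cm", "diagonal_cm", "chest_cm", "lying_min", "standing_min",
  "rr_per_min", "urination_n"
)

config_abort <- function(path, msg) {
  rlang::abort(sprintf("Invalid model config at /%s: %s", path, msg),
    class = "coldstress_error_configuration"
  )
}

parse_matrix_node <- function(node, path) {
  if (is.null(node$labels) || is.null(node$upper)) {
    config_abort(path, "needs `labels` and `upper`")
  }
  judgment_matrix(unlist(node$upper), labels = unlist(node$labels))
}

#' Load an evaluation-model configuration
#'
#' Reads a YAML document describing the cold-stress evaluation model: the
#' five evaluation levels, one or more scoring panels (each a first-level
#' judgment-matrix upper triangle plus one per factor group), and
#' optionally explicit indicator weights and/or explicit membership
#' matrices (as used in an expert-scored worked evaluation). Judgment
#' values may be written as fractions (`"1/3"`). Every judgment matrix is
#' reciprocal-completed and consistency-checked at load time; a CR failure
#' aborts unless `allow_inconsistent` is set, in which case it warns.
#'
#' @param path Path to the YAML file. Fixtures shipped with the package
#'   (`expert.yaml`, `farmer.yaml`, `worked_example.yaml`) are available
#'   via `system.file("extdata", ..., package = "coldstress")`.
#' @param allow_inconsistent Tolerate CR >= 0.10 with a warning.
#' @return A `coldstress_config`: `levels`, `panels` (named list of
#'   `hierarchy_model`), `weights`, `membership`, `mode`, `operator`.
#' @export
load_model <- function(path, allow_inconsistent = FALSE) {
  doc <- yaml::read_yaml(path)
  levels <- unlist(doc$evaluation_levels %||% cold_stress_levels())
  if (length(levels) != 5L) {
    config_abort("evaluation_levels", "exactly five severity-ordered levels are required")
  }
  panels <- purrr::imap(doc$panels %||% list(), function(p, pname) {
    if (is.null(p$first_level)) config_abort(paste0("panels/", pname), "missing `first_level`")
    fl <- parse_matrix_node(p$first_level, paste0("panels/", pname, "/first_level"))
    grps <- purrr::imap(
      p$groups %||% list(),
      function(g, gname) parse_matrix_node(g, paste0("panels/", pname, "/groups/", gname))
    )
    hierarchy_model(fl, grps, force = allow_inconsistent)
  })
  membership <- NULL
  if (!is.null(doc$membership)) {
    membership <- purrr::imap(doc$membership, function(m, gname) {
      membership_matrix(do.call(rbind, lapply(m, unlist)))
    })
  }
  weights <- doc$weights
  if (!is.null(weights)) {
    if (is.null(weights$first_level) || is.null(weights$groups)) {
      config_abort("weights", "needs `first_level` and `groups`")
    }
    weights$first_level <- unlist(weights$first_level)
    weights$groups <- purrr::map(weights$groups, unlist)
  }
  structure(
    list(
      levels = levels,
      panels = panels,
      weights = weights,
      membership = membership,
      mode = doc$mode %||% "global",
      operator = doc$operator %||% "weighted_average"
    ),
    class = "coldstress_config"
  )
}

#' Build an evaluation model from a loaded configuration
#'
#' Uses the configuration's explicit weight vectors when present (as in the
#' worked-example fixture); otherwise derives weights from the named
#' panel's hierarchy. Explicit membership matrices in the configuration
#' take precedence over trapezoidal membership specifications.
#'
#' @param config A `coldstress_config` from [load_model()].
#' @param panel Panel name (default the first panel) when weights are
#'   derived from a hierarchy.
#' @param mode,operator Override the configuration's evaluation mode or
#'   composition operator.
#' @param spec Optional membership specification used when the
#'   configuration carries no explicit membership matrices.
#' @return An `fce_model`.
#' @export
build_fce_model <- function(config, panel = NULL, mode = NULL, operator = NULL,
                            spec = NULL) {
  stopifnot(inherits(config, "coldstress_config"))
  mode <- mode %||% config$mode
  operator <- operator %||% config$operator
  if (!is.null(config$weights)) {
    groups <- names(config$weights$groups)
    fce_model(
      config$weights$first_level, config$weights$groups,
      membership = config$membership, spec = spec,
      mode = mode, operator = operator, groups = groups
    )
  } else {
    if (length(config$panels) == 0) {
      config_abort("panels", "no panel to derive weights from")
    }
    panel <- panel %||% names(config$panels)[1]
    if (!panel %in% names(config$panels)) {
      config_abort("panels", sprintf("panel '%s' not found", panel))
    }
    fce_model_from_hierarchy(config$panels[[panel]],
      membership = config$membership, spec = spec,
      mode = mode, operator = operator
    )
  }
}

#' Read a calf daily-record CSV
#'
#' Expects the documented header
#' `calf_id,date,temperature_c,humidity_pct,wind,weight_kg,height_cm,`
#' `diagonal_cm,chest_cm,lying_min,standing_min,rr_per_min,urination_n`
#' (extra columns such as `group` are carried through). Unit checks:
#' humidity in `[0, 100]`, lying/standing minutes in `[0, 1440]`, wind
#' non-negative. An empty file with a valid header yields an empty tibble.
#'
#' @param path CSV path.
#' @return A validated tibble of records.
#' @export
read_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(rec))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Record file is missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "coldstress_error_schema"
    )
  }
  prob <- readr::problems(rec)
  if (nrow(prob) > 0) {
    rlang::abort(
      sprintf(
        "Malformed record row(s): %s.",
        paste(unique(prob$row), collapse = ", ")
      ),
      class = "coldstress_error_schema"
    )
  }
  if (nrow(rec) == 0) {
    return(rec)
  }
  check_unit <- function(col, lo, hi) {
    bad <- which(rec[[col]] < lo | rec[[col]] > hi)
    if (length(bad) > 0) {
      rlang::abort(
        sprintf(
          "Column '%s' outside [%s, %s] at row(s) %s.",
          col, format(lo), format(hi), paste(utils::head(bad, 5), collapse = ", ")
        ),
        class = "coldstress_error_domain"
      )
    }
  }
  check_unit("humidity_pct", 0, 100)
  check_unit("lying_min", 0, 1440)
  check_unit("standing_min", 0, 1440)
  check_unit("wind", 0, Inf)
  rec
}

#' Write records or evaluation results to CSV
#'
#' Numeric fields are serialized at full precision; the `detail`
#' list-column of evaluation results (group vectors and raw V) is dropped
#' on write.
#'
#' @param x A tibble of records or of [fce_evaluate()] results.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  x_out <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_csv(x_out, path)
  invisible(x)
}

#' @rdname write_results
#' @export
write_records <- write_results
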