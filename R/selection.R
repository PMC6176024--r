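#' Category key for condition stratification
#'
#' A partial pattern over the categorical condition metadata. Any field left
#' `NULL` is a wildcard; a fully wildcarded key selects every condition.
#' Keys drive the liver-category stratification of signatures (e.g. rat
#' liver in vitro, human liver in vitro) and the choice of the scoring
#' category.
#'
#' @param species `"human"`, `"rat"` or `NULL` (wildcard).
#' @param tissue `"liver"`, `"kidney"` or `NULL`.
#' @param setting `"in_vitro"`, `"in_vivo"` or `NULL`.
#' @param dosing `"bolus"`, `"repeated"` or `NULL`.
#' @return An object of class `category_key`.
#' @export
#' @examples
#' category_key(species = "human", tissue = "liver", setting = "in_vitro")
category_key <- function(species = NULL, tissue = NULL, setting = NULL,
                         dosing = NULL) {
  chk <- function(value, levels, what) {
    if (is.null(value)) {
      return(NULL)
    }
    value <- as.character(value)
    if (length(value) != 1L || !value %in% levels) {
      abort(
        paste0(
          what, " must be NULL or one of ",
          paste(shQuote(levels), collapse = ", ")
        ),
        class = "toxsig_argument_error"
      )
    }
    value
  }
  structure(
    list(
      species = chk(species, .species_levels, "species"),
      tissue = chk(tissue, .tissue_levels, "tissue"),
      setting = chk(setting, .setting_levels, "setting"),
      dosing = chk(dosing, .dosing_levels, "dosing")
    ),
    class = "category_key"
  )
}

#' @export
format.category_key <- function(x, ...) {
  parts <- vapply(
    c("species", "tissue", "setting", "dosing"),
    function(f) x[[f]] %||% "*", character(1L)
  )
  paste(parts, collapse = "/")
}

#' @export
print.category_key <- function(x, ...) {
  cat("<category_key> ", format(x), "\n", sep = "")
  invisible(x)
}

selection_report <- function(before, after, description) {
  structure(
    list(
      n_conditions_before = nrow(before$conditions),
      n_conditions_after = nrow(after$conditions),
      n_values_before = nrow(before$values),
      n_values_after = nrow(after$values),
      description = description
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(
    "<selection_report> ", x$description, "\n  conditions: ",
    x$n_conditions_before, " -> ", x$n_conditions_after,
    "; values: ", x$n_values_before, " -> ", x$n_values_after, "\n",
    sep = ""
  )
  invisible(x)
}

#' Drop conditions measured after a maximum exposure time
#'
#' Exposures longer than 24 h tend to produce mixed stress responses that
#' blur the attribution of transcriptional changes to a single pathway, so
#' the analysis excludes them by default. The bound is inclusive: `time_h`
#' equal to `max_hours` is retained. Early kidney in-vivo time points are
#' not treated specially (they pass any bound at or above their time).
#'
#' @param matrix An [fc_matrix()].
#' @param max_hours Positive number of hours; conditions with
#'   `time_h <= max_hours` are kept. Use `Inf` for no filtering.
#' @return A list with elements `matrix` (the filtered [fc_matrix()]) and
#'   `report` (a `selection_report` with condition and value counts before
#'   and after).
#' @export
filter_by_max_time <- function(matrix, max_hours = 24) {
  if (!is.numeric(max_hours) || length(max_hours) != 1L ||
      is.na(max_hours) || max_hours <= 0) {
    abort("`max_hours` must be a single positive number",
      class = "toxsig_argument_error"
    )
  }
  keep <- matrix$conditions$condition_id[matrix$conditions$time_h <= max_hours]
  out <- fc_keep_conditions(matrix, keep)
  list(
    matrix = out,
    report = selection_report(
      matrix, out,
      paste0("retain conditions with time_h <= ", max_hours, " h")
    )
  )
}

#' Select the conditions of an experimental category
#'
#' @param matrix An [fc_matrix()].
#' @param key A [category_key()]; wildcarded fields match everything.
#' @return The [fc_matrix()] restricted to conditions matching every
#'   non-wildcard field of `key`. An empty selection is allowed and raises a
#'   warning.
#' @export
select_category <- function(matrix, key = category_key()) {
  if (!inherits(key, "category_key")) {
    abort("`key` must be a category_key()", class = "toxsig_argument_error")
  }
  cond <- matrix$conditions
  keep <- rep(TRUE, nrow(cond))
  for (field in c("species", "tissue", "setting", "dosing")) {
    if (!is.null(key[[field]])) {
      keep <- keep & cond[[field]] == key[[field]]
    }
  }
  out <- fc_keep_conditions(matrix, cond$condition_id[keep])
  if (nrow(out$conditions) == 0L && nrow(cond) > 0L) {
    warn(paste0("category ", format(key), " selects no conditions"))
  }
  out
}

#' Select all conditions of a set of chemicals
#'
#' Chemical names are compared case-insensitively after whitespace
#' normalisation; no fuzzy matching. Listed chemicals absent from the
#' dataset are reported as uncovered by a warning rather than silently
#' ignored, because an activator that covers no conditions invalidates the
#' pathway profile built from it.
#'
#' @param matrix An [fc_matrix()].
#' @param chemicals Non-empty character vector of chemical names.
#' @return The [fc_matrix()] restricted to conditions of the listed
#'   chemicals.
#' @export
select_chemical_conditions <- function(matrix, chemicals) {
  if (length(chemicals) == 0L) {
    abort("`chemicals` must be non-empty", class = "toxsig_argument_error")
  }
  want <- norm_chem(chemicals)
  have <- norm_chem(matrix$conditions$chemical)
  uncovered <- chemicals[!want %in% have]
  if (length(uncovered) > 0L) {
    warn(
      paste0(
        "uncovered activator chemical(s), no conditions in dataset: ",
        paste(uncovered, collapse = ", ")
      ),
      class = "toxsig_uncovered_activator"
    )
  }
  keep <- matrix$conditions$condition_id[have %in% want]
  fc_keep_conditions(matrix, keep)
}
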