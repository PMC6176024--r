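#' Fold-change matrix
#'
#' The analysis substrate: a sparse condition-by-gene table of log2 fold
#' changes over time-matched controls, together with per-condition metadata.
#' Stored in long (tidy) form because the source toxicogenomic projects use
#' incompatible wide layouts. A missing (condition, gene) entry means "not
#' measured" and is distinct from a stored zero: per-gene means skip missing
#' data rather than treating it as no change.
#'
#' @param conditions Tibble of condition metadata with columns
#'   `condition_id`, `chemical`, `species` (`"human"`/`"rat"`), `tissue`
#'   (`"liver"`/`"kidney"`), `setting` (`"in_vitro"`/`"in_vivo"`), `dosing`
#'   (`"bolus"`/`"repeated"`), `time_h` (exposure duration in hours, > 0),
#'   `dose_label` and `project` (free strings).
#' @param values Tibble with columns `condition_id`, `gene`, `log2fc`; one
#'   row per stored value. Every `condition_id` must appear in `conditions`;
#'   no duplicate (condition, gene) pairs; values finite.
#' @param genes Optional character vector of gene symbols covered by the
#'   dataset. Defaults to the genes present in `values`; may be a superset,
#'   so that genes known to the study but unmeasured under some conditions
#'   can still be reported as excluded downstream.
#'
#' @return An object of class `fc_matrix`: a list with elements
#'   `conditions`, `values` and `genes`.
#' @export
#' @examples
#' m <- fc_matrix(
#'   conditions = tibble::tibble(
#'     condition_id = "c1", chemical = "Tunicamycin", species = "human",
#'     tissue = "liver", setting = "in_vitro", dosing = "bolus",
#'     time_h = 24, dose_label = "high", project = "demo"
#'   ),
#'   values = tibble::tibble(condition_id = "c1", gene = "DDIT3", log2fc = 1.6)
#' )
#' m
fc_matrix <- function(conditions, values, genes = NULL) {
  conditions <- as_tibble(conditions)
  values <- as_tibble(values)

  meta_cols <- c(
    "condition_id", "chemical", "species", "tissue", "setting",
    "dosing", "time_h", "dose_label", "project"
  )
  missing_meta <- setdiff(meta_cols, names(conditions))
  if (length(missing_meta) > 0L) {
    abort(
      paste0(
        "condition metadata is missing column(s): ",
        paste(missing_meta, collapse = ", ")
      ),
      class = "toxsig_schema_error"
    )
  }
  missing_val <- setdiff(c("condition_id", "gene", "log2fc"), names(values))
  if (length(missing_val) > 0L) {
    abort(
      paste0(
        "value table is missing column(s): ",
        paste(missing_val, collapse = ", ")
      ),
      class = "toxsig_schema_error"
    )
  }

  conditions <- conditions[meta_cols]
  values <- values[c("condition_id", "gene", "log2fc")]
  conditions$condition_id <- as.character(conditions$condition_id)
  conditions$time_h <- as.numeric(conditions$time_h)
  values$condition_id <- as.character(values$condition_id)
  values$gene <- as.character(values$gene)
  values$log2fc <- as.numeric(values$log2fc)

  if (anyDuplicated(conditions$condition_id)) {
    dups <- unique(conditions$condition_id[duplicated(conditions$condition_id)])
    abort(
      paste0(
        "duplicate condition_id(s): ", paste(head(dups, 5L), collapse = ", ")
      ),
      class = "toxsig_integrity_error"
    )
  }
  check_enum <- function(col, levels) {
    bad <- setdiff(unique(conditions[[col]]), levels)
    if (length(bad) > 0L) {
      abort(
        paste0(
          "invalid ", col, " value(s): ", paste(bad, collapse = ", "),
          " (allowed: ", paste(levels, collapse = ", "), ")"
        ),
        class = "toxsig_schema_error"
      )
    }
  }
  check_enum("species", .species_levels)
  check_enum("tissue", .tissue_levels)
  check_enum("setting", .setting_levels)
  check_enum("dosing", .dosing_levels)
  if (any(!is.finite(conditions$time_h)) || any(conditions$time_h <= 0)) {
    abort("time_h must be finite and > 0 for every condition",
      class = "toxsig_schema_error"
    )
  }

  unknown <- setdiff(unique(values$condition_id), conditions$condition_id)
  if (length(unknown) > 0L) {
    abort(
      paste0(
        "values reference unknown condition_id(s): ",
        paste(head(unknown, 5L), collapse = ", ")
      ),
      class = "toxsig_integrity_error"
    )
  }
  if (any(!is.finite(values$log2fc))) {
    abort("log2fc values must be finite (blank cells are dropped, not stored)",
      class = "toxsig_integrity_error"
    )
  }
  key <- paste(values$condition_id, values$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- values[duplicated(key), , drop = FALSE]
    abort(
      paste0(
        "duplicate (condition, gene) pair(s), e.g. (",
        dup$condition_id[1L], ", ", dup$gene[1L], ")"
      ),
      class = "toxsig_integrity_error"
    )
  }

  genes <- sort(unique(c(as.character(genes %||% character()), values$gene)))

  structure(
    list(conditions = conditions, values = values, genes = genes),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(
    "<fc_matrix> ", nrow(x$conditions), " conditions x ", length(x$genes),
    " genes; ", nrow(x$values), " stored log2FC values (",
    format(
      100 * nrow(x$values) /
        max(1, nrow(x$conditions) * length(x$genes)),
      digits = 3
    ),
    "% dense)\n",
    sep = ""
  )
  chems <- unique(x$conditions$chemical)
  cat(
    "  chemicals: ", length(chems), "; time points (h): ",
    paste(sort(unique(x$conditions$time_h)), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Accessors for fold-change matrices
#'
#' @param matrix An [fc_matrix()].
#' @return `fc_conditions()` the condition metadata tibble, `fc_values()`
#'   the long value tibble, `fc_genes()` the gene symbol vector,
#'   `fc_chemicals()` the unique chemical names in metadata order.
#' @export
fc_conditions <- function(matrix) matrix$conditions

#' @rdname fc_conditions
#' @export
fc_values <- function(matrix) matrix$values

#' @rdname fc_conditions
#' @export
fc_genes <- function(matrix) matrix$genes

#' @rdname fc_conditions
#' @export
fc_chemicals <- function(matrix) unique(matrix$conditions$chemical)

# Restrict a matrix to a set of condition ids. The gene universe is kept:
# genes losing all their values remain known to the dataset (so they can be
# reported as "excluded for having no data" rather than silently vanishing).
fc_keep_conditions <- function(matrix, condition_ids) {
  cond <- matrix$conditions[matrix$conditions$condition_id %in% condition_ids, ,
    drop = FALSE
  ]
  vals <- matrix$values[matrix$values$condition_id %in% condition_ids, ,
    drop = FALSE
  ]
  structure(
    list(conditions = cond, values = vals, genes = matrix$genes),
    class = "fc_matrix"
  )
}
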