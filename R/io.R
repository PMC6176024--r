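#' Read a long-format fold-change table
#'
#' Reads a delimited (TSV or CSV) long-format table with one row per
#' condition-gene pair and the full condition metadata repeated on every
#' row. Rows with a blank `log2fc` cell record that the gene was part of the
#' condition's platform but yielded no value; they contribute to the gene
#' universe but store no value (missing is never zero).
#'
#' @param path Path to the file. UTF-8, header row required, decimal point
#'   `.`. Required columns: `condition_id`, `chemical`, `species`, `tissue`,
#'   `setting`, `dosing`, `time_h`, `dose_label`, `project`, `gene`,
#'   `log2fc`.
#' @param dialect `"auto"` (default; decided by file extension, `.csv` means
#'   comma), `"long_tsv"` or `"long_csv"`.
#'
#' @return An [fc_matrix()].
#' @export
read_fold_change_table <- function(path,
                                   dialect = c("auto", "long_tsv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "toxsig_io_error")
  }
  delim <- switch(dialect,
    long_tsv = "\t",
    long_csv = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  )
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  required <- c(
    "condition_id", "chemical", "species", "tissue", "setting", "dosing",
    "time_h", "dose_label", "project", "gene", "log2fc"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(
      paste0(
        "fold-change table is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "toxsig_schema_error"
    )
  }

  fc_chr <- trimws(raw$log2fc)
  blank <- is.na(fc_chr) | fc_chr == "" | toupper(fc_chr) == "NA"
  fc_num <- suppressWarnings(as.numeric(fc_chr))
  bad <- !blank & is.na(fc_num)
  if (any(bad)) {
    abort(
      paste0(
        "non-numeric log2fc at data row(s): ",
        paste(head(which(bad), 5L), collapse = ", "),
        " (value ", shQuote(fc_chr[which(bad)[1L]]), ")"
      ),
      class = "toxsig_parse_error"
    )
  }

  meta_cols <- required[1:9]
  meta <- unique(raw[meta_cols])
  conflicting <- meta$condition_id[duplicated(meta$condition_id)]
  if (length(conflicting) > 0L) {
    abort(
      paste0(
        "conflicting metadata for condition_id(s): ",
        paste(unique(head(conflicting, 5L)), collapse = ", ")
      ),
      class = "toxsig_integrity_error"
    )
  }
  meta$time_h <- suppressWarnings(as.numeric(meta$time_h))

  values <- tibble(
    condition_id = raw$condition_id[!blank],
    gene = raw$gene[!blank],
    log2fc = fc_num[!blank]
  )
  fc_matrix(meta, values, genes = unique(raw$gene))
}

#' Write a fold-change matrix as a long-format delimited table
#'
#' Inverse of [read_fold_change_table()]: every stored value becomes a row
#' with its full condition metadata; genes known to the dataset but
#' unmeasured under a condition are written once per condition with a blank
#' `log2fc` cell only when `keep_missing = TRUE` (the default keeps the file
#' sparse and writes stored values only, plus one blank row per gene that
#' has no values at all, so the gene universe round-trips).
#'
#' @param matrix An [fc_matrix()].
#' @param path Output path; extension `.csv` selects comma, otherwise tab.
#' @param keep_missing If `TRUE`, writes a blank-valued row for every
#'   missing (condition, gene) cell. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(matrix, path, keep_missing = FALSE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rows <- dplyr::inner_join(matrix$conditions, matrix$values,
    by = "condition_id"
  )
  rows$log2fc <- format(rows$log2fc, digits = 15, trim = TRUE,
    scientific = FALSE
  )
  extra <- if (keep_missing) {
    all_cells <- tidyr::expand_grid(
      condition_id = matrix$conditions$condition_id,
      gene = matrix$genes
    )
    miss <- dplyr::anti_join(all_cells, matrix$values,
      by = c("condition_id", "gene")
    )
    dplyr::inner_join(matrix$conditions, miss, by = "condition_id")
  } else {
    # one blank row per value-less gene keeps the gene universe in the file
    orphans <- setdiff(matrix$genes, unique(matrix$values$gene))
    if (length(orphans) > 0L && nrow(matrix$conditions) > 0L) {
      tibble(gene = orphans) |>
        dplyr::cross_join(matrix$conditions[1L, , drop = FALSE]) |>
        dplyr::relocate("gene", .after = dplyr::last_col())
    } else {
      NULL
    }
  }
  if (!is.null(extra) && nrow(extra) > 0L) {
    extra$log2fc <- ""
    rows <- dplyr::bind_rows(rows, extra)
  }
  rows <- dplyr::arrange(rows, .data$condition_id, .data$gene)
  readr::write_delim(rows, path, delim = delim, na = "")
  invisible(path)
}

#' Gene target catalog
#'
#' A-priori assignment of gene symbols to the pathways under which they were
#' curated. A gene may be listed under several pathways; memberships are
#' unioned. The catalog is reporting metadata: signature derivation itself
#' runs over all measured genes, and the a-priori pathway is attached to
#' output tables for comparison.
#'
#' @param df Data frame with columns `gene` and `pathway` (values among
#'   [pathway_ids()]).
#' @return An object of class `gene_catalog`: a tibble of unique
#'   (gene, pathway) rows sorted by gene then pathway.
#' @export
#' @examples
#' gene_catalog(data.frame(
#'   gene = c("NQO1", "NQO1"),
#'   pathway = c("AhR", "Nrf2")
#' ))
gene_catalog <- function(df) {
  df <- as_tibble(df)
  missing_cols <- setdiff(c("gene", "pathway"), names(df))
  if (length(missing_cols) > 0L) {
    abort(
      paste0(
        "gene catalog is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "toxsig_schema_error"
    )
  }
  df$gene <- as.character(df$gene)
  df$pathway <- as.character(df$pathway)
  bad <- setdiff(unique(df$pathway), pathway_ids())
  if (length(bad) > 0L) {
    abort(
      paste0("unknown pathway label(s): ", paste(bad, collapse = ", ")),
      class = "toxsig_schema_error"
    )
  }
  out <- df |>
    dplyr::distinct(.data$gene, .data$pathway) |>
    dplyr::arrange(
      .data$gene, factor(.data$pathway, levels = pathway_ids())
    )
  structure(out, class = c("gene_catalog", class(out)))
}

#' @rdname gene_catalog
#' @param path Path to a TSV/CSV file with columns `gene`, `pathway`.
#' @export
read_gene_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "toxsig_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  gene_catalog(df)
}

#' @rdname gene_catalog
#' @param catalog A `gene_catalog`.
#' @export
write_gene_catalog <- function(catalog, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(as_tibble(catalog), path, delim = delim)
  invisible(path)
}

#' A-priori pathway labels for a set of genes
#'
#' @param catalog A [gene_catalog()].
#' @param genes Character vector of gene symbols.
#' @return Character vector: space-separated sorted a-priori memberships per
#'   gene (`NA` for genes absent from the catalog).
#' @export
a_priori_pathways <- function(catalog, genes) {
  tab <- as_tibble(catalog) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      label = paste(
        intersect(pathway_ids(), .data$pathway),
        collapse = " "
      ),
      .groups = "drop"
    )
  tab$label[match(genes, tab$gene)]
}

#' Activator configuration
#'
#' Maps each pathway to its reference activator chemicals: compounds whose
#' known mode of action turns on that pathway without directly engaging the
#' other two (e.g. tunicamycin for ATF4). An activator may carry an optional
#' category scope (species/tissue/setting where it is considered
#' applicable); scopes are retained as metadata and reported, but profile
#' construction pools all conditions of all configured activators.
#'
#' @param ... Named character vectors, one per pathway, e.g.
#'   `AhR = c("Benzo(a)pyrene", "Omeprazole")`. Each listed pathway must
#'   have at least one chemical.
#' @param scopes Optional tibble with columns `chemical` plus any of
#'   `species`, `tissue`, `setting`, `dosing`.
#' @return An object of class `activator_config`: a named list of character
#'   vectors keyed by pathway.
#' @export
#' @examples
#' activator_config(
#'   AhR = c("Benzo(a)pyrene", "Omeprazole"),
#'   Nrf2 = c("Potassium Bromate", "Phorone"),
#'   ATF4 = "Tunicamycin"
#' )
activator_config <- function(..., scopes = NULL) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1L]]) && is.null(names(cfg))) {
    cfg <- cfg[[1L]]
  }
  bad <- setdiff(names(cfg), pathway_ids())
  if (length(bad) > 0L || is.null(names(cfg)) || any(names(cfg) == "")) {
    abort(
      paste0(
        "activator config keys must be pathways (",
        paste(pathway_ids(), collapse = ", "), ")",
        if (length(bad) > 0L) paste0("; got: ", paste(bad, collapse = ", "))
      ),
      class = "toxsig_config_error"
    )
  }
  cfg <- lapply(cfg, function(x) as.character(unlist(x)))
  empty <- names(cfg)[lengths(cfg) == 0L]
  if (length(empty) > 0L) {
    abort(
      paste0(
        "pathway(s) with empty activator list: ",
        paste(empty, collapse = ", ")
      ),
      class = "toxsig_config_error"
    )
  }
  absent <- setdiff(pathway_ids(), names(cfg))
  if (length(absent) > 0L) {
    warn(paste0(
      "no activators configured for pathway(s): ",
      paste(absent, collapse = ", ")
    ))
  }
  cfg <- cfg[intersect(pathway_ids(), names(cfg))]
  structure(cfg, class = "activator_config", scopes = scopes)
}

#' @rdname activator_config
#' @param path Path to a YAML (or JSON) file. Either
#'   `pathway: [chemical, ...]` entries, or a list of
#'   `{chemical: ..., species: ..., tissue: ...}` maps per pathway, in which
#'   case the extra fields become the activator's category scope.
#' @export
read_activator_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "toxsig_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) {
    abort("activator config must be a mapping of pathway to chemical list",
      class = "toxsig_config_error"
    )
  }
  scopes <- list()
  cfg <- lapply(raw, function(entries) {
    if (!is.list(entries)) entries <- as.list(entries)
    vapply(entries, function(e) {
      if (is.list(e)) {
        chem <- e$chemical %||%
          abort("scoped activator entry needs a 'chemical' field",
            class = "toxsig_config_error"
          )
        scope <- e[intersect(
          names(e), c("species", "tissue", "setting", "dosing")
        )]
        if (length(scope) > 0L) {
          scopes[[length(scopes) + 1L]] <<- tibble(
            chemical = as.character(chem), !!!scope
          )
        }
        as.character(chem)
      } else {
        as.character(e)
      }
    }, character(1L))
  })
  scopes <- if (length(scopes) > 0L) dplyr::bind_rows(scopes) else NULL
  activator_config(cfg, scopes = scopes)
}

#' @rdname activator_config
#' @param config An `activator_config`.
#' @export
write_activator_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), as.list), path)
  invisible(path)
}

#' @export
print.activator_config <- function(x, ...) {
  cat("<activator_config>\n")
  for (p in names(x)) {
    cat("  ", p, ": ", paste(x[[p]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
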