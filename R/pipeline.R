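#' Run the full signature-and-scoring pipeline
#'
#' Executes the whole analysis in order: read (or accept in-memory) inputs,
#' filter conditions to the exposure window, derive the three pathway
#' activation profiles from the configured activator chemicals, threshold
#' them into signatures, partition the signatures into the 7 Venn zones,
#' score every chemical of the scoring category by its CAC vector, and
#' classify chemicals into pathway-specific potent activators. Each stage
#' logs its input/output dimensions (via `message()`), because the
#' selection steps silently drop data and those drops must be auditable.
#' Any stage failure halts with the stage name; no partial silent output.
#'
#' @param data An [fc_matrix()] or a path for [read_fold_change_table()].
#' @param activators An [activator_config()] or a path for
#'   [read_activator_config()].
#' @param catalog Optional [gene_catalog()] or path; reporting metadata
#'   only.
#' @param max_hours Exposure-time cut (inclusive); default 24.
#' @param sigma_mult Signature threshold multiplier; default 2.
#' @param signature_key [category_key()] the signatures are derived on;
#'   default all conditions.
#' @param scoring_key [category_key()] selecting the scoring category;
#'   default human liver in vitro, the category relevant for human risk
#'   assessment.
#' @param cos_cutoff,module_cutoff Classification cut-offs; defaults
#'   `1/sqrt(3)` and 0.5.
#' @param out_dir Optional output directory; when given, writes the seven
#'   signature tables, the Venn summary (TSV + JSON), the per-chemical
#'   score table, per-pathway ranked lists and the scatter coordinates,
#'   plus `run_summary.json`.
#' @param quiet Suppress stage messages.
#' @return An object of class `run_summary`: list with `selection`
#'   (report), `profiles` (per-pathway mu/sigma/gene-count tibble),
#'   `signature_set`, `partition`, `venn` (tibble), `scores`,
#'   `classification`, `pass_counts`, `top_chemicals`, `parameters`.
#' @export
run_pipeline <- function(data, activators, catalog = NULL,
                         max_hours = 24, sigma_mult = 2,
                         signature_key = category_key(),
                         scoring_key = category_key(
                           species = "human", tissue = "liver",
                           setting = "in_vitro"
                         ),
                         cos_cutoff = 1 / sqrt(3), module_cutoff = 0.5,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[toxsig] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "toxsig_pipeline_error", parent = e
      )
    })
  }

  matrix <- stage("read", {
    if (inherits(data, "fc_matrix")) data else read_fold_change_table(data)
  })
  activators <- stage("read", {
    if (inherits(activators, "activator_config")) {
      activators
    } else {
      read_activator_config(activators)
    }
  })
  if (!is.null(catalog) && !inherits(catalog, "gene_catalog")) {
    catalog <- stage("read", read_gene_catalog(catalog))
  }
  say(
    "read: ", nrow(matrix$conditions), " conditions x ",
    length(matrix$genes), " genes, ", nrow(matrix$values), " values"
  )

  filt <- stage("filter", filter_by_max_time(matrix, max_hours))
  say(
    "filter (<= ", max_hours, " h): conditions ",
    filt$report$n_conditions_before, " -> ", filt$report$n_conditions_after
  )

  set <- stage(
    "signatures",
    build_signatures(filt$matrix, activators,
      key = signature_key,
      sigma_mult = sigma_mult
    )
  )
  for (s in set$signatures) {
    say(
      "signature ", s$pathway, ": ", nrow(s$activated), " activated + ",
      nrow(s$inhibited), " inhibited"
    )
  }

  partition <- stage("partition", partition_overlaps(set))
  venn <- venn_summary(partition)
  say("zones: ", paste(venn$zone, venn$n_genes, sep = "=", collapse = ", "))

  scoring_matrix <- stage(
    "scoring",
    select_category(filt$matrix, scoring_key)
  )
  scores <- stage(
    "scoring",
    score_chemicals(scoring_matrix, partition,
      cos_cutoff = cos_cutoff, module_cutoff = module_cutoff
    )
  )
  classification <- stage(
    "classification",
    classify_chemicals(scores,
      cos_cutoff = cos_cutoff,
      module_cutoff = module_cutoff
    )
  )
  pass_counts <- vapply(
    classification$per_pathway, nrow, integer(1L)
  )
  say(
    "classified: ",
    paste(pathway_ids(), pass_counts, sep = "=", collapse = ", "),
    " of ", nrow(scores), " chemicals (",
    length(classification$not_scorable), " not scorable)"
  )

  profiles <- dplyr::bind_rows(lapply(pathway_ids(), function(p) {
    pr <- set$profiles[[p]]
    tibble(
      pathway = p,
      mu = if (is.null(pr)) NA_real_ else pr$mu,
      sigma = if (is.null(pr)) NA_real_ else pr$sigma,
      n_genes = if (is.null(pr)) 0L else length(pr$combined),
      n_excluded = if (is.null(pr)) NA_integer_ else {
        length(pr$excluded_genes)
      },
      available = !is.null(pr)
    )
  }))

  summary <- structure(
    list(
      selection = filt$report,
      profiles = profiles,
      signature_set = set,
      partition = partition,
      venn = venn,
      scores = scores,
      classification = classification,
      pass_counts = pass_counts,
      top_chemicals = lapply(
        classification$per_pathway,
        function(tab) head(tab$chemical, 5L)
      ),
      parameters = list(
        max_hours = max_hours, sigma_mult = sigma_mult,
        signature_key = format(signature_key),
        scoring_key = format(scoring_key),
        cos_cutoff = cos_cutoff, module_cutoff = module_cutoff,
        version = as.character(utils::packageVersion("toxsig"))
      )
    ),
    class = "run_summary"
  )

  if (!is.null(out_dir)) {
    stage("write", write_run_outputs(summary, out_dir, catalog = catalog))
    say("outputs written to ", out_dir)
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  print(x$selection)
  cat(
    "  zones: ",
    paste(x$venn$zone, x$venn$n_genes, sep = "=", collapse = ", "), "\n",
    "  classified: ",
    paste(names(x$pass_counts), x$pass_counts, sep = "=", collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write all pipeline output tables
#'
#' @param summary A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param catalog Optional [gene_catalog()] for a-priori annotation of the
#'   signature tables.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(summary, dir, catalog = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) {
    abort(paste0("cannot create output directory: ", dir),
      class = "toxsig_io_error"
    )
  }
  write_signature_tables(
    summary$signature_set, summary$partition,
    file.path(dir, "signatures"),
    catalog = catalog
  )
  readr::write_tsv(summary$venn, file.path(dir, "venn_summary.tsv"))
  jsonlite::write_json(
    setNames(as.list(summary$venn$n_genes), summary$venn$zone),
    file.path(dir, "venn_counts.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  readr::write_tsv(
    as_tibble(summary$scores),
    file.path(dir, "chemical_scores.tsv"), na = ""
  )
  for (p in pathway_ids()) {
    readr::write_tsv(
      summary$classification$per_pathway[[p]],
      file.path(dir, paste0("ranked_", p, ".tsv"))
    )
  }
  readr::write_tsv(
    export_scatter_data(summary$scores),
    file.path(dir, "scatter_coordinates.tsv"), na = ""
  )
  jsonlite::write_json(
    list(
      selection = unclass(summary$selection),
      profiles = summary$profiles,
      venn = setNames(as.list(summary$venn$n_genes), summary$venn$zone),
      pass_counts = as.list(summary$pass_counts),
      top_chemicals = summary$top_chemicals,
      not_scorable = summary$classification$not_scorable,
      parameters = summary$parameters
    ),
    file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
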