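#' Chemical activation capacity for one chemical and gene set
#'
#' The CAC of a chemical for a pathway is the mean of all available log2
#' fold changes over the chemical's conditions and the pathway's exclusive
#' signature genes — a single pooled mean over the condition-by-gene block,
#' skipping missing cells. CACs are negative for chemicals that
#' predominantly down-regulate the gene set.
#'
#' @param matrix An [fc_matrix()], already restricted to the scoring
#'   category and time window.
#' @param chemical Chemical name (matched case-insensitively after
#'   whitespace normalisation).
#' @param genes Non-empty character vector of gene symbols.
#' @return A single number, or `NA` (with a warning) when the chemical has
#'   no value for any of the genes — a missing coordinate, distinct from a
#'   true zero.
#' @export
chemical_cac <- function(matrix, chemical, genes) {
  if (length(genes) == 0L) {
    abort("`genes` must be non-empty", class = "toxsig_argument_error")
  }
  ids <- matrix$conditions$condition_id[
    norm_chem(matrix$conditions$chemical) == norm_chem(chemical)
  ]
  if (length(ids) == 0L) {
    warn(paste0("chemical ", chemical, " absent from dataset"))
    return(NA_real_)
  }
  v <- matrix$values
  sel <- v$log2fc[v$condition_id %in% ids & v$gene %in% genes]
  if (length(sel) == 0L) {
    warn(paste0(
      "chemical ", chemical, " has no data for the requested genes"
    ))
    return(NA_real_)
  }
  mean(sel)
}

#' Specificity and potency geometry
#'
#' A chemical's three CACs place it as a point K in a 3-dimensional space
#' whose axes are the pathways. `axis_cosine()` is the absolute cosine of
#' the angle between the vector OK and a pathway's axis, `|v_axis| / ||v||`
#' — the chemical's specificity for that pathway (1 = exactly on the axis).
#' `vector_module()` is the Euclidean norm `||OK||` — the chemical's overall
#' activation potency. Their per-pathway product, the pathway score, equals
#' `|v_axis|` identically.
#'
#' The equidistant direction (1,1,1) has cosine `1/sqrt(3) = 0.57735` to
#' every axis, which motivates the default specificity cut-off: a chemical
#' must beat the no-preference direction.
#'
#' @param v Numeric 3-vector of CACs, ordered as [pathway_ids()].
#' @param axis One of [pathway_ids()] (or an index 1:3).
#' @return `axis_cosine()`: a number in \[0, 1\], or `NA` for the zero
#'   vector (the angle is undefined; callers treat such chemicals as not
#'   specific to anything). `vector_module()`: a number >= 0.
#' @export
#' @examples
#' axis_cosine(c(1, 1, 1), "AhR") # 0.57735
#' vector_module(c(3, 4, 0)) # 5
axis_cosine <- function(v, axis) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(is.na(v))) {
    abort("`v` must be a numeric 3-vector without NA",
      class = "toxsig_argument_error"
    )
  }
  i <- if (is.numeric(axis)) as.integer(axis) else match(axis, pathway_ids())
  if (is.na(i) || i < 1L || i > 3L) {
    abort("`axis` must be a pathway label or an index in 1:3",
      class = "toxsig_argument_error"
    )
  }
  n <- sqrt(sum(v^2))
  if (n == 0) {
    return(NA_real_)
  }
  abs(v[i]) / n
}

#' @rdname axis_cosine
#' @export
vector_module <- function(v) {
  v <- as.numeric(v)
  sqrt(sum(v^2))
}

#' Score chemicals by chemical activation capacity
#'
#' Computes, for every chemical, the CAC 3-vector over the three exclusive
#' signature gene sets, the per-axis specificity cosines, the potency
#' module and the per-pathway scores (cosine times module). A chemical
#' lacking data for any pathway's exclusive genes gets an `NA` coordinate
#' and is flagged not scorable: treating a missing coordinate as 0 would
#' fabricate specificity for the remaining axes. A chemical with the exact
#' zero vector has undefined angles; its cosines are reported as 0 (not
#' specific to anything) and it can never pass the module cut-off.
#'
#' @param matrix An [fc_matrix()] restricted to the scoring category.
#' @param partition An [partition_overlaps()] result supplying the
#'   exclusive gene sets.
#' @param chemicals Chemicals to score; default all chemicals in `matrix`.
#' @param cos_cutoff,module_cutoff Cut-offs used for the per-pathway raw
#'   pass flags (both strictly exceeded); defaults `1/sqrt(3)` and 0.5.
#' @return A tibble of class `chemical_scores`, one row per chemical:
#'   `chemical`, `n_conditions`, `cac_AhR`, `cac_Nrf2`, `cac_ATF4`,
#'   `n_genes_AhR`, ..., `cos_AhR`, ..., `module`, `score_AhR`, ...,
#'   `pass_AhR`, ..., `scorable`. Cut-offs are attached as attributes.
#' @export
score_chemicals <- function(matrix, partition, chemicals = NULL,
                            cos_cutoff = 1 / sqrt(3), module_cutoff = 0.5) {
  chemicals <- chemicals %||% fc_chemicals(matrix)
  excl <- lapply(pathway_ids(), function(p) exclusive_genes(partition, p))
  names(excl) <- pathway_ids()
  if (any(lengths(excl) == 0L)) {
    warn(paste0(
      "empty exclusive signature for pathway(s): ",
      paste(pathway_ids()[lengths(excl) == 0L], collapse = ", "),
      "; affected CAC coordinates are NA"
    ))
  }

  cond <- matrix$conditions
  cond$chem_key <- norm_chem(cond$chemical)
  vals <- dplyr::inner_join(
    matrix$values, cond[c("condition_id", "chem_key")],
    by = "condition_id"
  )
  keys <- norm_chem(chemicals)

  per_pathway <- lapply(pathway_ids(), function(p) {
    g <- excl[[p]]
    if (length(g) == 0L) {
      return(tibble(
        chem_key = character(0L),
        !!paste0("cac_", p) := numeric(0L),
        !!paste0("n_genes_", p) := integer(0L)
      ))
    }
    vals |>
      dplyr::filter(.data$gene %in% g) |>
      dplyr::group_by(.data$chem_key) |>
      dplyr::summarise(
        !!paste0("cac_", p) := mean(.data$log2fc),
        !!paste0("n_genes_", p) := dplyr::n_distinct(.data$gene),
        .groups = "drop"
      )
  })

  out <- tibble(chemical = chemicals, chem_key = keys)
  out$n_conditions <- vapply(
    keys, function(k) sum(cond$chem_key == k), integer(1L)
  )
  for (tab in per_pathway) {
    out <- dplyr::left_join(out, tab, by = "chem_key")
  }
  for (p in pathway_ids()) {
    nm <- paste0("n_genes_", p)
    if (!nm %in% names(out)) out[[nm]] <- NA_integer_
    out[[nm]][is.na(out[[nm]])] <- 0L
  }

  cac <- as.matrix(out[paste0("cac_", pathway_ids())])
  out$scorable <- rowSums(is.na(cac)) == 0L & out$n_conditions > 0L
  module <- sqrt(rowSums(cac^2))
  out$module <- ifelse(out$scorable, module, NA_real_)
  for (p in pathway_ids()) {
    ci <- ifelse(
      out$scorable & module > 0,
      abs(cac[, paste0("cac_", p)]) / module,
      ifelse(out$scorable, 0, NA_real_)
    )
    out[[paste0("cos_", p)]] <- ci
    out[[paste0("score_", p)]] <- ci * out$module
    out[[paste0("pass_", p)]] <-
      !is.na(ci) & ci > cos_cutoff & out$module > module_cutoff
  }
  out$chem_key <- NULL
  structure(
    out,
    class = c("chemical_scores", class(out)),
    cos_cutoff = cos_cutoff, module_cutoff = module_cutoff,
    key = partition$key
  )
}

#' Classify chemicals into pathway-specific potent activators
#'
#' A chemical is assigned to a pathway when (i) its specificity cosine for
#' that pathway strictly exceeds `cos_cutoff`, (ii) its potency module
#' strictly exceeds `module_cutoff`, and (iii) the pathway is its nearest
#' axis (strictly largest |cosine|). The nearest-axis condition is what
#' "specific" means geometrically; it guarantees a chemical lands in at
#' most one pathway list for any cut-off. (For cut-offs below `1/sqrt(2)`
#' the two cut-offs alone do not guarantee that: a chemical on a two-axis
#' diagonal has cosine `1/sqrt(2) = 0.707` to both axes.) Within each list
#' chemicals are ranked by decreasing score (cosine times module), ties
#' broken alphabetically. Because specificity uses |cos|, strong inhibitors
#' classify too; the signed CAC coordinate is carried so activators and
#' inhibitors stay distinguishable.
#'
#' @param scores A [score_chemicals()] tibble.
#' @param cos_cutoff Specificity cut-off in (0, 1\]; default `1/sqrt(3)`,
#'   the cosine of the equidistant direction.
#' @param module_cutoff Potency cut-off > 0; default 0.5.
#' @param nearest_axis If `TRUE` (default) require condition (iii) above.
#' @return An object of class `classification_result`: list with
#'   `per_pathway` (named list of tibbles `chemical`, `cac`, `cos_alpha`,
#'   `module`, `score`), `cos_cutoff`, `module_cutoff`, `not_scorable`
#'   (character vector).
#' @export
classify_chemicals <- function(scores, cos_cutoff = 1 / sqrt(3),
                               module_cutoff = 0.5, nearest_axis = TRUE) {
  if (!is.numeric(cos_cutoff) || cos_cutoff <= 0 || cos_cutoff > 1) {
    abort("`cos_cutoff` must be in (0, 1]", class = "toxsig_argument_error")
  }
  if (!is.numeric(module_cutoff) || module_cutoff <= 0) {
    abort("`module_cutoff` must be > 0", class = "toxsig_argument_error")
  }
  cos_mat <- as.matrix(scores[paste0("cos_", pathway_ids())])
  per_pathway <- lapply(seq_along(pathway_ids()), function(i) {
    p <- pathway_ids()[i]
    ok <- scores$scorable &
      cos_mat[, i] > cos_cutoff &
      scores$module > module_cutoff
    if (nearest_axis) {
      others <- cos_mat[, -i, drop = FALSE]
      ok <- ok & cos_mat[, i] > apply(others, 1L, max)
    }
    ok[is.na(ok)] <- FALSE
    sub <- tibble(
      chemical = scores$chemical[ok],
      cac = scores[[paste0("cac_", p)]][ok],
      cos_alpha = unname(cos_mat[ok, i]),
      module = scores$module[ok],
      score = scores[[paste0("score_", p)]][ok]
    )
    sub[order(-sub$score, sub$chemical), , drop = FALSE]
  })
  names(per_pathway) <- pathway_ids()
  structure(
    list(
      per_pathway = per_pathway,
      cos_cutoff = cos_cutoff, module_cutoff = module_cutoff,
      not_scorable = scores$chemical[!scores$scorable]
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(
    "<classification_result> cos > ", format(x$cos_cutoff, digits = 5),
    ", module > ", format(x$module_cutoff, digits = 5), "\n",
    sep = ""
  )
  for (p in pathway_ids()) {
    tab <- x$per_pathway[[p]]
    cat(
      "  ", p, ": ", nrow(tab), " chemical(s)",
      if (nrow(tab) > 0L) {
        paste0(" — top: ", paste(head(tab$chemical, 3L), collapse = ", "))
      },
      "\n",
      sep = ""
    )
  }
  if (length(x$not_scorable) > 0L) {
    cat("  not scorable: ", length(x$not_scorable), " chemical(s)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Export scatter-plot coordinates of specificity versus potency
#'
#' One row per chemical and pathway with the coordinates of the
#' potency-versus-specificity scatter: the chemical's rank in the
#' alphabetically ordered chemical list (stable across pathways), its
#' |cos alpha| for the pathway, its module, the score, and a raw pass flag
#' that is true iff both cut-offs are strictly exceeded (the dashed-limit
#' definition; classification additionally requires the nearest axis, see
#' [classify_chemicals()]).
#'
#' @param scores A [score_chemicals()] tibble.
#' @param cos_cutoff,module_cutoff Cut-offs for the pass flag; default to
#'   the ones stored on `scores`.
#' @return Tibble: `chemical`, `rank`, `pathway`, `cac`, `cos_alpha`,
#'   `module`, `score`, `pass`.
#' @export
export_scatter_data <- function(scores,
                                cos_cutoff = attr(scores, "cos_cutoff"),
                                module_cutoff = attr(scores, "module_cutoff")) {
  ord <- order(scores$chemical)
  rank_of <- integer(nrow(scores))
  rank_of[ord] <- seq_len(nrow(scores))
  rows <- lapply(pathway_ids(), function(p) {
    ci <- scores[[paste0("cos_", p)]]
    tibble(
      chemical = scores$chemical,
      rank = rank_of,
      pathway = p,
      cac = scores[[paste0("cac_", p)]],
      cos_alpha = ci,
      module = scores$module,
      score = scores[[paste0("score_", p)]],
      pass = !is.na(ci) & ci > cos_cutoff &
        !is.na(scores$module) & scores$module > module_cutoff
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$rank, factor(.data$pathway, levels = pathway_ids()))
}
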