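#' Write the seven signature zone tables
#'
#' One delimited (TSV) table per Venn zone: three exclusive signatures and
#' four overlap signatures. Exclusive tables carry the pathway's average
#' activation value and an `section` column (`activated` / `inhibited`);
#' overlap tables carry one value column per member pathway and merge the
#' two sections, as overlap genes can disagree in sign between pathways.
#' Rows are sorted by decreasing absolute average (the largest member-value
#' magnitude for overlap zones), ties broken alphabetically by gene symbol.
#' When a catalog is supplied, an `a_priori_pathway` column is appended for
#' comparison of derived versus curated membership.
#'
#' @param set A [build_signatures()] result.
#' @param partition The matching [partition_overlaps()] result.
#' @param dir Output directory (created if needed); files are named
#'   `signature_<zone>.tsv` with `-` replaced by `_`.
#' @param catalog Optional [gene_catalog()].
#' @return Named character vector of the seven file paths, invisibly.
#' @export
write_signature_tables <- function(set, partition, dir, catalog = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) {
    abort(paste0("cannot create output directory: ", dir),
      class = "toxsig_io_error"
    )
  }
  paths <- character(0L)
  for (zone in .zone_names) {
    members <- zone_pathways(zone)
    genes <- partition$zones[[zone]]
    vals <- partition$values[
      match(genes, partition$values$gene), ,
      drop = FALSE
    ]
    tab <- tibble(gene = genes)
    for (p in members) {
      tab[[paste0("value_", p)]] <- vals[[paste0("value_", p)]]
    }
    if (length(members) == 1L) {
      tab$section <- ifelse(tab[[paste0("value_", members)]] > 0,
        "activated", "inhibited"
      )
    }
    key <- if (nrow(tab) > 0L) {
      do.call(
        pmax,
        c(lapply(members, function(p) abs(tab[[paste0("value_", p)]])),
          na.rm = TRUE
        )
      )
    } else {
      numeric(0L)
    }
    tab <- tab[order(-key, tab$gene), , drop = FALSE]
    if (!is.null(catalog)) {
      tab$a_priori_pathway <- a_priori_pathways(catalog, tab$gene)
    }
    path <- file.path(
      dir, paste0("signature_", gsub("-", "_", zone), ".tsv")
    )
    readr::write_tsv(tab, path, na = "")
    paths[zone] <- path
  }
  invisible(paths)
}

#' Re-read signature zone tables written by [write_signature_tables()]
#'
#' @param dir Directory containing the seven `signature_*.tsv` files.
#' @return Named list of tibbles, one per zone.
#' @export
read_signature_tables <- function(dir) {
  out <- lapply(.zone_names, function(zone) {
    path <- file.path(
      dir, paste0("signature_", gsub("-", "_", zone), ".tsv")
    )
    if (!file.exists(path)) {
      abort(paste0("missing signature table: ", path),
        class = "toxsig_io_error"
      )
    }
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  })
  names(out) <- .zone_names
  out
}
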