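#' Partition three pathway signatures into exclusive and overlapping zones
#'
#' Genes appearing in the signature (activated or inhibited) of more than
#' one pathway are set apart into overlapping signatures. The result is the
#' 7-zone Venn partition of the three signatures: three exclusive zones,
#' three pairwise overlaps and the triple overlap. Zones are mutually
#' disjoint and jointly cover the union of the signatures (asserted on
#' every call). Per-gene average activation values of every member pathway
#' are carried along for reporting, since overlap genes may disagree in
#' sign between pathways.
#'
#' @param set A [build_signatures()] result (`signature_set`).
#' @return An object of class `overlap_partition`: list with
#'   * `zones`: named list of sorted gene vectors, names
#'     `AhR`, `Nrf2`, `ATF4` (exclusive), `AhR-Nrf2`, `Nrf2-ATF4`,
#'     `AhR-ATF4`, `AhR-Nrf2-ATF4`;
#'   * `values`: tibble `gene`, `zone`, plus one `value_<pathway>` column
#'     per pathway (`NA` where the gene is not in that pathway's
#'     signature);
#'   * `key`: the category key the signatures were computed on.
#' @export
partition_overlaps <- function(set) {
  if (!inherits(set, "signature_set")) {
    abort("`set` must be a signature_set", class = "toxsig_argument_error")
  }
  members <- lapply(set$signatures, signature_genes)
  all_genes <- sort(unique(unlist(members)))
  in_p <- vapply(
    pathway_ids(), function(p) all_genes %in% members[[p]],
    logical(length(all_genes))
  )
  in_p <- matrix(in_p,
    nrow = length(all_genes), ncol = 3L,
    dimnames = list(all_genes, pathway_ids())
  )
  zone_of <- apply(in_p, 1L, function(row) {
    paste(pathway_ids()[row], collapse = "-")
  })
  zones <- lapply(.zone_names, function(z) {
    sort(all_genes[zone_of == z])
  })
  names(zones) <- .zone_names

  # disjointness and coverage are structural invariants; fail loudly if
  # the membership algebra is ever broken
  stopifnot(
    sum(lengths(zones)) == length(all_genes),
    !anyDuplicated(unlist(zones))
  )

  sig_values <- lapply(set$signatures, function(s) {
    dplyr::bind_rows(s$activated, s$inhibited)
  })
  values <- tibble(gene = all_genes, zone = unname(zone_of[all_genes]))
  for (p in pathway_ids()) {
    sv <- sig_values[[p]]
    values[[paste0("value_", p)]] <- sv$value[match(all_genes, sv$gene)]
  }

  structure(
    list(zones = zones, values = values, key = set$key),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("<overlap_partition> 7 zones, ", nrow(x$values), " genes\n", sep = "")
  for (z in .zone_names) {
    cat("  ", format(z, width = 14), length(x$zones[[z]]), "\n", sep = " ")
  }
  invisible(x)
}

#' Exclusive signature genes of one pathway
#'
#' The genes belonging to the pathway's signature but to no other
#' pathway's; chemicals are scored on these genes only, so that a shared
#' responder cannot credit several pathways at once.
#'
#' @param partition An [partition_overlaps()] result.
#' @param pathway One of [pathway_ids()].
#' @return Sorted character vector (activated and inhibited genes alike).
#' @export
exclusive_genes <- function(partition, pathway) {
  assert_pathway(pathway)
  partition$zones[[pathway]]
}

#' Venn zone summary
#'
#' @param partition An [partition_overlaps()] result.
#' @return Tibble with one row per zone: `zone`, `n_genes`, `genes`
#'   (comma-separated, alphabetical).
#' @export
venn_summary <- function(partition) {
  tibble(
    zone = .zone_names,
    n_genes = unname(
      vapply(partition$zones[.zone_names], length, integer(1L))
    ),
    genes = unname(vapply(
      partition$zones[.zone_names],
      function(g) paste(g, collapse = ","), character(1L)
    ))
  )
}
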