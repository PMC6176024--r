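#' Per-gene mean log2 fold change under one activator chemical
#'
#' Over all conditions of the given activator present in `matrix`, computes
#' for every gene the arithmetic mean of its available log2 fold changes.
#' Genes with no value under any of the activator's conditions are omitted
#' (missing is "not measured", never zero).
#'
#' @param matrix An [fc_matrix()], already filtered to the time window and
#'   category of interest.
#' @param activator Chemical name (matched case-insensitively after
#'   whitespace normalisation).
#' @return Named numeric vector, gene -> mean log2FC, sorted by gene symbol.
#'   Empty (with a warning) when the activator has no conditions.
#' @export
per_activator_gene_means <- function(matrix, activator) {
  ids <- matrix$conditions$condition_id[
    norm_chem(matrix$conditions$chemical) == norm_chem(activator)
  ]
  if (length(ids) == 0L) {
    warn(
      paste0("activator ", activator, " has no conditions in this dataset"),
      class = "toxsig_uncovered_activator"
    )
    return(setNames(numeric(0L), character(0L)))
  }
  vals <- matrix$values[matrix$values$condition_id %in% ids, , drop = FALSE]
  if (nrow(vals) == 0L) {
    return(setNames(numeric(0L), character(0L)))
  }
  means <- tapply(vals$log2fc, vals$gene, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out[order(names(out))]
}

#' Combine per-activator gene means into average activation values
#'
#' Unweighted mean of the per-activator means, over the activators in which
#' each gene has data (mean of means, not a pooled mean over conditions —
#' with unequal condition counts per activator the two differ, and the
#' mean-of-means weights each reference chemical equally). Genes covered by
#' only a subset of activators are averaged over that subset unless
#' `require_all` is set, in which case they are dropped.
#'
#' @param means List of named numeric vectors as returned by
#'   [per_activator_gene_means()]; at least one.
#' @param require_all If `TRUE`, keep only genes with data under every
#'   activator. Default `FALSE`: average over available activators.
#' @return Named numeric vector, gene -> average activation value.
#' @export
combine_activator_means <- function(means, require_all = FALSE) {
  if (length(means) == 0L) {
    abort("`means` must contain at least one mapping",
      class = "toxsig_argument_error"
    )
  }
  means <- means[lengths(means) > 0L]
  if (length(means) == 0L) {
    warn("all per-activator mappings are empty")
    return(setNames(numeric(0L), character(0L)))
  }
  genes <- sort(unique(unlist(lapply(means, names))))
  mat <- vapply(
    means, function(m) unname(m[genes]),
    numeric(length(genes))
  )
  mat <- matrix(mat, nrow = length(genes))
  n_obs <- rowSums(!is.na(mat))
  combined <- rowMeans(mat, na.rm = TRUE)
  names(combined) <- genes
  if (require_all) combined <- combined[n_obs == ncol(mat)]
  combined[!is.nan(combined)]
}

#' Pathway activation profile
#'
#' For one pathway: selects all conditions of its configured activator
#' chemicals, computes per-activator per-gene mean log2FC, averages those
#' means across activators into each gene's average activation value, and
#' summarises the distribution of those values by its mean `mu` and
#' standard deviation `sigma`. Genes with no data under any activator
#' condition are excluded from the distribution and listed in
#' `excluded_genes`.
#'
#' @param matrix An [fc_matrix()], already time/category filtered.
#' @param pathway One of [pathway_ids()].
#' @param config An [activator_config()] covering `pathway`.
#' @param sd_type `"population"` (divisor N, the default) or `"sample"`
#'   (divisor N-1); immaterial at the ~800-gene scale of real catalogs but
#'   documented and configurable.
#' @param require_all_activators Passed to [combine_activator_means()].
#' @return An object of class `activation_profile` with elements `pathway`,
#'   `activators`, `per_activator_means`, `combined` (named numeric),
#'   `mu`, `sigma`, `sd_type`, `excluded_genes`, `n_conditions` (per
#'   activator, named).
#' @export
compute_profile <- function(matrix, pathway, config,
                            sd_type = c("population", "sample"),
                            require_all_activators = FALSE) {
  assert_pathway(pathway)
  sd_type <- match.arg(sd_type)
  activators <- config[[pathway]]
  if (is.null(activators) || length(activators) == 0L) {
    abort(
      paste0("activator config does not cover pathway ", pathway),
      class = "toxsig_config_error"
    )
  }
  have <- norm_chem(matrix$conditions$chemical)
  n_cond <- vapply(
    activators, function(a) sum(have == norm_chem(a)), integer(1L)
  )
  names(n_cond) <- activators
  if (sum(n_cond) == 0L) {
    abort(
      paste0(
        "no conditions for any ", pathway, " activator (",
        paste(activators, collapse = ", "), ") in this dataset/category"
      ),
      class = "toxsig_no_activator_error"
    )
  }
  per_act <- lapply(activators[n_cond > 0L], function(a) {
    per_activator_gene_means(matrix, a)
  })
  names(per_act) <- activators[n_cond > 0L]
  if (any(n_cond == 0L)) {
    warn(
      paste0(
        "uncovered ", pathway, " activator(s): ",
        paste(activators[n_cond == 0L], collapse = ", ")
      ),
      class = "toxsig_uncovered_activator"
    )
  }
  combined <- combine_activator_means(per_act,
    require_all = require_all_activators
  )
  excluded <- setdiff(matrix$genes, names(combined))
  mu <- if (length(combined) > 0L) mean(combined) else NA_real_
  sigma <- if (length(combined) > 0L) {
    if (sd_type == "population") {
      sqrt(mean((combined - mu)^2))
    } else {
      stats::sd(combined)
    }
  } else {
    NA_real_
  }
  structure(
    list(
      pathway = pathway,
      activators = activators,
      per_activator_means = per_act,
      combined = combined,
      mu = mu,
      sigma = sigma,
      sd_type = sd_type,
      excluded_genes = excluded,
      n_conditions = n_cond
    ),
    class = "activation_profile"
  )
}

#' @export
print.activation_profile <- function(x, ...) {
  cat(
    "<activation_profile> ", x$pathway, ": ", length(x$combined),
    " genes with data, ", length(x$excluded_genes), " excluded; mu = ",
    format(x$mu, digits = 4), ", sigma = ", format(x$sigma, digits = 4),
    " (", x$sd_type, ")\n  activators: ",
    paste0(names(x$n_conditions), " (", x$n_conditions, ")",
      collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Threshold an activation profile into a pathway signature
#'
#' The signature keeps the genes in the tails of the average activation
#' value distribution: activated genes have values strictly greater than
#' `mu + sigma_mult * sigma` and strictly positive; inhibited genes have
#' values strictly smaller than `mu - sigma_mult * sigma` and strictly
#' negative. The sign guards prevent a gene from being called activated on
#' a negative average (or vice versa) when `mu` itself is far from zero.
#' With `sigma = 0` the strict inequalities admit nothing and the signature
#' is empty (with a warning). Within each section genes are ordered by
#' decreasing absolute value, ties broken alphabetically.
#'
#' @param profile An [compute_profile()] result.
#' @param sigma_mult Positive multiplier of `sigma` (default 2).
#' @return An object of class `pathway_signature` with elements `pathway`,
#'   `activated` and `inhibited` (tibbles with columns `gene`, `value`),
#'   `mu`, `sigma`, `sigma_mult`.
#' @export
threshold_signature <- function(profile, sigma_mult = 2) {
  if (!is.numeric(sigma_mult) || length(sigma_mult) != 1L || sigma_mult <= 0) {
    abort("`sigma_mult` must be a single positive number",
      class = "toxsig_argument_error"
    )
  }
  v <- profile$combined
  empty <- tibble(gene = character(0L), value = numeric(0L))
  if (length(v) == 0L) {
    warn(paste0("profile for ", profile$pathway, " has no genes with data"))
    act <- inh <- empty
  } else {
    if (profile$sigma == 0) {
      warn(paste0(
        "sigma = 0 for ", profile$pathway,
        ": all average activation values identical, signature is empty"
      ))
    }
    hi <- profile$mu + sigma_mult * profile$sigma
    lo <- profile$mu - sigma_mult * profile$sigma
    pick <- function(mask) {
      g <- names(v)[mask]
      val <- unname(v[mask])
      ord <- order(-abs(val), g)
      tibble(gene = g[ord], value = val[ord])
    }
    act <- pick(v > hi & v > 0)
    inh <- pick(v < lo & v < 0)
  }
  structure(
    list(
      pathway = profile$pathway, activated = act, inhibited = inh,
      mu = profile$mu, sigma = profile$sigma, sigma_mult = sigma_mult
    ),
    class = "pathway_signature"
  )
}

#' @export
print.pathway_signature <- function(x, ...) {
  cat(
    "<pathway_signature> ", x$pathway, ": ", nrow(x$activated),
    " activated + ", nrow(x$inhibited), " inhibited genes (mu ",
    format(x$mu, digits = 3), " +/- ", x$sigma_mult, " x sigma ",
    format(x$sigma, digits = 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Genes of a pathway signature
#'
#' @param signature A [threshold_signature()] result.
#' @return Character vector: activated and inhibited gene symbols.
#' @export
signature_genes <- function(signature) {
  c(signature$activated$gene, signature$inhibited$gene)
}

# empty placeholder used when a category lacks any activator for a pathway
unavailable_signature <- function(pathway, reason) {
  empty <- tibble(gene = character(0L), value = numeric(0L))
  structure(
    list(
      pathway = pathway, activated = empty, inhibited = empty,
      mu = NA_real_, sigma = NA_real_, sigma_mult = NA_real_
    ),
    class = "pathway_signature", unavailable = TRUE, reason = reason
  )
}

#' Derive the three pathway signatures on one category
#'
#' Convenience wrapper running [compute_profile()] and
#' [threshold_signature()] for every pathway on the (optionally
#' category-selected) matrix. A pathway whose activators have no conditions
#' in the selected category yields an empty signature marked unavailable
#' (with a warning) rather than an error, so stratified runs over sparse
#' categories complete.
#'
#' @inheritParams compute_profile
#' @inheritParams threshold_signature
#' @param key Optional [category_key()] applied with [select_category()]
#'   before profiling.
#' @return An object of class `signature_set`: list with `signatures` and
#'   `profiles` (both named by pathway; a profile is `NULL` when
#'   unavailable) and `key`.
#' @export
build_signatures <- function(matrix, config, key = NULL, sigma_mult = 2,
                             sd_type = c("population", "sample"),
                             require_all_activators = FALSE) {
  sd_type <- match.arg(sd_type)
  sub <- if (is.null(key)) matrix else select_category(matrix, key)
  profiles <- list()
  signatures <- list()
  for (p in pathway_ids()) {
    prof <- tryCatch(
      compute_profile(sub, p, config,
        sd_type = sd_type,
        require_all_activators = require_all_activators
      ),
      toxsig_config_error = function(e) e,
      toxsig_no_activator_error = function(e) e
    )
    if (inherits(prof, "condition")) {
      warn(paste0(
        "signature for ", p,
        if (!is.null(key)) paste0(" in category ", format(key)),
        " unavailable: ", conditionMessage(prof)
      ))
      profiles[p] <- list(NULL)
      signatures[[p]] <- unavailable_signature(p, conditionMessage(prof))
    } else {
      profiles[[p]] <- prof
      signatures[[p]] <- threshold_signature(prof, sigma_mult = sigma_mult)
    }
  }
  structure(
    list(signatures = signatures, profiles = profiles, key = key),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(
    "<signature_set>",
    if (!is.null(x$key)) paste0(" [", format(x$key), "]"), "\n",
    sep = ""
  )
  for (s in x$signatures) {
    cat(
      "  ", s$pathway, ": ", nrow(s$activated), " activated, ",
      nrow(s$inhibited), " inhibited",
      if (isTRUE(attr(s, "unavailable"))) "  (unavailable)", "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Stratified signature sets
#'
#' Runs [build_signatures()] once per category key, mirroring the
#' per-category stratification (all liver, rat liver in vitro, rat liver in
#' vivo, human liver in vitro, ...) used to probe species and in-vitro /
#' in-vivo differences between signatures.
#'
#' @inheritParams build_signatures
#' @param keys Non-empty list of [category_key()] objects.
#' @return Named list of `signature_set` objects (names from
#'   `format(key)`).
#' @export
stratified_signatures <- function(matrix, config, keys, sigma_mult = 2,
                                  sd_type = c("population", "sample")) {
  if (length(keys) == 0L) {
    abort("`keys` must be non-empty", class = "toxsig_argument_error")
  }
  sd_type <- match.arg(sd_type)
  out <- lapply(keys, function(k) {
    build_signatures(matrix, config,
      key = k, sigma_mult = sigma_mult,
      sd_type = sd_type
    )
  })
  names(out) <- vapply(keys, format, character(1L))
  out
}
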