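# independent brute-force oracles: plain loops, no shared code with the
# implementation under test

bf_activator_means <- function(matrix, activator) {
  cond <- fc_conditions(matrix)
  vals <- fc_values(matrix)
  canon <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  ids <- cond$condition_id[canon(cond$chemical) == canon(activator)]
  out <- numeric(0)
  for (g in sort(unique(vals$gene))) {
    xs <- c()
    for (id in ids) {
      xs <- c(xs, vals$log2fc[vals$condition_id == id & vals$gene == g])
    }
    if (length(xs) > 0) out[g] <- sum(xs) / length(xs)
  }
  out
}

bf_combine <- function(means_list) {
  means_list <- means_list[vapply(means_list, length, 1L) > 0]
  genes <- sort(unique(unlist(lapply(means_list, names))))
  out <- numeric(0)
  for (g in genes) {
    xs <- c()
    for (m in means_list) {
      if (g %in% names(m)) xs <- c(xs, m[[g]])
    }
    out[g] <- sum(xs) / length(xs)
  }
  out
}

bf_mu_sigma <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  list(mu = mu, sigma = sqrt(sum((v - mu)^2) / n))
}

# 2^3 membership-label oracle for the Venn partition
bf_partition <- function(genes_ahr, genes_nrf2, genes_atf4) {
  zones <- list(
    "AhR" = character(0), "Nrf2" = character(0), "ATF4" = character(0),
    "AhR-Nrf2" = character(0), "Nrf2-ATF4" = character(0),
    "AhR-ATF4" = character(0), "AhR-Nrf2-ATF4" = character(0)
  )
  for (g in sort(unique(c(genes_ahr, genes_nrf2, genes_atf4)))) {
    m <- c(g %in% genes_ahr, g %in% genes_nrf2, g %in% genes_atf4)
    label <- paste(c("AhR", "Nrf2", "ATF4")[m], collapse = "-")
    zones[[label]] <- c(zones[[label]], g)
  }
  zones
}

# double loop over conditions x genes
bf_cac <- function(matrix, chemical, genes) {
  cond <- fc_conditions(matrix)
  vals <- fc_values(matrix)
  canon <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  ids <- cond$condition_id[canon(cond$chemical) == canon(chemical)]
  xs <- c()
  for (id in ids) {
    for (g in genes) {
      xs <- c(xs, vals$log2fc[vals$condition_id == id & vals$gene == g])
    }
  }
  if (length(xs) == 0) {
    return(NA_real_)
  }
  sum(xs) / length(xs)
}

# pooled-over-conditions mean (the estimator the method does NOT use)
bf_pooled_mean <- function(matrix, activators, gene) {
  cond <- fc_conditions(matrix)
  vals <- fc_values(matrix)
  canon <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  ids <- cond$condition_id[canon(cond$chemical) %in% canon(activators)]
  xs <- vals$log2fc[vals$condition_id %in% ids & vals$gene == gene]
  sum(xs) / length(xs)
}
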