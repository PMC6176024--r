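# in-code fixtures: no data files, everything built at test time

mk_conditions <- function(n,
                          chemical = "ChemA",
                          species = "human", tissue = "liver",
                          setting = "in_vitro", dosing = "bolus",
                          time_h = 24,
                          ids = sprintf("c%03d", seq_len(n))) {
  tibble::tibble(
    condition_id = ids,
    chemical = rep_len(chemical, n),
    species = rep_len(species, n),
    tissue = rep_len(tissue, n),
    setting = rep_len(setting, n),
    dosing = rep_len(dosing, n),
    time_h = rep_len(time_h, n),
    dose_label = "d1",
    project = "test"
  )
}

# dense-ish random matrix with mixed metadata, for oracle comparisons
random_fc <- function(seed, n_genes = 50, n_cond = 30,
                      chemicals = paste0("Chem", LETTERS[1:5]),
                      missing_frac = 0.1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  cond <- tibble::tibble(
    condition_id = sprintf("c%03d", seq_len(n_cond)),
    chemical = sample(chemicals, n_cond, replace = TRUE),
    species = sample(c("human", "rat"), n_cond, replace = TRUE),
    tissue = sample(c("liver", "kidney"), n_cond, replace = TRUE),
    setting = sample(c("in_vitro", "in_vivo"), n_cond, replace = TRUE),
    dosing = sample(c("bolus", "repeated"), n_cond, replace = TRUE),
    time_h = sample(c(2, 6, 24, 72), n_cond, replace = TRUE),
    dose_label = sample(c("low", "high"), n_cond, replace = TRUE),
    project = "test"
  )
  vals <- tidyr::expand_grid(condition_id = cond$condition_id, gene = genes)
  vals$log2fc <- round(stats::rnorm(nrow(vals)), 6)
  vals <- vals[stats::runif(nrow(vals)) >= missing_frac, , drop = FALSE]
  fc_matrix(cond, vals, genes = genes)
}

# a chemical_scores-shaped tibble built straight from CAC vectors, for
# geometry tests that do not need a dataset
scores_from_vectors <- function(vectors) {
  cac <- do.call(rbind, vectors)
  module <- sqrt(rowSums(cac^2))
  out <- tibble::tibble(
    chemical = sprintf("V%04d", seq_along(vectors)),
    n_conditions = 1L
  )
  for (i in seq_along(pathway_ids())) {
    p <- pathway_ids()[i]
    out[[paste0("cac_", p)]] <- cac[, i]
    out[[paste0("n_genes_", p)]] <- 1L
  }
  out$scorable <- TRUE
  out$module <- module
  for (i in seq_along(pathway_ids())) {
    p <- pathway_ids()[i]
    ci <- ifelse(module > 0, abs(cac[, i]) / module, 0)
    out[[paste0("cos_", p)]] <- ci
    out[[paste0("score_", p)]] <- ci * module
    out[[paste0("pass_", p)]] <- ci > 1 / sqrt(3) & module > 0.5
  }
  out
}
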