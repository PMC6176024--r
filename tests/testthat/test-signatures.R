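test_that("per-activator means average available values and skip no-data genes", {
  cond <- mk_conditions(3, chemical = c("Phorone", "Phorone", "Other"),
                        ids = c("a1", "a2", "x1"))
  vals <- tibble::tibble(
    condition_id = c("a1", "a2", "a1", "x1"),
    gene = c("G1", "G1", "G2", "G3"),
    log2fc = c(1.0, 3.0, 0.5, 9.9)
  )
  m <- fc_matrix(cond, vals, genes = c("G1", "G2", "G3", "G4"))
  means <- per_activator_gene_means(m, "phorone")
  expect_equal(means[["G1"]], 2.0)
  expect_equal(means[["G2"]], 0.5)
  expect_false("G3" %in% names(means)) # only measured under another chemical
  expect_false("G4" %in% names(means)) # never measured at all
  expect_warning(
    none <- per_activator_gene_means(m, "Absent"),
    class = "toxsig_uncovered_activator"
  )
  expect_length(none, 0L)
})

test_that("combining is a mean of means over available activators", {
  a <- c(g = 1.0, h = 0.8)
  b <- c(g = 0.0)
  comb <- combine_activator_means(list(a, b))
  expect_equal(comb[["g"]], 0.5) # mean of the two activator means
  expect_equal(comb[["h"]], 0.8) # single-activator gene passes through
  expect_equal(
    combine_activator_means(list(a, b), require_all = TRUE),
    c(g = 0.5)
  )
  expect_warning(
    empty <- combine_activator_means(list(numeric(0), numeric(0)))
  )
  expect_length(empty, 0L)
})

test_that("mean-of-means differs from the pooled mean under unequal counts", {
  # activator A: 3 conditions, activator B: 1 condition, same gene
  cond <- mk_conditions(4, chemical = c("A", "A", "A", "B"),
                        ids = sprintf("c%d", 1:4))
  vals <- tibble::tibble(
    condition_id = sprintf("c%d", 1:4),
    gene = "G1",
    log2fc = c(1, 1, 1, 5)
  )
  m <- fc_matrix(cond, vals)
  comb <- combine_activator_means(list(
    per_activator_gene_means(m, "A"),
    per_activator_gene_means(m, "B")
  ))
  expect_equal(comb[["G1"]], 3) # (1 + 5) / 2
  pooled <- bf_pooled_mean(m, c("A", "B"), "G1")
  expect_equal(pooled, 2) # (1+1+1+5) / 4
  expect_false(isTRUE(all.equal(comb[["G1"]], pooled)))

  # with equal condition counts the two estimators coincide
  m_eq <- fc_matrix(
    mk_conditions(4, chemical = c("A", "A", "B", "B"),
                  ids = sprintf("e%d", 1:4)),
    tibble::tibble(
      condition_id = sprintf("e%d", 1:4), gene = "G1",
      log2fc = c(1, 3, 2, 6)
    )
  )
  comb_eq <- combine_activator_means(list(
    per_activator_gene_means(m_eq, "A"),
    per_activator_gene_means(m_eq, "B")
  ))
  expect_equal(comb_eq[["G1"]], bf_pooled_mean(m_eq, c("A", "B"), "G1"))
})

test_that("profile mu/sigma follow the closed form and exclusions", {
  # four genes with combined values {0, 0, 0, 10} under one activator
  cond <- mk_conditions(1, chemical = "Tunicamycin", ids = "c1")
  vals <- tibble::tibble(
    condition_id = "c1",
    gene = c("G1", "G2", "G3", "G4"),
    log2fc = c(0, 0, 0, 10)
  )
  m <- fc_matrix(cond, vals, genes = c("G1", "G2", "G3", "G4", "G5"))
  cfg <- activator_config(AhR = "u1", Nrf2 = "u2", ATF4 = "Tunicamycin")
  prof <- compute_profile(m, "ATF4", cfg)
  expect_equal(prof$mu, 2.5)
  expect_equal(prof$sigma, sqrt((3 * 2.5^2 + 7.5^2) / 4)) # population SD
  expect_equal(prof$excluded_genes, "G5")
  prof_s <- compute_profile(m, "ATF4", cfg, sd_type = "sample")
  expect_equal(prof_s$sigma, stats::sd(c(0, 0, 0, 10)))

  # a pathway with no activator conditions errors with its name
  expect_error(
    suppressWarnings(compute_profile(m, "AhR", cfg)),
    "AhR",
    class = "toxsig_no_activator_error"
  )
})

test_that("thresholding keeps the tails with sign guards and ordering", {
  mk_profile <- function(values) {
    mu <- mean(values)
    structure(
      list(
        pathway = "AhR", combined = values, mu = mu,
        sigma = sqrt(mean((values - mu)^2)), sd_type = "population",
        excluded_genes = character(0)
      ),
      class = "activation_profile"
    )
  }

  v <- setNames(
    c(rep(0.1, 98), 5, -5),
    c(sprintf("bg%02d", 1:98), "UP", "DOWN")
  )
  sig <- threshold_signature(mk_profile(v))
  expect_equal(sig$activated$gene, "UP")
  expect_equal(sig$inhibited$gene, "DOWN")

  # all equal -> sigma 0 -> empty signature with a warning
  flat <- setNames(rep(0.3, 10), paste0("g", 1:10))
  expect_warning(empty <- threshold_signature(mk_profile(flat)), "sigma")
  expect_equal(nrow(empty$activated) + nrow(empty$inhibited), 0L)

  # a value above mu + 2 sigma but negative is not "activated"
  v2 <- setNames(c(-10, -10, -10, -10, -1), paste0("g", 1:5))
  sig2 <- threshold_signature(mk_profile(v2))
  expect_equal(nrow(sig2$activated), 0L)
  expect_equal(nrow(sig2$inhibited), 0L)

  # ordering: decreasing |value|, alphabetical ties
  v3 <- setNames(c(0.01, 0.01, 0.9, -1.2, 0.9), c("a", "b", "zz", "dn", "aa"))
  sig3 <- threshold_signature(mk_profile(v3), sigma_mult = 1)
  expect_equal(sig3$activated$gene, c("aa", "zz"))
  expect_equal(sig3$inhibited$gene, "dn")
})

test_that("signature derivation matches brute-force oracles on random data", {
  for (seed in 61:63) {
    m <- random_fc(seed, n_genes = 25, n_cond = 20,
                   chemicals = c("ActA", "ActB", "Other"))
    cfg <- activator_config(AhR = c("ActA", "ActB"), Nrf2 = "Other",
                            ATF4 = "ActA")
    for (act in c("ActA", "ActB")) {
      expect_equal(
        per_activator_gene_means(m, act),
        bf_activator_means(m, act)
      )
    }
    prof <- compute_profile(m, "AhR", cfg)
    combined_bf <- bf_combine(list(
      bf_activator_means(m, "ActA"), bf_activator_means(m, "ActB")
    ))
    expect_equal(prof$combined, combined_bf)
    ms <- bf_mu_sigma(combined_bf)
    expect_equal(prof$mu, ms$mu)
    expect_equal(prof$sigma, ms$sigma)
  }
})

test_that("signatures are invariant under row order and scale equivariant", {
  m <- random_fc(71, n_genes = 30, n_cond = 15,
                 chemicals = c("ActA", "ActB"))
  cfg <- activator_config(AhR = c("ActA", "ActB"), Nrf2 = "ActA",
                          ATF4 = "ActB")

  set.seed(72)
  perm_vals <- fc_values(m)[sample(nrow(fc_values(m))), ]
  perm_cond <- fc_conditions(m)[sample(nrow(fc_conditions(m))), ]
  m_perm <- fc_matrix(perm_cond, perm_vals, genes = fc_genes(m))
  s1 <- threshold_signature(compute_profile(m, "AhR", cfg))
  s2 <- threshold_signature(compute_profile(m_perm, "AhR", cfg))
  expect_equal(s1$activated, s2$activated)
  expect_equal(s1$inhibited, s2$inhibited)

  # scaling all values by c > 0 scales mu, sigma, values; membership fixed
  c_scale <- 3.7
  vals_sc <- dplyr::mutate(fc_values(m), log2fc = .data$log2fc * c_scale)
  m_sc <- fc_matrix(fc_conditions(m), vals_sc, genes = fc_genes(m))
  p1 <- compute_profile(m, "AhR", cfg)
  p2 <- compute_profile(m_sc, "AhR", cfg)
  expect_equal(p2$mu, c_scale * p1$mu)
  expect_equal(p2$sigma, c_scale * p1$sigma)
  s1s <- threshold_signature(p1)
  s2s <- threshold_signature(p2)
  expect_equal(s2s$activated$gene, s1s$activated$gene)
  expect_equal(s2s$inhibited$gene, s1s$inhibited$gene)
  expect_equal(s2s$activated$value, c_scale * s1s$activated$value)
})

test_that("stratified runs cover keys and survive missing activators", {
  cfg <- study_mimic_config(seed = 81)
  d <- generate_synthetic(cfg)
  keys <- list(
    category_key(tissue = "liver"),
    category_key(species = "human", tissue = "liver", setting = "in_vitro"),
    category_key(species = "rat") # nothing: mimic data are all human
  )
  suppressWarnings(sets <- stratified_signatures(d$matrix, d$activators, keys))
  expect_length(sets, 3L)
  expect_named(sets, vapply(keys, format, character(1)))
  # the empty category yields unavailable (empty) signatures, not an error
  rat <- sets[[3]]
  expect_true(all(vapply(
    rat$signatures, function(s) nrow(s$activated) + nrow(s$inhibited) == 0L,
    logical(1)
  )))
  # the populated categories recover the planted AhR set
  expect_gt(nrow(sets[[1]]$signatures$AhR$activated), 20L)
})
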