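test_that("axis cosine and module follow the vector geometry", {
  expect_equal(axis_cosine(c(1, 1, 1), "AhR"), 1 / sqrt(3))
  expect_equal(round(axis_cosine(c(1, 1, 1), "Nrf2"), 5), 0.57735)
  expect_equal(axis_cosine(c(1, 0, 0), "AhR"), 1)
  expect_equal(axis_cosine(c(0, -2, 0), "Nrf2"), 1) # |cos|: inhibitors count
  expect_equal(vector_module(c(0, 0, 0)), 0)
  expect_equal(vector_module(c(3, 4, 0)), 5)
  expect_equal(vector_module(c(-0.3, 0.4, 0)), 0.5) # exactly on the cut-off
  expect_true(is.na(axis_cosine(c(0, 0, 0), "AhR"))) # undefined angle

  # random vectors match the dot-product formula against each basis axis
  set.seed(101)
  basis <- diag(3)
  for (i in 1:50) {
    v <- stats::rnorm(3)
    for (ax in 1:3) {
      expect_equal(
        axis_cosine(v, pathway_ids()[ax]),
        abs(sum(v * basis[, ax])) / (sqrt(sum(v^2)) * 1)
      )
    }
  }
})

test_that("chemical CAC equals the brute-force mean over conditions x genes", {
  cond <- mk_conditions(2, chemical = "ChemK", ids = c("k1", "k2"))
  vals <- tibble::tibble(
    condition_id = c("k1", "k1"),
    gene = c("g1", "g2"),
    log2fc = c(0.4, 0.8)
  )
  m <- fc_matrix(cond, vals)
  expect_equal(chemical_cac(m, "ChemK", c("g1", "g2")), 0.6)

  # negative values give a negative CAC
  m_neg <- fc_matrix(cond, dplyr::mutate(vals, log2fc = -.data$log2fc))
  expect_lt(chemical_cac(m_neg, "chemk", c("g1", "g2")), 0)

  # missing chemical and missing data are flagged NA with a warning
  expect_warning(na1 <- chemical_cac(m, "Nope", "g1"))
  expect_true(is.na(na1))
  expect_warning(na2 <- chemical_cac(m, "ChemK", "g99"))
  expect_true(is.na(na2))
  expect_error(chemical_cac(m, "ChemK", character(0)),
               class = "toxsig_argument_error")

  for (seed in 111:113) {
    mr <- random_fc(seed, n_genes = 15, n_cond = 12,
                    chemicals = c("A", "B"))
    genes <- sample(fc_genes(mr), 6)
    for (chem in c("A", "B")) {
      expect_equal(chemical_cac(mr, chem, genes), bf_cac(mr, chem, genes))
    }
  }
})

test_that("score identity, cosine normalisation and monotone scaling hold", {
  set.seed(121)
  for (i in 1:200) {
    v <- stats::rnorm(3) * 10^sample(-2:2, 1)
    if (sum(v^2) == 0) next
    mod <- vector_module(v)
    cosines <- vapply(pathway_ids(), function(p) axis_cosine(v, p), 1)
    expect_equal(sum(cosines^2), 1, tolerance = 1e-12)
    for (ax in 1:3) {
      expect_equal(unname(cosines[ax]) * mod, abs(v[ax]), tolerance = 1e-12)
    }
    # scalar multiplication preserves cosines, scales module exactly
    c_mult <- 1 + stats::runif(1, 0.1, 4)
    expect_equal(
      vapply(pathway_ids(), function(p) axis_cosine(c_mult * v, p), 1),
      cosines
    )
    expect_equal(vector_module(c_mult * v), c_mult * mod)
  }
})

test_that("classification applies both cut-offs and the nearest axis", {
  scores <- scores_from_vectors(list(
    c(0.6, 0.05, 0.05),   # specific and potent -> AhR
    c(0.4, 0, 0),         # specific, weak: module 0.4 < 0.5 -> rejected
    c(-0.3, 0.4, 0),      # module exactly 0.5: strict cut-off rejects
    c(0.5, 0.5, 0.5),     # equidistant: cos = cut-off exactly, rejected
    c(0, 0, -0.9),        # potent pure inhibitor -> ATF4 via |cos|
    c(0, 0, 0)            # zero vector: never specific
  ))
  cls <- classify_chemicals(scores)
  expect_equal(cls$per_pathway$AhR$chemical, "V0001")
  expect_equal(cls$per_pathway$Nrf2$chemical, character(0))
  expect_equal(cls$per_pathway$ATF4$chemical, "V0005")
  expect_equal(cls$per_pathway$ATF4$cac, -0.9) # sign kept for inhibitors

  # explicit numbers for the classified chemical
  expect_equal(
    cls$per_pathway$AhR$cos_alpha,
    0.6 / sqrt(0.6^2 + 2 * 0.05^2)
  )
  expect_equal(cls$per_pathway$AhR$module, sqrt(0.6^2 + 2 * 0.05^2))

  expect_error(classify_chemicals(scores, cos_cutoff = 0),
               class = "toxsig_argument_error")
  expect_error(classify_chemicals(scores, module_cutoff = -1),
               class = "toxsig_argument_error")
})

test_that("classification lists are mutually exclusive and rank by score", {
  set.seed(131)
  vs <- replicate(300, stats::rnorm(3), simplify = FALSE)
  cls <- classify_chemicals(scores_from_vectors(vs))
  listed <- unlist(lapply(cls$per_pathway, function(t) t$chemical))
  expect_equal(anyDuplicated(listed), 0L)
  for (p in pathway_ids()) {
    sc <- cls$per_pathway[[p]]$score
    expect_true(all(diff(sc) <= 1e-12))
    expect_true(all(cls$per_pathway[[p]]$cos_alpha > 1 / sqrt(3)))
    expect_true(all(cls$per_pathway[[p]]$module > 0.5))
  }

  # permuting the input order changes nothing
  perm <- sample(length(vs))
  scores_perm <- scores_from_vectors(vs[perm])
  scores_perm$chemical <- sprintf("V%04d", perm) # keep original names
  cls2 <- classify_chemicals(scores_perm)
  for (p in pathway_ids()) {
    expect_equal(cls2$per_pathway[[p]]$chemical,
                 cls$per_pathway[[p]]$chemical)
  }

  # without the nearest-axis guard, a diagonal vector passes two lists:
  # the guard is what makes the default cut-off exclusive
  diag_scores <- scores_from_vectors(list(c(1, 1, 0) / sqrt(2) * 0.9))
  raw <- classify_chemicals(diag_scores, nearest_axis = FALSE)
  expect_equal(
    sum(vapply(raw$per_pathway, nrow, 1L)), 2L
  )
  guarded <- classify_chemicals(diag_scores)
  expect_equal(sum(vapply(guarded$per_pathway, nrow, 1L)), 0L)
})

test_that("not-scorable chemicals are excluded, not zero-filled", {
  cfg <- synthetic_config(seed = 141, noise_sd = 0.05)
  d <- generate_synthetic(cfg)
  filt <- filter_by_max_time(d$matrix, 24)$matrix
  part <- partition_overlaps(build_signatures(filt, d$activators))

  # a chemical with values only for non-signature genes is not scorable
  cond_x <- mk_conditions(1, chemical = "NoDataChem", ids = "nx1")
  vals_x <- tibble::tibble(condition_id = "nx1", gene = "BG0001",
                           log2fc = 0.2)
  m2 <- fc_matrix(
    dplyr::bind_rows(fc_conditions(filt), cond_x),
    dplyr::bind_rows(fc_values(filt), vals_x),
    genes = fc_genes(filt)
  )
  suppressWarnings(scores <- score_chemicals(m2, part))
  row <- scores[scores$chemical == "NoDataChem", ]
  expect_false(row$scorable)
  expect_true(is.na(row$cac_AhR))
  cls <- classify_chemicals(scores)
  expect_true("NoDataChem" %in% cls$not_scorable)
  expect_false("NoDataChem" %in% unlist(
    lapply(cls$per_pathway, function(t) t$chemical)
  ))
})

test_that("scatter export carries ranks, coordinates and raw pass flags", {
  scores <- scores_from_vectors(list(c(0.6, 0.05, 0.05), c(0.1, 0.2, 0.1)))
  scores$chemical <- c("Zeta", "Alpha")
  tab <- export_scatter_data(scores, cos_cutoff = 1 / sqrt(3),
                             module_cutoff = 0.5)
  expect_equal(nrow(tab), 6L) # 2 chemicals x 3 pathways
  # alphabetical rank stable across pathways
  expect_equal(unique(tab$rank[tab$chemical == "Alpha"]), 1L)
  expect_equal(unique(tab$rank[tab$chemical == "Zeta"]), 2L)
  # pass flag true iff both cut-offs exceeded
  expect_equal(
    tab$pass,
    tab$cos_alpha > 1 / sqrt(3) & tab$module > 0.5
  )
  expect_true(any(tab$pass[tab$chemical == "Zeta" & tab$pathway == "AhR"]))
  expect_false(any(tab$pass[tab$chemical == "Alpha"]))
})
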