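#' Configuration of the synthetic fold-change generator
#'
#' Describes a dataset with planted pathway structure under an additive
#' signal-plus-Gaussian-noise model: the value for condition `c` of
#' chemical `k` and gene `g` is
#' `sum_p activation_p(k) * effect_p(g) + Normal(0, noise_sd^2)`.
#' Background genes have all effects zero; exclusive planted genes respond
#' to one pathway (positively for activated, negatively for inhibited
#' genes); overlap genes carry independent effects for each member pathway
#' (signs configurable per zone, since real overlap genes can disagree in
#' sign between pathways).
#'
#' @param n_background_genes Number of unresponsive background genes.
#' @param planted Named list, pathway -> `c(activated = , inhibited = )`
#'   counts of exclusive planted genes.
#' @param overlap Named integer vector of planted gene counts per overlap
#'   zone (`"AhR-Nrf2"`, `"Nrf2-ATF4"`, `"AhR-ATF4"`, `"AhR-Nrf2-ATF4"`).
#' @param overlap_signs Named list, zone -> named vector of effect signs
#'   per member pathway; unlisted pathways default to +1.
#' @param effect_size,effect_sd Mean and SD of the absolute planted effect
#'   (log2FC units); each planted gene-pathway effect magnitude is drawn
#'   from `Normal(effect_size, effect_sd^2)`.
#' @param noise_sd SD of the additive Gaussian noise per condition-gene
#'   cell (log2FC units); >= 0.
#' @param noise `"gaussian"` (default) or `"t"` for heavier-tailed
#'   Student-t (df = 3) noise scaled to `noise_sd`, to stress-test the
#'   2-sigma rule.
#' @param missing_frac Fraction of condition-gene cells blanked at random
#'   (missing, not zero), in \[0, 1).
#' @param chemicals Tibble with columns `name`, `v_AhR`, `v_Nrf2`,
#'   `v_ATF4` (true activation vector) and `activator_for` (`NA` or a
#'   pathway label marking the chemical as a reference activator).
#' @param times Numeric vector of exposure times in hours; one condition
#'   per chemical and time (times > 24 h exercise the time filter).
#' @param replicates Conditions per chemical and time point.
#' @param category List with `species`, `tissue`, `setting`, `dosing`
#'   applied to every condition.
#' @param seed Integer seed; the generator draws, in documented order,
#'   (1) planted effect magnitudes, (2) background catalog pathways,
#'   (3) noise condition-by-condition, (4) the missing-cell mask.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_background_genes = 200,
                             planted = list(
                               AhR = c(activated = 10, inhibited = 2),
                               Nrf2 = c(activated = 10, inhibited = 2),
                               ATF4 = c(activated = 10, inhibited = 2)
                             ),
                             overlap = c(
                               "AhR-Nrf2" = 2, "Nrf2-ATF4" = 2,
                               "AhR-ATF4" = 1, "AhR-Nrf2-ATF4" = 1
                             ),
                             overlap_signs = list(
                               "AhR-ATF4" = c(AhR = 1, ATF4 = -1)
                             ),
                             effect_size = 1, effect_sd = 0,
                             noise_sd = 0.1,
                             noise = c("gaussian", "t"),
                             missing_frac = 0,
                             chemicals = NULL,
                             times = c(2, 8, 24),
                             replicates = 1,
                             category = list(
                               species = "human", tissue = "liver",
                               setting = "in_vitro", dosing = "bolus"
                             ),
                             seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(chemicals)) {
    chemicals <- tibble(
      name = c(
        "Activator AhR", "Activator Nrf2", "Activator ATF4",
        "Inert compound"
      ),
      v_AhR = c(1, 0, 0, 0),
      v_Nrf2 = c(0, 1, 0, 0),
      v_ATF4 = c(0, 0, 1, 0),
      activator_for = c("AhR", "Nrf2", "ATF4", NA)
    )
  }
  chemicals <- as_tibble(chemicals)
  need <- c("name", "v_AhR", "v_Nrf2", "v_ATF4", "activator_for")
  if (!all(need %in% names(chemicals))) {
    abort(
      paste0(
        "`chemicals` needs columns: ", paste(need, collapse = ", ")
      ),
      class = "toxsig_config_error"
    )
  }
  counts <- c(
    n_background_genes,
    unlist(planted, use.names = FALSE), overlap
  )
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("gene counts must be non-negative integers",
      class = "toxsig_config_error"
    )
  }
  if (!setequal(names(planted), pathway_ids())) {
    abort("`planted` must name exactly the three pathways",
      class = "toxsig_config_error"
    )
  }
  bad_zone <- setdiff(names(overlap), .zone_names[4:7])
  if (length(bad_zone) > 0L) {
    abort(
      paste0(
        "unknown overlap zone(s): ", paste(bad_zone, collapse = ", ")
      ),
      class = "toxsig_config_error"
    )
  }
  if (noise_sd < 0 || effect_sd < 0) {
    abort("`noise_sd` and `effect_sd` must be >= 0",
      class = "toxsig_config_error"
    )
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    abort("`missing_frac` must be in [0, 1)",
      class = "toxsig_config_error"
    )
  }
  if (length(times) == 0L || any(times <= 0) || replicates < 1) {
    abort("`times` must be positive and `replicates` >= 1",
      class = "toxsig_config_error"
    )
  }
  covered <- unique(stats::na.omit(chemicals$activator_for))
  if (!all(pathway_ids() %in% covered)) {
    warn(paste0(
      "no reference activator for pathway(s): ",
      paste(setdiff(pathway_ids(), covered), collapse = ", "),
      "; signature derivation cannot be tested on this dataset"
    ))
  }
  structure(
    list(
      n_background_genes = as.integer(n_background_genes),
      planted = planted, overlap = overlap, overlap_signs = overlap_signs,
      effect_size = effect_size, effect_sd = effect_sd,
      noise_sd = noise_sd, noise = noise, missing_frac = missing_frac,
      chemicals = chemicals, times = times,
      replicates = as.integer(replicates),
      category = category, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# zone -> member pathways
zone_pathways <- function(zone) strsplit(zone, "-", fixed = TRUE)[[1L]]

#' Generate a synthetic fold-change dataset with planted structure
#'
#' Emits the four artifacts the pipeline consumes — a fold-change matrix, a
#' gene target catalog, an activator configuration — plus the planted
#' ground truth enabling recovery tests. Planted gene names encode their
#' role (`AhR_ACT01`, `Nrf2_INH01`, `OVL_AhR-Nrf2_01`, `BG0001`); the
#' catalog assigns planted genes their zone pathways and background genes a
#' random pathway (background genes are curated targets that simply do not
#' respond in this dataset). Reproducible: the same config and seed yield
#' an identical dataset.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with elements `matrix` ([fc_matrix()]), `catalog`
#'   ([gene_catalog()]), `activators` ([activator_config()]) and `truth`
#'   (list with `genes`, `chemicals`, `config`).
#' @export
generate_synthetic <- function(config, seed = NULL) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config()",
      class = "toxsig_argument_error"
    )
  }
  set.seed(seed %||% config$seed)

  # --- gene table with per-pathway effects -------------------------------
  gene_rows <- list()
  add_gene <- function(gene, zone, signs) {
    # signs: named vector over member pathways, magnitude drawn below
    gene_rows[[length(gene_rows) + 1L]] <<- tibble(
      gene = gene, zone = zone,
      pathway = names(signs), sign = unname(signs)
    )
  }
  for (p in pathway_ids()) {
    n_act <- config$planted[[p]][["activated"]]
    n_inh <- config$planted[[p]][["inhibited"]]
    if (n_act > 0L) {
      add_gene(
        sprintf("%s_ACT%02d", p, seq_len(n_act)), p,
        setNames(rep(1, n_act), rep(p, n_act))
      )
    }
    if (n_inh > 0L) {
      add_gene(
        sprintf("%s_INH%02d", p, seq_len(n_inh)), p,
        setNames(rep(-1, n_inh), rep(p, n_inh))
      )
    }
  }
  # exclusive rows were added with one row per gene; overlap genes need one
  # row per member pathway
  gene_rows <- list(dplyr::bind_rows(gene_rows))
  for (zone in names(config$overlap)) {
    n <- config$overlap[[zone]]
    if (n == 0L) next
    members <- zone_pathways(zone)
    signs <- config$overlap_signs[[zone]]
    for (p in members) {
      s <- if (!is.null(signs) && p %in% names(signs)) signs[[p]] else 1
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene = sprintf("OVL_%s_%02d", zone, seq_len(n)),
        zone = zone, pathway = p, sign = s
      )
    }
  }
  effects_long <- dplyr::bind_rows(c(
    list(tibble(
      gene = character(0), zone = character(0),
      pathway = character(0), sign = numeric(0)
    )),
    gene_rows
  ))
  # draw order (1): effect magnitudes, in table order
  effects_long$effect <- effects_long$sign * abs(
    rnorm(nrow(effects_long), config$effect_size, config$effect_sd)
  )
  bg_genes <- if (config$n_background_genes > 0L) {
    sprintf("BG%04d", seq_len(config$n_background_genes))
  } else {
    character(0L)
  }
  planted_genes <- unique(effects_long$gene)
  genes <- c(planted_genes, bg_genes)

  # effect matrix gene x pathway
  eff <- matrix(0,
    nrow = length(genes), ncol = 3L,
    dimnames = list(genes, pathway_ids())
  )
  eff[cbind(
    match(effects_long$gene, genes),
    match(effects_long$pathway, pathway_ids())
  )] <- effects_long$effect

  # --- catalog: draw order (2) background a-priori pathways --------------
  catalog <- gene_catalog(dplyr::bind_rows(
    dplyr::distinct(effects_long, .data$gene, .data$pathway),
    tibble(
      gene = bg_genes,
      pathway = sample(pathway_ids(), length(bg_genes), replace = TRUE)
    )
  ))

  # --- conditions --------------------------------------------------------
  chem <- config$chemicals
  grid <- tidyr::expand_grid(
    name = chem$name, time_h = config$times, rep = seq_len(config$replicates)
  )
  conditions <- tibble(
    condition_id = sprintf("C%05d", seq_len(nrow(grid))),
    chemical = grid$name,
    species = config$category$species,
    tissue = config$category$tissue,
    setting = config$category$setting,
    dosing = config$category$dosing,
    time_h = grid$time_h,
    dose_label = "single",
    project = "synthetic"
  )

  # --- values: signal + noise, draw order (3) condition-major ------------
  act <- as.matrix(chem[c("v_AhR", "v_Nrf2", "v_ATF4")])
  rownames(act) <- chem$name
  signal_by_chem <- act %*% t(eff) # chemical x gene
  signal <- signal_by_chem[match(conditions$chemical, chem$name), ,
    drop = FALSE
  ]
  n_cells <- nrow(conditions) * length(genes)
  noise <- if (config$noise_sd == 0) {
    0
  } else if (config$noise == "gaussian") {
    rnorm(n_cells, 0, config$noise_sd)
  } else {
    stats::rt(n_cells, df = 3) * config$noise_sd / sqrt(3)
  }
  vals <- as.numeric(t(signal)) + noise # gene fastest within condition
  values <- tibble(
    condition_id = rep(conditions$condition_id, each = length(genes)),
    gene = rep(genes, times = nrow(conditions)),
    log2fc = vals
  )

  # --- draw order (4): missing-cell mask ---------------------------------
  if (config$missing_frac > 0) {
    keep <- stats::runif(nrow(values)) >= config$missing_frac
    values <- values[keep, , drop = FALSE]
  }

  matrix <- fc_matrix(conditions, values, genes = genes)

  cfg_list <- lapply(
    pathway_ids(),
    function(p) chem$name[!is.na(chem$activator_for) & chem$activator_for == p]
  )
  names(cfg_list) <- pathway_ids()
  activators <- activator_config(cfg_list[lengths(cfg_list) > 0L])

  truth_genes <- dplyr::bind_rows(
    effects_long |>
      dplyr::select("gene", "zone", "pathway", "effect") |>
      tidyr::pivot_wider(
        names_from = "pathway", values_from = "effect",
        names_prefix = "effect_", values_fill = 0
      ),
    tibble(gene = bg_genes, zone = "background")
  )
  for (p in pathway_ids()) {
    nm <- paste0("effect_", p)
    if (!nm %in% names(truth_genes)) truth_genes[[nm]] <- 0
    truth_genes[[nm]][is.na(truth_genes[[nm]])] <- 0
  }

  list(
    matrix = matrix,
    catalog = catalog,
    activators = activators,
    truth = list(
      genes = truth_genes,
      chemicals = chem,
      config = config
    )
  )
}

#' Ready-made generator configuration at the scale of a real study
#'
#' A configuration echoing the dimensions of the consolidated toxicogenomic
#' dataset the method was designed for: roughly 900 genes (800
#' unresponsive background genes, 30 exclusive planted responders per
#' pathway, overlap zones of 5/7/1/1 genes), 160 chemicals, and four time
#' points (2, 8, 24 and 72 h; the 72 h conditions exist to be removed by
#' the 24 h filter, leaving 3 conditions per chemical). The five reference
#' activators carry the names of the classical pathway-specific chemicals —
#' Benzo(a)pyrene and Omeprazole for AhR, Potassium Bromate and Phorone for
#' Nrf2, Tunicamycin for ATF4 — with unit activation vectors. Three
#' selective probe chemicals activate one pathway at 0.8, two equipotent
#' probes activate all three at 0.5, and 150 inert chemicals complete the
#' set. Planted signatures are activated-dominant (27 up, 3 down per
#' pathway, |effect| = 1), so a reference activator's expected CAC on its
#' own axis is (27 - 3)/30 = 0.8.
#'
#' @param seed Integer seed stored in the config.
#' @param noise_sd Per-cell noise SD; default 0.1.
#' @return A [synthetic_config()].
#' @export
study_mimic_config <- function(seed = 1L, noise_sd = 0.1) {
  chems <- dplyr::bind_rows(
    tibble(
      name = c("Benzo(a)pyrene", "Omeprazole"),
      v_AhR = 1, v_Nrf2 = 0, v_ATF4 = 0, activator_for = "AhR"
    ),
    tibble(
      name = c("Potassium Bromate", "Phorone"),
      v_AhR = 0, v_Nrf2 = 1, v_ATF4 = 0, activator_for = "Nrf2"
    ),
    tibble(
      name = "Tunicamycin",
      v_AhR = 0, v_Nrf2 = 0, v_ATF4 = 1, activator_for = "ATF4"
    ),
    tibble(
      name = c(
        "Selective probe AhR", "Selective probe Nrf2", "Selective probe ATF4"
      ),
      v_AhR = c(0.8, 0, 0), v_Nrf2 = c(0, 0.8, 0), v_ATF4 = c(0, 0, 0.8),
      activator_for = NA_character_
    ),
    tibble(
      name = paste("Equipotent probe", 1:2),
      v_AhR = 0.5, v_Nrf2 = 0.5, v_ATF4 = 0.5,
      activator_for = NA_character_
    ),
    tibble(
      name = sprintf("Inert compound %03d", seq_len(150L)),
      v_AhR = 0, v_Nrf2 = 0, v_ATF4 = 0, activator_for = NA_character_
    )
  )
  synthetic_config(
    n_background_genes = 800L,
    planted = list(
      AhR = c(activated = 27, inhibited = 3),
      Nrf2 = c(activated = 27, inhibited = 3),
      ATF4 = c(activated = 27, inhibited = 3)
    ),
    overlap = c(
      "AhR-Nrf2" = 5, "Nrf2-ATF4" = 7, "AhR-ATF4" = 1, "AhR-Nrf2-ATF4" = 1
    ),
    overlap_signs = list("AhR-ATF4" = c(AhR = 1, ATF4 = -1)),
    effect_size = 1, effect_sd = 0,
    noise_sd = noise_sd,
    missing_frac = 0,
    chemicals = chems,
    times = c(2, 8, 24, 72),
    replicates = 1L,
    seed = seed
  )
}
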