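#' Configuration for the linked biophysics + expression simulator
#'
#' Defaults emulate a three-model PDX-style experiment measured on a
#' linked SMR / Smart-seq2 platform: right-skewed (lognormal) buoyant-mass
#' distributions with model-specific medians, a cell-cycle-driven mass
#' increase (G2-M > S > G0-G1 within every model), stiffness drawn
#' independently of mass (so their empirical R-squared is near zero),
#' negative-binomial counts with designated gene subsets whose log-mean is
#' coupled to the standardized log biophysical covariate, and an injected
#' fraction of low-quality cells (tiny libraries or high mitochondrial
#' fraction) so QC gates have known ground truth.
#'
#' The default problem size (3 x 167 cells, 2000 genes) keeps simulations
#' fast; `preset = "full_scale"` switches to the platform-scale 500 cells
#' by 9442 genes.
#'
#' @param n_models Number of models (default 3).
#' @param cells_per_model Cells per model (default 167, ~500 total).
#' @param n_genes Number of genes, including mitochondrial (default 2000).
#' @param mass_median_per_model G0-G1 median buoyant mass per model, pg
#'   (default 55, 62, 80).
#' @param mass_lognormal_sigma Log-scale SD of within-phase mass
#'   (default 0.25).
#' @param stiffness_median,stiffness_sigma Lognormal stiffness parameters,
#'   arbitrary units (defaults 1, 0.3).
#' @param cellcycle_fractions Matrix `n_models x 3` of (G0G1, S, G2M)
#'   fractions per model, rows summing to 1.
#' @param cellcycle_mass_multipliers Mass multipliers (1, m_S, m_G2M) with
#'   `1 < m_S < m_G2M` (default 1, 1.15, 1.35, matching the ~30-45%
#'   G2-M mass excess seen in nocodazole-synchronized lymphoma lines).
#' @param n_mass_genes,n_stiff_genes,n_both_genes Sizes of the disjoint
#'   gene subsets coupled to mass, stiffness, or both (defaults 30, 30, 20).
#' @param effect_size Log-fold change per SD of the standardized log
#'   covariate for coupled genes (default 0.26, tuned to an injected
#'   Spearman association of about 0.3 at 500 cells).
#' @param nb_dispersion Negative-binomial dispersion `alpha` with
#'   `var = mu + alpha mu^2` (default 0.4).
#' @param library_median,library_sigma Lognormal per-cell total-count
#'   parameters (defaults 50000, 0.35).
#' @param mito_fraction_beta Beta(a, b) parameters of the per-cell
#'   mitochondrial read fraction (default a = 2, b = 38; mean 5%).
#' @param n_mito_genes Number of `MT-` genes (default 13).
#' @param frac_lowquality_cells Fraction of cells made QC-failing
#'   (default 0.05).
#' @param preset `"default"` or `"full_scale"` (500 cells x 9442 genes).
#' @return A list of class `linked_sim_config`.
#' @export
linked_sim_config <- function(n_models = 3, cells_per_model = 167,
                              n_genes = 2000,
                              mass_median_per_model = c(55, 62, 80),
                              mass_lognormal_sigma = 0.25,
                              stiffness_median = 1,
                              stiffness_sigma = 0.3,
                              cellcycle_fractions = NULL,
                              cellcycle_mass_multipliers = c(1, 1.15, 1.35),
                              n_mass_genes = 30, n_stiff_genes = 30,
                              n_both_genes = 20,
                              effect_size = 0.26,
                              nb_dispersion = 0.4,
                              library_median = 50000,
                              library_sigma = 0.35,
                              mito_fraction_beta = c(2, 38),
                              n_mito_genes = 13,
                              frac_lowquality_cells = 0.05,
                              preset = c("default", "full_scale")) {
  preset <- match.arg(preset)
  if (preset == "full_scale") {
    n_genes <- 9442
    cells_per_model <- 167
    n_models <- 3
  }
  if (is.null(cellcycle_fractions)) {
    cellcycle_fractions <- matrix(c(0.65, 0.20, 0.15,
                                    0.45, 0.25, 0.30,
                                    0.40, 0.25, 0.35),
                                  nrow = 3, byrow = TRUE)[seq_len(n_models),
                                                          , drop = FALSE]
  }
  cellcycle_fractions <- as.matrix(cellcycle_fractions)
  if (nrow(cellcycle_fractions) != n_models ||
      ncol(cellcycle_fractions) != 3 ||
      any(abs(rowSums(cellcycle_fractions) - 1) > 1e-8) ||
      any(cellcycle_fractions < 0)) {
    stop("cellcycle_fractions must be an n_models x 3 simplex per row",
         call. = FALSE)
  }
  m <- cellcycle_mass_multipliers
  if (length(m) != 3 || m[1] != 1 || !(m[1] < m[2] && m[2] < m[3])) {
    stop("cellcycle_mass_multipliers must be (1, m_S, m_G2M) with 1 < m_S < m_G2M",
         call. = FALSE)
  }
  if (length(mass_median_per_model) != n_models) {
    stop("mass_median_per_model must have one entry per model",
         call. = FALSE)
  }
  stopifnot(nb_dispersion > 0, n_genes > n_mito_genes,
            frac_lowquality_cells >= 0, frac_lowquality_cells < 1,
            n_mass_genes + n_stiff_genes + n_both_genes + n_mito_genes <=
              n_genes)
  structure(as.list(environment())[c(
    "n_models", "cells_per_model", "n_genes", "mass_median_per_model",
    "mass_lognormal_sigma", "stiffness_median", "stiffness_sigma",
    "cellcycle_fractions", "cellcycle_mass_multipliers", "n_mass_genes",
    "n_stiff_genes", "n_both_genes", "effect_size", "nb_dispersion",
    "library_median", "library_sigma", "mito_fraction_beta",
    "n_mito_genes", "frac_lowquality_cells")],
    class = "linked_sim_config")
}

#' Simulate a paired single-cell biophysics + expression dataset
#'
#' Draws per-cell model, cell-cycle phase, buoyant mass (lognormal times
#' phase multiplier), independent lognormal stiffness, a density/volume
#' pair consistent with the buoyant-mass relation, and a gene-by-cell
#' negative-binomial count matrix in which designated genes are coupled to
#' the standardized log mass and/or stiffness through their log-mean. A
#' configured fraction of cells is made QC-failing (library under 1000
#' reads or mitochondrial fraction over 20%).
#'
#' @param cfg A [linked_sim_config()].
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return A list of class `linked_sim` with `paired` (a
#'   `paired_dataset`), `truth` (data frame: gene, role in
#'   background/mass/stiffness/both/mito, effect sizes), `cell_truth`
#'   (per-cell model, phase, low-quality flag) and `config`.
#' @export
simulate_linked <- function(cfg = linked_sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "linked_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_cells <- cfg$n_models * cfg$cells_per_model
  model_names <- paste0("model", seq_len(cfg$n_models))
  model <- rep(model_names, each = cfg$cells_per_model)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  phases <- c("G0G1", "S", "G2M")

  phase <- character(n_cells)
  for (i in seq_len(cfg$n_models)) {
    idx <- model == model_names[i]
    phase[idx] <- sample(phases, sum(idx), replace = TRUE,
                         prob = cfg$cellcycle_fractions[i, ])
  }
  mult <- cfg$cellcycle_mass_multipliers[match(phase, phases)]
  med <- cfg$mass_median_per_model[match(model, model_names)]
  mass <- rlnorm(n_cells, log(med), cfg$mass_lognormal_sigma) * mult
  stiffness <- rlnorm(n_cells, log(cfg$stiffness_median),
                      cfg$stiffness_sigma)
  dens <- pmax(rnorm(n_cells, 1.07, 0.005), 1.02)
  volume <- mass / (dens - 1.005)

  # gene roles: mito first, then coupled subsets, rest background
  n_g <- cfg$n_genes
  mito_names <- paste0("MT-G", seq_len(cfg$n_mito_genes))
  n_nuc <- n_g - cfg$n_mito_genes
  nuc_names <- paste0("GENE", sprintf("%05d", seq_len(n_nuc)))
  gene_names <- c(mito_names, nuc_names)
  role <- rep("background", n_g)
  role[seq_len(cfg$n_mito_genes)] <- "mito"
  pos <- cfg$n_mito_genes
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pos + seq_len(k)
    pos <<- pos + k
    out
  }
  i_mass <- take(cfg$n_mass_genes)
  i_stiff <- take(cfg$n_stiff_genes)
  i_both <- take(cfg$n_both_genes)
  role[i_mass] <- "mass"
  role[i_stiff] <- "stiffness"
  role[i_both] <- "both"

  beta_mass <- numeric(n_g)
  beta_stiff <- numeric(n_g)
  beta_mass[c(i_mass, i_both)] <- cfg$effect_size
  beta_stiff[c(i_stiff, i_both)] <- cfg$effect_size

  # relative abundances: lognormal for nuclear genes, flat across mito
  w <- numeric(n_g)
  w[role != "mito"] <- rlnorm(n_nuc, 0, 1.2)
  w[role == "mito"] <- 1

  lib <- rlnorm(n_cells, log(cfg$library_median), cfg$library_sigma)
  mito_frac <- rbeta(n_cells, cfg$mito_fraction_beta[1],
                     cfg$mito_fraction_beta[2])

  n_lq <- floor(cfg$frac_lowquality_cells * n_cells)
  lowq <- rep("good", n_cells)
  if (n_lq > 0) {
    lq_idx <- sample.int(n_cells, n_lq)
    half <- lq_idx[seq_len(ceiling(n_lq / 2))]
    rest <- setdiff(lq_idx, half)
    lib[half] <- runif(length(half), 100, 900)
    lowq[half] <- "low_reads"
    if (length(rest) > 0) {
      mito_frac[rest] <- runif(length(rest), 0.25, 0.5)
      lowq[rest] <- "high_mito"
    }
  }

  s_mass <- as.numeric(scale(log(mass)))
  s_stiff <- as.numeric(scale(log(stiffness)))
  is_mito <- role == "mito"

  # per-cell expected counts: coupled log-mean, then renormalized within
  # the nuclear/mito blocks so library size and mito fraction are honoured
  coupling <- exp(outer(beta_mass, s_mass) + outer(beta_stiff, s_stiff))
  mu <- w * coupling
  nuc_share <- colSums(mu[!is_mito, , drop = FALSE])
  mito_share <- colSums(mu[is_mito, , drop = FALSE])
  mu[!is_mito, ] <- t(t(mu[!is_mito, , drop = FALSE]) *
                        (lib * (1 - mito_frac) / nuc_share))
  mu[is_mito, ] <- t(t(mu[is_mito, , drop = FALSE]) *
                       (lib * mito_frac / mito_share))
  counts <- matrix(rnbinom(n_g * n_cells, mu = as.numeric(mu),
                           size = 1 / cfg$nb_dispersion),
                   nrow = n_g, dimnames = list(gene_names, cell_id))

  events <- as_smr_events(data.frame(
    cell_id = cell_id, sample_id = model, condition = "untyped",
    buoyant_mass = mass, stiffness = stiffness, volume = volume,
    viable = TRUE, stringsAsFactors = FALSE))
  cm <- count_matrix(counts, mito_genes = mito_names)
  paired <- pair_events_with_matrix(events, cm,
                                    model_map = setNames(model, cell_id))
  structure(list(
    paired = paired,
    truth = data.frame(gene = gene_names, role = role,
                       effect_mass = beta_mass, effect_stiffness = beta_stiff,
                       row.names = NULL),
    cell_truth = data.frame(cell_id = cell_id, model = model, phase = phase,
                            quality = lowq, library_size = lib,
                            mito_fraction = mito_frac, row.names = NULL),
    config = cfg, seed = seed),
    class = "linked_sim")
}

#' Configuration for the drug-response triplet simulator
#'
#' Emulates the ex vivo sensitivity design: one DMSO-treated sample serves
#' as the reference distribution Z, a second DMSO replicate is the vehicle
#' arm Y (its median perturbed by a small multiplicative jitter modelling
#' treatment-independent drift), and the drug arm X has its median
#' multiplied by `1 - mass_reduction_fraction` when the sample is
#' sensitive, and is unchanged when resistant.
#'
#' @param n_cells Cells per arm (>= 50; default 1000).
#' @param baseline_median Baseline median buoyant mass, pg (default 70).
#' @param baseline_sigma Lognormal log-scale SD (default 0.25).
#' @param sensitivity `"sensitive"` or `"resistant"`.
#' @param mass_reduction_fraction Multiplicative median mass reduction in
#'   the sensitive drug arm, in \[0, 0.5\] (default 0.20).
#' @param replicate_jitter Half-width of the uniform multiplicative
#'   perturbation of the vehicle replicate's median (default 0.01).
#' @return A list of class `drug_sim_config`.
#' @export
drug_sim_config <- function(n_cells = 1000, baseline_median = 70,
                            baseline_sigma = 0.25,
                            sensitivity = c("sensitive", "resistant"),
                            mass_reduction_fraction = 0.20,
                            replicate_jitter = 0.01) {
  sensitivity <- match.arg(sensitivity)
  if (n_cells < 50) stop("n_cells must be at least 50 per arm",
                         call. = FALSE)
  if (mass_reduction_fraction < 0 || mass_reduction_fraction > 0.5) {
    stop("mass_reduction_fraction must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(n_cells = n_cells, baseline_median = baseline_median,
                 baseline_sigma = baseline_sigma, sensitivity = sensitivity,
                 mass_reduction_fraction = mass_reduction_fraction,
                 replicate_jitter = replicate_jitter),
            class = "drug_sim_config")
}

#' Simulate a reference / vehicle / drug mass-distribution triplet
#'
#' @param cfg A [drug_sim_config()].
#' @param seed Integer seed; bit-reproducible for a fixed seed.
#' @return List of class `drug_triplet` with `mass_sample` elements
#'   `reference` (Z), `vehicle` (Y) and `drug` (X), plus `config`.
#' @export
simulate_drug_triplet <- function(cfg = drug_sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "drug_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_cells
  mu <- log(cfg$baseline_median)
  z <- rlnorm(n, mu, cfg$baseline_sigma)
  jit <- 1 + runif(1, -cfg$replicate_jitter, cfg$replicate_jitter)
  y <- rlnorm(n, mu + log(jit), cfg$baseline_sigma)
  red <- if (cfg$sensitivity == "sensitive") cfg$mass_reduction_fraction
         else 0
  x <- rlnorm(n, mu + log(1 - red), cfg$baseline_sigma)
  structure(list(
    reference = mass_sample(z, "reference_DMSO", "reference"),
    vehicle = mass_sample(y, "vehicle_DMSO", "vehicle"),
    drug = mass_sample(x, "drug", "drug"),
    config = cfg, seed = seed),
    class = "drug_triplet")
}

#' Write a simulated linked dataset to disk
#'
#' Writes the SMR event CSV, the MatrixMarket counts with label sidecars,
#' and the gene-truth TSV.
#'
#' @param sim A `linked_sim` from [simulate_linked()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_linked_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "linked_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "smr_events.csv"),
             counts = file.path(dir, "counts.mtx"),
             truth = file.path(dir, "gene_truth.tsv"))
  write_smr_events(sim$paired$events, paths[["events"]])
  write_count_matrix(sim$paired$matrix, paths[["counts"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
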