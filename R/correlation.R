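#' Quality-control configuration for single-cell libraries
#'
#' Defaults mirror standard Smart-seq2 gating: cells with fewer than 1000
#' total reads or with more than 20% of reads from mitochondrial genes are
#' removed (strict inequalities: exactly 1000 reads or exactly 20% mito is
#' retained), and genes expressed in less than 10% of cells in any model
#' are excluded from cross-model correlation.
#'
#' @param min_total_reads Minimum total counts per cell (default 1000).
#' @param max_mito_fraction Maximum mitochondrial read fraction
#'   (default 0.20).
#' @param min_expressing_fraction Per-model minimum fraction of cells with
#'   nonzero counts for a gene to be retained (default 0.10).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_total_reads = 1000, max_mito_fraction = 0.20,
                      min_expressing_fraction = 0.10) {
  stopifnot(min_total_reads >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_expressing_fraction >= 0, min_expressing_fraction <= 1)
  structure(list(min_total_reads = min_total_reads,
                 max_mito_fraction = max_mito_fraction,
                 min_expressing_fraction = min_expressing_fraction),
            class = "qc_config")
}

#' Filter low-quality cells from a count matrix
#'
#' Retains cells with total counts >= `min_total_reads` AND mitochondrial
#' fraction <= `max_mito_fraction` (both boundaries inclusive, per the
#' strict "fewer than" / "greater than" removal rules).
#'
#' @param x A [count_matrix()] with `mito_genes` set.
#' @param cfg A [qc_config()].
#' @return List with `matrix` (the filtered [count_matrix()]) and `report`
#'   (data frame of all input cells with `total_reads`, `mito_fraction`,
#'   `removed` and `reason`).
#' @export
qc_filter_cells <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  mito <- if (length(x$mito_genes) > 0) {
    Matrix::colSums(x$counts[x$mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(x$counts))
  }
  frac <- ifelse(totals > 0, mito / totals, 1)
  low_reads <- totals < cfg$min_total_reads
  high_mito <- frac > cfg$max_mito_fraction
  removed <- low_reads | high_mito
  reason <- rep("", length(removed))
  reason[low_reads] <- "low_total_reads"
  reason[high_mito] <- paste0(reason[high_mito],
                              ifelse(reason[high_mito] == "", "", "+"),
                              "high_mito_fraction")
  report <- data.frame(cell_id = cells(x), total_reads = as.numeric(totals),
                       mito_fraction = as.numeric(frac), removed = removed,
                       reason = reason, row.names = NULL)
  if (all(removed)) {
    stop("QC removed every cell; check thresholds or input", call. = FALSE)
  }
  keep <- count_matrix(x$counts[, !removed, drop = FALSE],
                       mito_genes = x$mito_genes)
  list(matrix = keep, report = report)
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to `scale` total (counts-per-10k by
#' default) and transformed as `log(1 + x)` (natural log).
#'
#' @param x A [count_matrix()]; cells with zero total counts are an error
#'   (run [qc_filter_cells()] first).
#' @param scale Per-cell target total (default 10000).
#' @return A sparse `dgCMatrix` of normalized expression, same dimnames.
#' @export
log_normalize <- function(x, scale = 10000) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts present; apply qc_filter_cells() first",
         call. = FALSE)
  }
  m <- x$counts %*% Matrix::Diagonal(x = scale / totals)
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(x$counts)
  as(m, "CsparseMatrix")
}

#' Exclude model-specific genes
#'
#' Removes genes expressed (raw count > 0) in less than
#' `min_expressing_fraction` of cells in any model, so cross-model
#' correlations are not driven by inherent model-specific factors (sex,
#' immunoglobulin clonotype, ...). The boundary is strict: a gene expressed
#' in exactly the threshold fraction in every model is retained.
#'
#' @param x A [count_matrix()].
#' @param model Character vector of model labels, one per cell (in column
#'   order or named by cell_id).
#' @param min_expressing_fraction Threshold fraction (default 0.10).
#' @return List with `genes` (retained gene symbols) and `report` (data
#'   frame of per-gene minimum expressing fraction across models and the
#'   retention flag).
#' @export
exclude_model_specific_genes <- function(x, model,
                                         min_expressing_fraction = 0.10) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.null(names(model))) model <- model[cells(x)]
  if (length(model) != ncol(x$counts) || anyNA(model)) {
    stop("model labels must cover every cell", call. = FALSE)
  }
  model <- as.character(model)
  if (any(table(model) == 0)) stop("a model has zero cells", call. = FALSE)
  expressed <- x$counts > 0
  fracs <- sapply(unique(model), function(m) {
    Matrix::rowMeans(expressed[, model == m, drop = FALSE])
  })
  min_frac <- apply(as.matrix(fracs), 1, min)
  keep <- min_frac >= min_expressing_fraction
  list(genes = genes(x)[keep],
       report = data.frame(gene = genes(x),
                           min_expressing_fraction = as.numeric(min_frac),
                           retained = keep, row.names = NULL))
}

#' Per-gene Spearman correlation with a biophysical covariate
#'
#' @param norm Normalized expression matrix (genes x cells; base or
#'   `Matrix`), e.g. from [log_normalize()].
#' @param biophys Numeric covariate (buoyant mass or stiffness), one value
#'   per cell, in column order or named by cell_id.
#' @return Named numeric vector of Spearman rho per gene; genes with
#'   constant expression yield `NA` (excluded downstream).
#' @export
spearman_vs_biophys <- function(norm, biophys) {
  if (!is.null(names(biophys)) && !is.null(colnames(norm))) {
    biophys <- biophys[colnames(norm)]
  }
  if (length(biophys) != ncol(norm) || anyNA(biophys)) {
    stop("biophys must supply one finite value per cell", call. = FALSE)
  }
  if (ncol(norm) < 3) {
    stop("at least 3 cells are required for correlation", call. = FALSE)
  }
  rho <- suppressWarnings(
    cor(t(as.matrix(norm)), as.numeric(biophys), method = "spearman"))[, 1]
  setNames(as.numeric(rho), rownames(norm))
}

#' Convert per-gene correlation coefficients to z scores
#'
#' The default standardizes rho across genes,
#' `z = (rho - mean(rho)) / sd(rho)`, so mass- and stiffness-derived
#' scores share a common scale before the selection cutoff. A
#' Fisher-transform variant (`atanh(rho) * sqrt(n - 3)`) is available.
#'
#' @param rho Named numeric vector of per-gene correlations; `NA`s are
#'   carried through.
#' @param method `"standardize"` (default) or `"fisher"`.
#' @param n Number of cells (required for `"fisher"`).
#' @return Named numeric vector of z scores.
#' @export
rho_to_z <- function(rho, method = c("standardize", "fisher"), n = NULL) {
  method <- match.arg(method)
  ok <- is.finite(rho)
  if (sum(ok) < 2) {
    stop("need at least 2 finite correlations", call. = FALSE)
  }
  if (method == "fisher") {
    if (is.null(n)) stop("n (number of cells) required for fisher z",
                         call. = FALSE)
    return(atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3))
  }
  s <- sd(rho[ok])
  if (s == 0) stop("correlations are constant; z scores undefined",
                   call. = FALSE)
  (rho - mean(rho[ok])) / s
}

#' Select top genes by z score
#'
#' @param z Named numeric vector of z scores.
#' @param threshold Selection cutoff (default 2.5); strictly greater-than.
#' @return Character vector of selected gene symbols, sorted by descending
#'   z (possibly empty).
#' @export
select_top <- function(z, threshold = 2.5) {
  sel <- z[is.finite(z) & z > threshold]
  names(sel)[order(-sel)]
}

#' Combined ranking across biophysical correlates
#'
#' Ranks genes by descending average of the mass and stiffness z scores;
#' ties are broken lexicographically by gene symbol so the ranking is
#' deterministic.
#'
#' @param z_mass,z_stiffness Named z-score vectors on a common gene set.
#' @return Data frame with `gene`, `combined_z` and `rank_combined`
#'   (a permutation of 1..G), sorted by rank.
#' @export
combined_rank <- function(z_mass, z_stiffness) {
  common <- intersect(names(z_mass), names(z_stiffness))
  if (length(common) == 0) {
    stop("z_mass and z_stiffness share no genes", call. = FALSE)
  }
  avg <- (z_mass[common] + z_stiffness[common]) / 2
  o <- order(-avg, common)
  data.frame(gene = common[o], combined_z = as.numeric(avg[o]),
             rank_combined = seq_along(o), row.names = NULL)
}

#' Permutation null bound on per-gene correlation
#'
#' Builds an empirical null by randomly re-pairing expression profiles
#' with the biophysical profile: at each iteration the covariate is
#' permuted over cells and every gene's Spearman rho is recomputed. The
#' per-gene bound is the 95th percentile (configurable) of the signed
#' null rho distribution; set `absolute = TRUE` for a two-sided magnitude
#' bound.
#'
#' @inheritParams spearman_vs_biophys
#' @param n_iter Number of random pairings (>= 100; default 10000).
#' @param percentile Null percentile reported per gene (default 0.95).
#' @param seed Integer seed; bounds are bit-reproducible for a fixed seed.
#' @param absolute If `TRUE`, take the percentile of |rho| instead of
#'   signed rho.
#' @return Named numeric vector of per-gene null bounds (`NA` for
#'   constant genes).
#' @export
permutation_ci <- function(norm, biophys, n_iter = 10000, percentile = 0.95,
                           seed = NULL, absolute = FALSE) {
  if (n_iter < 100) {
    stop("n_iter must be at least 100", call. = FALSE)
  }
  if (!is.null(names(biophys)) && !is.null(colnames(norm))) {
    biophys <- biophys[colnames(norm)]
  }
  nc <- ncol(norm)
  if (length(biophys) != nc || anyNA(biophys)) {
    stop("biophys must supply one finite value per cell", call. = FALSE)
  }
  rb <- rank(as.numeric(biophys))
  if (sd(rb) == 0) {
    stop("biophysical covariate is constant; permutation null undefined",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(norm)
  # Spearman rho = Pearson on average ranks; precompute standardized gene
  # ranks once so each iteration is a single matrix-vector product
  rmat <- t(apply(m, 1, rank))
  ctr <- rmat - rowMeans(rmat)
  ss <- sqrt(rowSums(ctr^2))
  degenerate <- ss == 0
  ctr[degenerate, ] <- NA_real_
  ss[degenerate] <- NA_real_
  null_rho <- matrix(NA_real_, nrow(m), n_iter)
  for (it in seq_len(n_iter)) {
    v <- rb[sample.int(nc)]
    vc <- v - mean(v)
    null_rho[, it] <- (ctr %*% vc) / (ss * sqrt(sum(vc^2)))
  }
  if (absolute) null_rho <- abs(null_rho)
  bounds <- apply(null_rho, 1, function(r) {
    if (anyNA(r)) NA_real_ else unname(quantile(r, percentile, type = 7))
  })
  setNames(as.numeric(bounds), rownames(norm))
}

#' Gene-biophysics correlation pipeline for a paired dataset
#'
#' Runs the full association analysis on a [pair_events_with_matrix()]
#' dataset: viability gating, cell QC, model-specific gene exclusion,
#' log-normalization, Spearman correlation of every retained gene with
#' buoyant mass (and stiffness when measured), cross-gene z scoring,
#' z > threshold selection, combined ranking, and permutation null bounds.
#'
#' @param paired A `paired_dataset`.
#' @param qc A [qc_config()].
#' @param scale Normalization scale (default 10000).
#' @param z_threshold Selection cutoff on z (default 2.5).
#' @param z_method `"standardize"` or `"fisher"` (see [rho_to_z()]).
#' @param n_iter Permutation iterations for the null bounds (default
#'   10000); set to `0` to skip the permutation step.
#' @param percentile Null percentile (default 0.95).
#' @param seed Integer seed for the permutation step.
#' @return An object of class `correlation_result`: list with `table`
#'   (per-gene data frame: rho/z/null bound/selection for mass and
#'   stiffness, combined z and rank) and `meta` (thresholds, seed,
#'   filtered dimensions, QC and exclusion reports).
#' @export
correlate_biophysics <- function(paired, qc = qc_config(), scale = 10000,
                                 z_threshold = 2.5,
                                 z_method = c("standardize", "fisher"),
                                 n_iter = 10000, percentile = 0.95,
                                 seed = NULL) {
  stopifnot(inherits(paired, "paired_dataset"))
  z_method <- match.arg(z_method)
  events <- gate_viable(paired$events)
  keep_cells <- intersect(cells(paired$matrix), events$cell_id)
  cm <- count_matrix(paired$matrix$counts[, keep_cells, drop = FALSE],
                     paired$matrix$mito_genes)
  qcres <- qc_filter_cells(cm, qc)
  cm <- qcres$matrix
  model <- paired$model[cells(cm)]
  excl <- exclude_model_specific_genes(cm, model,
                                       qc$min_expressing_fraction)
  cm <- count_matrix(cm$counts[excl$genes, , drop = FALSE],
                     intersect(cm$mito_genes, excl$genes))
  norm <- log_normalize(cm, scale = scale)

  ev <- events[match(cells(cm), events$cell_id), , drop = FALSE]
  mass <- setNames(ev$buoyant_mass, ev$cell_id)
  n_cells <- ncol(norm)

  rho_mass <- spearman_vs_biophys(norm, mass)
  z_mass <- rho_to_z(rho_mass, method = z_method, n = n_cells)
  ci_mass <- if (n_iter > 0) {
    permutation_ci(norm, mass, n_iter = n_iter, percentile = percentile,
                   seed = seed)
  } else {
    setNames(rep(NA_real_, length(rho_mass)), names(rho_mass))
  }

  has_stiff <- "stiffness" %in% names(ev) && !anyNA(ev$stiffness)
  if (has_stiff) {
    stiff <- setNames(ev$stiffness, ev$cell_id)
    rho_st <- spearman_vs_biophys(norm, stiff)
    z_st <- rho_to_z(rho_st, method = z_method, n = n_cells)
    ci_st <- if (n_iter > 0) {
      permutation_ci(norm, stiff, n_iter = n_iter, percentile = percentile,
                     seed = if (is.null(seed)) NULL else seed + 1L)
    } else {
      setNames(rep(NA_real_, length(rho_st)), names(rho_st))
    }
    cr <- combined_rank(z_mass, z_st)
  } else {
    rho_st <- z_st <- ci_st <- setNames(rep(NA_real_, length(rho_mass)),
                                        names(rho_mass))
    cr <- data.frame(gene = names(sort(z_mass, decreasing = TRUE)),
                     combined_z = as.numeric(sort(z_mass,
                                                  decreasing = TRUE)),
                     rank_combined = seq_along(z_mass))
  }
  g <- names(rho_mass)
  tab <- data.frame(
    gene = g,
    rho_mass = as.numeric(rho_mass),
    z_mass = as.numeric(z_mass),
    ci95_mass = as.numeric(ci_mass[g]),
    selected_mass = is.finite(z_mass) & z_mass > z_threshold,
    rho_stiffness = as.numeric(rho_st[g]),
    z_stiffness = as.numeric(z_st[g]),
    ci95_stiffness = as.numeric(ci_st[g]),
    selected_stiffness = is.finite(z_st[g]) & z_st[g] > z_threshold,
    combined_z = as.numeric(cr$combined_z[match(g, cr$gene)]),
    rank_combined = cr$rank_combined[match(g, cr$gene)],
    row.names = NULL)
  structure(list(
    table = tab,
    meta = list(n_cells = n_cells, n_genes = nrow(tab),
                z_threshold = z_threshold, z_method = z_method,
                scale = scale, n_iter = n_iter, percentile = percentile,
                seed = seed, qc = unclass(qc),
                qc_report = qcres$report,
                exclusion_report = excl$report,
                stiffness_used = has_stiff)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "correlation_result: %d genes x %d cells; %d mass-selected, %d stiffness-selected (z > %g)\n",
    x$meta$n_genes, x$meta$n_cells, sum(x$table$selected_mass),
    sum(x$table$selected_stiffness, na.rm = TRUE), x$meta$z_threshold))
  invisible(x)
}
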