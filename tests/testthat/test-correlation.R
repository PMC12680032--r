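test_that("QC gates use strict removal boundaries", {
  # per-cell totals: 999 / 1000 / 1000 with 21% mito / 1000 with 20% mito
  m <- cbind(c999 = c(0, 999), c1000 = c(0, 1000),
             mito21 = c(210, 790), mito20 = c(200, 800))
  cm <- toy_counts(m, gene_names = c("MT-G1", "G1"), mito = "MT-G1")
  res <- qc_filter_cells(cm, qc_config())
  expect_setequal(cells(res$matrix), c("c1000", "mito20"))
  rep <- res$report
  expect_true(rep$removed[rep$cell_id == "c999"])
  expect_match(rep$reason[rep$cell_id == "c999"], "low_total_reads")
  expect_true(rep$removed[rep$cell_id == "mito21"])
  expect_match(rep$reason[rep$cell_id == "mito21"], "high_mito")
  expect_false(any(rep$removed[rep$cell_id %in% c("c1000", "mito20")]))
})

test_that("QC filtering is idempotent and errs when nothing survives", {
  set.seed(11)
  m <- matrix(rpois(200, 30), 10, 20,
              dimnames = list(paste0("G", 1:10), paste0("c", 1:20)))
  cm <- count_matrix(m)
  once <- qc_filter_cells(cm, qc_config(min_total_reads = 250))
  twice <- qc_filter_cells(once$matrix, qc_config(min_total_reads = 250))
  expect_equal(as.matrix(twice$matrix$counts), as.matrix(once$matrix$counts))
  expect_error(qc_filter_cells(cm, qc_config(min_total_reads = 1e6)),
               "every cell")
})

test_that("log-normalization is counts-per-scale then log1p", {
  m <- matrix(0L, 3, 2, dimnames = list(paste0("G", 1:3), c("a", "b")))
  m[, 1] <- c(100L, 9900L, 0L)          # total 10000
  m[, 2] <- c(10L, 10L, 20L)            # total 40
  cm <- count_matrix(m)
  norm <- log_normalize(cm)
  expect_equal(norm["G1", "a"], log(101))
  expect_equal(norm["G3", "a"], 0)
  expect_equal(norm["G3", "b"], log(1 + 20 / 40 * 10000))
  # compositional invariance: doubling a cell's counts changes nothing
  m2 <- m
  m2[, 2] <- m[, 2] * 2L
  expect_equal(as.matrix(log_normalize(count_matrix(m2))),
               as.matrix(norm))
  m3 <- m
  m3[, 2] <- 0L
  expect_error(log_normalize(count_matrix(m3)), "zero total")
})

test_that("model-specific gene exclusion uses a strict <10% rule", {
  # 20 cells per model; expressing-cell counts per model chosen around
  # the boundary
  n_per <- 20
  model <- rep(c("m1", "m2", "m3"), each = n_per)
  m <- matrix(0L, 3, 60)
  expressing <- list(g_fail = c(10, 10, 1),  # 50% / 50% / 5% -> excluded
                     g_edge = c(2, 2, 2),    # exactly 10% everywhere -> kept
                     g_zero = c(0, 0, 0))    # never expressed -> excluded
  for (g in seq_along(expressing)) {
    for (mod in 1:3) {
      k <- expressing[[g]][mod]
      if (k > 0) m[g, (mod - 1) * n_per + seq_len(k)] <- 5L
    }
  }
  cm <- toy_counts(m, gene_names = names(expressing))
  res <- exclude_model_specific_genes(cm, model)
  expect_identical(res$genes, "g_edge")
  expect_equal(res$report$min_expressing_fraction,
               c(0.05, 0.10, 0))
  # permuting cell order does not change the retained set
  perm <- sample(60)
  res2 <- exclude_model_specific_genes(
    count_matrix(cm$counts[, perm]), model[perm])
  expect_identical(res2$genes, res$genes)
  expect_error(exclude_model_specific_genes(cm, model[1:10]), "every cell")
})

test_that("Spearman correlations respect rank structure and ties", {
  set.seed(21)
  mass <- rlnorm(30, log(60), 0.3)
  m <- rbind(up = exp(mass / 20),          # strictly increasing in mass
             down = max(mass) - mass + 1,  # strictly decreasing
             flat = rep(3, 30),
             noise = rnorm(30))
  colnames(m) <- paste0("c", 1:30)
  rho <- spearman_vs_biophys(m, setNames(mass, colnames(m)))
  expect_equal(rho[["up"]], 1)
  expect_equal(rho[["down"]], -1)
  expect_true(is.na(rho[["flat"]]))
  expect_equal(rho[["noise"]],
               cor(m["noise", ], mass, method = "spearman"))
  # invariance under strictly monotone transforms of either side
  rho_t <- spearman_vs_biophys(m, setNames(log(mass), colnames(m)))
  expect_equal(rho_t[["noise"]], rho[["noise"]])
  expect_error(spearman_vs_biophys(m[, 1:2], mass[1:2]), "3 cells")
})

test_that("null Spearman correlations are centred near zero", {
  set.seed(33)
  n <- 500
  mass <- rlnorm(n, log(60), 0.3)
  m <- matrix(rnbinom(1000 * n, mu = 5, size = 2), 1000, n,
              dimnames = list(paste0("G", 1:1000), paste0("c", 1:n)))
  rho <- spearman_vs_biophys(m, setNames(mass, colnames(m)))
  expect_lt(abs(mean(rho, na.rm = TRUE)), 0.01)
})

test_that("z-scoring standardizes the cross-gene rho distribution", {
  z <- rho_to_z(c(a = -0.1, b = 0, c = 0.1))
  expect_equal(unname(z), c(-1, 0, 1))
  set.seed(2)
  rho <- setNames(rnorm(50, 0, 0.05), paste0("g", 1:50))
  z2 <- rho_to_z(rho)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_equal(rho_to_z(rho + 0.3), z2)   # location invariance
  expect_error(rho_to_z(rep(0.2, 10)), "constant")
  expect_error(rho_to_z(c(0.1, NA)), "finite")
  zf <- rho_to_z(rho, method = "fisher", n = 100)
  expect_equal(order(zf), order(rho))
  expect_error(rho_to_z(rho, method = "fisher"), "n ")
})

test_that("top-gene selection is strict and sorted", {
  z <- c(g1 = 2.5, g2 = 3.1, g3 = -4, g4 = 2.50001, g5 = NA)
  expect_identical(select_top(z), c("g2", "g4"))
  expect_identical(select_top(z, threshold = 5), character(0))
})

test_that("combined ranking averages z scores deterministically", {
  zm <- c(gA = 3, gB = 4, gC = 1)
  zs <- c(gA = 3, gB = 1, gC = 1)
  cr <- combined_rank(zm, zs)
  expect_identical(cr$gene[1], "gA")     # mean 3 beats mean 2.5
  expect_identical(sort(cr$rank_combined), 1:3)
  swapped <- combined_rank(zs, zm)
  expect_identical(swapped$gene, cr$gene)
  # lexicographic tie-break
  tie <- combined_rank(c(b = 1, a = 1), c(b = 1, a = 1))
  expect_identical(tie$gene, c("a", "b"))
  expect_error(combined_rank(c(a = 1), c(b = 1)), "no genes")
})

test_that("permutation null bounds match a direct Spearman oracle", {
  set.seed(14)
  n <- 40
  m <- matrix(rpois(20 * n, 4), 20, n,
              dimnames = list(paste0("G", 1:20), paste0("c", 1:n)))
  mass <- rlnorm(n, log(60), 0.3)
  ci <- permutation_ci(m, mass, n_iter = 200, seed = 99)
  # replay the same seeded permutations through stats::cor
  set.seed(99)
  null_rho <- matrix(NA_real_, 20, 200)
  for (it in 1:200) {
    null_rho[, it] <- suppressWarnings(
      cor(t(m), mass[sample.int(n)], method = "spearman"))
  }
  oracle <- apply(null_rho, 1, quantile, 0.95, type = 7)
  expect_equal(unname(ci), unname(oracle), tolerance = 1e-12)
  expect_identical(ci, permutation_ci(m, mass, n_iter = 200, seed = 99))
  expect_error(permutation_ci(m, rep(1, n), n_iter = 200), "constant")
  expect_error(permutation_ci(m, mass, n_iter = 50), "at least 100")
})

test_that("the correlation pipeline recovers injected gene programs", {
  sim <- simulate_linked(linked_sim_config(n_mass_genes = 20,
                                           n_stiff_genes = 20,
                                           n_both_genes = 0), seed = 5)
  res <- correlate_biophysics(sim$paired, n_iter = 200, seed = 6)
  tab <- res$table
  inj_mass <- sim$truth$gene[sim$truth$role == "mass"]
  inj_stiff <- sim$truth$gene[sim$truth$role == "stiffness"]
  sel_mass <- tab$gene[tab$selected_mass]
  sel_stiff <- tab$gene[tab$selected_stiffness]
  expect_gt(length(intersect(sel_mass, inj_mass)) / 20, 0.7)
  expect_gt(length(intersect(sel_stiff, inj_stiff)) / 20, 0.7)
  expect_lt(length(setdiff(sel_mass, inj_mass)), 10)
  # combined ranking is a permutation and favours injected genes
  expect_setequal(tab$rank_combined, seq_len(nrow(tab)))
  top50 <- tab$gene[order(tab$rank_combined)][1:50]
  expect_gt(length(intersect(top50, c(inj_mass, inj_stiff))), 20)
  # QC removed the injected low-quality cells
  lq <- sim$cell_truth$cell_id[sim$cell_truth$quality != "good"]
  qc_removed <- res$meta$qc_report$cell_id[res$meta$qc_report$removed]
  expect_true(all(lq %in% qc_removed))
})
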