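# Independent oracles kept free of the package's own code paths.

# all permutations of 1..n as an (n!) x n matrix (recursive construction)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact 1D EMD by brute-force assignment over all couplings (transportation
# LP extreme points are permutation matrices for uniform equal weights)
emd_assignment <- function(x, z) {
  n <- length(x)
  stopifnot(length(z) == n, n <= 8)
  pm <- perm_matrix(n)
  costs <- rowSums(abs(matrix(x[pm], nrow(pm)) -
                         matrix(z, nrow(pm), n, byrow = TRUE)))
  min(costs)
}

# piecewise-linear inversion of the empirical CDF with knots at
# (x_(i), (i-1)/(n-1)): an independent route to the interpolated quantile
quantile_cdf_inversion <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1) return(rep(xs, length(p)))
  knots <- (seq_len(n) - 1) / (n - 1)
  stats::approx(knots, xs, xout = p, rule = 2, ties = "ordered")$y
}

# small toy count matrix with named genes/cells
toy_counts <- function(mat, gene_names = NULL, cell_names = NULL,
                       mito = character(0)) {
  if (is.null(gene_names)) {
    gene_names <- if (!is.null(rownames(mat))) rownames(mat)
                  else paste0("G", seq_len(nrow(mat)))
  }
  if (is.null(cell_names)) {
    cell_names <- if (!is.null(colnames(mat))) colnames(mat)
                  else paste0("c", seq_len(ncol(mat)))
  }
  dimnames(mat) <- list(gene_names, cell_names)
  count_matrix(mat, mito_genes = mito)
}
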