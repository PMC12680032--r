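#' Construct a labeled single-cell mass sample
#'
#' @param masses Numeric vector of single-cell buoyant masses (pg),
#'   finite and strictly positive; n >= 2 for any statistical use.
#' @param label Sample label.
#' @param condition One of `"reference"`, `"vehicle"`, `"drug"`,
#'   `"untyped"`.
#' @return An object of class `mass_sample`.
#' @export
mass_sample <- function(masses, label = "sample",
                        condition = c("untyped", "reference", "vehicle",
                                      "drug")) {
  condition <- match.arg(condition)
  masses <- as.numeric(masses)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be finite and positive", call. = FALSE)
  }
  structure(list(label = label, masses = masses, condition = condition),
            class = "mass_sample")
}

#' @export
print.mass_sample <- function(x, ...) {
  s <- summarize_masses(x$masses)
  cat(sprintf("mass_sample '%s' (%s): n = %d, median = %.3g pg, IQR = %.3g pg\n",
              x$label, x$condition, s$n, s$median, s$iqr))
  invisible(x)
}

.sample_masses <- function(x) {
  if (inherits(x, "mass_sample")) x$masses else as.numeric(x)
}

.check_sample <- function(x, what) {
  v <- .sample_masses(x)
  if (length(v) < 2) {
    stop(what, " must contain at least 2 cells", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop(what, " masses must be finite and positive", call. = FALSE)
  }
  v
}

#' Harmonize two mass samples to a common length
#'
#' The mass-response formula presumes equal numbers of cells per
#' distribution; real SMR runs rarely oblige. Two policies reconcile
#' unequal sizes, both returning sorted vectors of length
#' `N = min(n_A, n_B)`:
#' \describe{
#'   \item{`"quantile"`}{(default, deterministic) evaluates the larger
#'     sample's empirical quantile function, with linear interpolation
#'     between order statistics (type 7), at the midpoint probability grid
#'     \eqn{(i - 0.5)/N}; a sample already of length `N` passes through
#'     sorted but otherwise unchanged.}
#'   \item{`"subsample"`}{draws `N` values without replacement from the
#'     larger sample (seeded), preserving equal-N semantics exactly.}
#' }
#'
#' @param a,b `mass_sample` objects or numeric vectors (n >= 2 each).
#' @param policy `"quantile"` or `"subsample"`.
#' @param seed Optional integer seed for `"subsample"`.
#' @return List with sorted numeric vectors `a` and `b` of equal length,
#'   and `n` (the common length).
#' @export
harmonize_masses <- function(a, b, policy = c("quantile", "subsample"),
                             seed = NULL) {
  policy <- match.arg(policy)
  va <- .check_sample(a, "sample A")
  vb <- .check_sample(b, "sample B")
  n <- min(length(va), length(vb))
  if (policy == "subsample") {
    if (!is.null(seed)) set.seed(seed)
    if (length(va) > n) va <- va[sample.int(length(va), n)]
    if (length(vb) > n) vb <- vb[sample.int(length(vb), n)]
    list(a = sort(va), b = sort(vb), n = n)
  } else {
    p <- (seq_len(n) - 0.5) / n
    list(a = .quantile_grid(va, p), b = .quantile_grid(vb, p), n = n)
  }
}

# type-7 quantile on an already-validated vector; returns sorted values
.quantile_grid <- function(x, p) {
  if (length(x) == length(p)) return(sort(x))
  unname(quantile(x, p, type = 7, names = FALSE))
}

#' Earth Mover's Distance between sorted, equal-length samples
#'
#' For two samples of equal size N, the 1D Earth Mover's Distance with
#' uniform weights is attained by pairing order statistics:
#' \eqn{EMD(X, Z) = \sum_i |X_{(i)} - Z_{(i)}|}. This equals N times the
#' 1-Wasserstein distance between the two empirical measures.
#'
#' @param x,z Sorted ascending numeric vectors of equal length.
#' @return The summed absolute difference of paired order statistics, in
#'   the units of the input (pg for masses).
#' @export
emd_sorted <- function(x, z) {
  if (length(x) != length(z)) {
    stop("emd_sorted requires equal-length vectors", call. = FALSE)
  }
  if (is.unsorted(x) || is.unsorted(z)) {
    stop("emd_sorted requires sorted inputs; see harmonize_masses()",
         call. = FALSE)
  }
  sum(abs(x - z))
}

#' Mass response of a treated sample against a reference
#'
#' The mass response of sample X against reference Z is the Earth Mover's
#' Distance between the two single-cell mass distributions normalized by
#' the total reference mass: \eqn{EMD(X, Z) / \sum_i Z_i}. It is
#' dimensionless, non-negative, zero iff the harmonized distributions
#' coincide, and invariant under a common rescaling of all masses.
#'
#' @inheritParams harmonize_masses
#' @param x Treated sample (`mass_sample` or numeric vector).
#' @param z Reference sample.
#' @return Dimensionless mass response >= 0.
#' @export
#' @examples
#' mass_response(c(2, 3, 4), c(1, 2, 3))   # EMD 3 over sum(Z) 6 -> 0.5
mass_response <- function(x, z, policy = c("quantile", "subsample"),
                          seed = NULL) {
  h <- harmonize_masses(x, z, policy = policy, seed = seed)
  emd_sorted(h$a, h$b) / sum(h$b)
}

#' Test statistic: difference of drug and vehicle mass responses
#'
#' \eqn{\theta(X, Y, Z) = MassResponse(X, Z) - MassResponse(Y, Z)}, where
#' X is the drug-treated sample, Y the vehicle (DMSO) sample and Z a
#' reference replicate of the vehicle. Differencing removes the
#' treatment-independent divergence (sampling error, instrument noise,
#' phenotypic drift) that both arms share against the reference. Both
#' terms use the same harmonization target length
#' `N = min(n_X, n_Y, n_Z)`.
#'
#' @param x Drug-treated sample.
#' @param y Vehicle-treated sample.
#' @param z Reference sample.
#' @inheritParams harmonize_masses
#' @return Dimensionless theta; positive when the drug arm diverges more
#'   from the reference than the vehicle arm does.
#' @export
theta_statistic <- function(x, y, z, policy = c("quantile", "subsample"),
                            seed = NULL) {
  policy <- match.arg(policy)
  vx <- .check_sample(x, "drug sample X")
  vy <- .check_sample(y, "vehicle sample Y")
  vz <- .check_sample(z, "reference sample Z")
  if (!is.null(seed)) set.seed(seed)
  .theta_core(vx, vy, vz, policy)
}

# shared-N theta on validated numeric vectors; uses the current RNG state
# when policy = "subsample"
.theta_core <- function(vx, vy, vz, policy) {
  n <- min(length(vx), length(vy), length(vz))
  if (policy == "subsample") {
    if (length(vx) > n) vx <- vx[sample.int(length(vx), n)]
    if (length(vy) > n) vy <- vy[sample.int(length(vy), n)]
    if (length(vz) > n) vz <- vz[sample.int(length(vz), n)]
    qx <- sort(vx); qy <- sort(vy); qz <- sort(vz)
  } else {
    p <- (seq_len(n) - 0.5) / n
    qx <- .quantile_grid(vx, p)
    qy <- .quantile_grid(vy, p)
    qz <- .quantile_grid(vz, p)
  }
  (sum(abs(qx - qz)) - sum(abs(qy - qz))) / sum(qz)
}

#' Bootstrap-t significance test for the mass-response statistic
#'
#' Compares the observed \eqn{\theta} (drug minus vehicle mass response
#' against a shared reference) to a resampled null. With the default
#' `null_resampling = "pooled"`, each bootstrap replicate draws X*, Y*
#' and Z* with replacement at the original sizes from the pooled vehicle
#' and reference masses - the two arms that are exchangeable replicates by
#' design - and recomputes \eqn{\theta^*}; this enforces the null
#' hypothesis in the resampling scheme, so the replicate distribution has
#' the null sampling variance of \eqn{\theta}. Replicates are centered at
#' their mean and studentized by the bootstrap standard deviation. The
#' add-one p-value is
#' \eqn{(1 + \#\{\theta^*_c \ge \theta_{obs}\}) / (B + 1)} for the
#' one-sided "greater" alternative (drug reduces mass, increasing
#' divergence from reference), or the doubled smaller tail for
#' "two_sided".
#'
#' `null_resampling = "per_arm"` resamples each of X, Y and Z from its own
#' empirical distribution instead. Because the Earth Mover's Distance is
#' not smooth at coinciding distributions, per-arm resampling inflates the
#' replicate variance at the null and (without a nested studentization) is
#' markedly conservative; it is retained for comparison. If every mass in
#' every sample is identical the statistic is degenerate and the p-value
#' is 1.
#'
#' @param x Drug-treated sample (`mass_sample` or numeric vector).
#' @param y Vehicle-treated sample.
#' @param z Reference sample.
#' @param n_boot Number of bootstrap replicates (>= 200; default 10000).
#' @param seed Integer seed; the test is bit-reproducible for a fixed seed.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param alpha Decision level (default 0.05).
#' @param null_resampling `"pooled"` (default; resample all arms from the
#'   pooled vehicle + reference masses) or `"per_arm"`.
#' @inheritParams harmonize_masses
#' @return An object of class `mass_response_result`: list with
#'   `mass_response_drug`, `mass_response_vehicle`, `theta`, `se_boot`,
#'   `t_obs`, `p_value`, `decision`, `n_boot`, `seed`, `harmonized_n`,
#'   `alternative`, `alpha`, `policy`, `null_resampling`.
#' @export
bootstrap_t_test <- function(x, y, z, n_boot = 10000, seed = NULL,
                             alternative = c("greater", "two_sided"),
                             alpha = 0.05,
                             policy = c("quantile", "subsample"),
                             null_resampling = c("pooled", "per_arm")) {
  alternative <- match.arg(alternative)
  policy <- match.arg(policy)
  null_resampling <- match.arg(null_resampling)
  if (n_boot < 200) {
    stop("n_boot must be at least 200 for a stable tail", call. = FALSE)
  }
  vx <- .check_sample(x, "drug sample X")
  vy <- .check_sample(y, "vehicle sample Y")
  vz <- .check_sample(z, "reference sample Z")
  if (!is.null(seed)) set.seed(seed)

  mr_x <- mass_response(vx, vz, policy = policy)
  mr_y <- mass_response(vy, vz, policy = policy)
  n <- min(length(vx), length(vy), length(vz))
  theta_obs <- .theta_core(vx, vy, vz, policy)

  nx <- length(vx); ny <- length(vy); nz <- length(vz)
  th_star <- numeric(n_boot)
  if (null_resampling == "pooled") {
    pool <- c(vy, vz)
    np <- length(pool)
    ix <- matrix(sample.int(np, nx * n_boot, replace = TRUE), nx, n_boot)
    iy <- matrix(sample.int(np, ny * n_boot, replace = TRUE), ny, n_boot)
    iz <- matrix(sample.int(np, nz * n_boot, replace = TRUE), nz, n_boot)
    bx <- by <- bz <- pool
  } else {
    ix <- matrix(sample.int(nx, nx * n_boot, replace = TRUE), nx, n_boot)
    iy <- matrix(sample.int(ny, ny * n_boot, replace = TRUE), ny, n_boot)
    iz <- matrix(sample.int(nz, nz * n_boot, replace = TRUE), nz, n_boot)
    bx <- vx; by <- vy; bz <- vz
  }
  if (nx == ny && ny == nz) {
    # equal sizes: harmonization reduces to sorting under either policy
    for (b in seq_len(n_boot)) {
      sx <- sort.int(bx[ix[, b]], method = "quick")
      sy <- sort.int(by[iy[, b]], method = "quick")
      sz <- sort.int(bz[iz[, b]], method = "quick")
      th_star[b] <- (sum(abs(sx - sz)) - sum(abs(sy - sz))) / sum(sz)
    }
  } else {
    for (b in seq_len(n_boot)) {
      th_star[b] <- .theta_core(bx[ix[, b]], by[iy[, b]], bz[iz[, b]],
                                policy)
    }
  }

  se <- sd(th_star)
  if (!is.finite(se) || se == 0) {
    # degenerate: all resampled statistics identical (e.g. constant masses)
    p <- 1
    t_obs <- NA_real_
  } else {
    centered <- th_star - mean(th_star)
    t_obs <- theta_obs / se
    ge <- sum(centered >= theta_obs)
    if (alternative == "greater") {
      p <- (1 + ge) / (n_boot + 1)
    } else {
      le <- sum(centered <= theta_obs)
      p <- min(1, 2 * (1 + min(ge, le)) / (n_boot + 1))
    }
  }
  structure(list(
    mass_response_drug = mr_x,
    mass_response_vehicle = mr_y,
    theta = theta_obs,
    se_boot = se,
    t_obs = t_obs,
    p_value = p,
    decision = p < alpha,
    n_boot = n_boot,
    seed = seed,
    harmonized_n = n,
    alternative = alternative,
    alpha = alpha,
    policy = policy,
    null_resampling = null_resampling),
    class = "mass_response_result")
}

#' @export
print.mass_response_result <- function(x, ...) {
  cat("Mass response bootstrap-t test\n")
  cat(sprintf("  mass response (drug vs ref):    %.5f\n",
              x$mass_response_drug))
  cat(sprintf("  mass response (vehicle vs ref): %.5f\n",
              x$mass_response_vehicle))
  cat(sprintf("  theta = %.5f (bootstrap SE %.5f), harmonized n = %d\n",
              x$theta, x$se_boot, x$harmonized_n))
  cat(sprintf("  p = %.4g (%s, %d replicates); %s at alpha = %g\n",
              x$p_value, x$alternative, x$n_boot,
              if (isTRUE(x$decision)) "SIGNIFICANT" else "not significant",
              x$alpha))
  invisible(x)
}

#' Restrict an event table to viable cells
#'
#' When the SMR event table carries a `viable` flag, only viable cells
#' enter mass analyses (mirroring viability gating on the instrument).
#' Tables without the flag are returned unchanged.
#'
#' @param events An `smr_events` table.
#' @return The gated `smr_events` table.
#' @export
gate_viable <- function(events) {
  if (!"viable" %in% names(events)) return(events)
  out <- events[!is.na(events$viable) & events$viable, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(events)
  out
}

#' Mass-response test from an SMR event table
#'
#' Convenience wrapper: gates viable cells, splits the table by
#' `sample_id` using a role map, and runs [bootstrap_t_test()].
#'
#' @param events An `smr_events` table.
#' @param roles Named character vector with entries `reference`, `vehicle`
#'   and `drug` giving the `sample_id` playing each role.
#' @inheritParams bootstrap_t_test
#' @return A `mass_response_result`.
#' @export
mass_response_from_events <- function(events, roles, n_boot = 10000,
                                      seed = NULL,
                                      alternative = c("greater", "two_sided"),
                                      alpha = 0.05,
                                      policy = c("quantile", "subsample")) {
  need <- c("reference", "vehicle", "drug")
  if (!all(need %in% names(roles))) {
    stop("roles must name reference, vehicle and drug sample_ids",
         call. = FALSE)
  }
  events <- gate_viable(events)
  pick <- function(role) {
    m <- events$buoyant_mass[events$sample_id == roles[[role]]]
    if (length(m) < 2) {
      stop("fewer than 2 viable cells for ", role, " sample '",
           roles[[role]], "'", call. = FALSE)
    }
    mass_sample(m, label = roles[[role]],
                condition = if (role == "drug") "drug"
                            else if (role == "vehicle") "vehicle"
                            else "reference")
  }
  bootstrap_t_test(pick("drug"), pick("vehicle"), pick("reference"),
                   n_boot = n_boot, seed = seed,
                   alternative = alternative, alpha = alpha,
                   policy = policy)
}
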