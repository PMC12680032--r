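test_that("sorted-pairing EMD matches hand examples and errors cleanly", {
  expect_equal(emd_sorted(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_sorted(c(2, 3, 4), c(1, 2, 3)), 3)
  expect_equal(emd_assignment(c(2, 3, 4), c(1, 2, 3)), 3)
  x <- sort(rlnorm(6, log(60), 0.2))
  expect_equal(emd_sorted(x + 5, x), 6 * 5, tolerance = 1e-12)
  expect_error(emd_sorted(1:3, 1:4), "equal-length")
  expect_error(emd_sorted(c(3, 1, 2), c(1, 2, 3)), "sorted")
})

test_that("sorted pairing attains the transportation-LP optimum", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    if (i %% 2 == 0) {
      x <- sample(0:20, n, replace = TRUE)
      z <- sample(0:20, n, replace = TRUE)
      expect_equal(emd_sorted(sort(x), sort(z)), emd_assignment(x, z))
    } else {
      x <- rlnorm(n, log(50), 0.4)
      z <- rlnorm(n, log(60), 0.4)
      expect_equal(emd_sorted(sort(x), sort(z)), emd_assignment(x, z),
                   tolerance = 1e-10)
    }
  }
})

test_that("harmonization returns equal-length sorted vectors", {
  a <- c(5, 1, 3, 2, 4)
  b <- c(9, 7, 8)
  for (policy in c("quantile", "subsample")) {
    h <- harmonize_masses(a, b, policy = policy, seed = 1)
    expect_equal(h$n, 3)
    expect_length(h$a, 3)
    expect_length(h$b, 3)
    expect_false(is.unsorted(h$a))
    expect_false(is.unsorted(h$b))
  }
  h_eq <- harmonize_masses(a, rev(a), policy = "quantile")
  expect_equal(h_eq$a, sort(a))
  expect_equal(h_eq$b, sort(a))
  expect_error(harmonize_masses(1, b), "at least 2")
})

test_that("quantile harmonization interpolates on the midpoint grid", {
  # the smaller sample (length N) passes through sorted; the larger is
  # interpolated at probabilities (i - 0.5)/N -- frozen values from the
  # independent CDF-inversion oracle at 1/4, 3/4
  h <- harmonize_masses(c(10, 0.5), c(0.5, 5, 10), policy = "quantile")
  p <- c(0.25, 0.75)
  expect_equal(h$a, c(0.5, 10))
  expect_equal(h$b, quantile_cdf_inversion(c(0.5, 5, 10), p))
  expect_equal(h$b, c(2.75, 7.5))
  # four-point grid on a five-value sample
  h2 <- harmonize_masses(c(1, 2, 3, 4), c(10, 20, 30, 40, 50),
                         policy = "quantile")
  p2 <- (1:4 - 0.5) / 4
  expect_equal(h2$b, quantile_cdf_inversion(c(10, 20, 30, 40, 50), p2))
  expect_equal(h2$b, c(15, 25, 35, 45))
})

test_that("mass response obeys its closed-form identities", {
  z <- rlnorm(40, log(70), 0.3)
  expect_equal(mass_response(z, z), 0)
  expect_equal(mass_response(c(2, 3, 4), c(1, 2, 3)), 0.5)
  expect_equal(mass_response(10 * c(2, 3, 4), 10 * c(1, 2, 3)), 0.5)
  # pure shift: delta / mean(Z) for equal-N inputs
  delta <- 4.2
  expect_equal(mass_response(z + delta, z), delta / mean(z),
               tolerance = 1e-12)
  expect_true(mass_response(rlnorm(30, 4, 0.3), rlnorm(30, 4.1, 0.3)) >= 0)
})

test_that("theta is antisymmetric and vanishes for identical arms", {
  set.seed(5)
  x <- rlnorm(50, log(55), 0.25)
  y <- rlnorm(60, log(70), 0.25)
  z <- rlnorm(55, log(68), 0.25)
  expect_equal(theta_statistic(x, x, z), 0)
  expect_equal(theta_statistic(x, y, z), -theta_statistic(y, x, z),
               tolerance = 1e-12)
  # a downward mass shift in the drug arm drives theta positive
  trip <- simulate_drug_triplet(drug_sim_config(n_cells = 1000,
                                                replicate_jitter = 0),
                                seed = 9)
  expect_gt(theta_statistic(trip$drug, trip$vehicle, trip$reference), 0)
})

test_that("the bootstrap test is internally consistent and reproducible", {
  trip <- simulate_drug_triplet(drug_sim_config(n_cells = 200), seed = 21)
  r1 <- bootstrap_t_test(trip$drug, trip$vehicle, trip$reference,
                         n_boot = 400, seed = 77)
  r2 <- bootstrap_t_test(trip$drug, trip$vehicle, trip$reference,
                         n_boot = 400, seed = 77)
  expect_identical(r1[c("theta", "p_value", "se_boot", "decision")],
                   r2[c("theta", "p_value", "se_boot", "decision")])
  expect_equal(r1$theta,
               theta_statistic(trip$drug, trip$vehicle, trip$reference))
  expect_equal(r1$theta,
               r1$mass_response_drug - r1$mass_response_vehicle,
               tolerance = 1e-12)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_equal(r1$harmonized_n, 200)
})

test_that("degenerate and invalid bootstrap inputs are handled", {
  const <- rep(5, 30)
  r <- bootstrap_t_test(const, const, const, n_boot = 300, seed = 1)
  expect_equal(r$p_value, 1)
  expect_false(r$decision)
  expect_error(bootstrap_t_test(1:10 + 0.5, 1:10 + 0.5, 1:10 + 0.5,
                                n_boot = 100),
               "at least 200")
})

test_that("per-arm null resampling is available and more conservative", {
  trip <- simulate_drug_triplet(
    drug_sim_config(n_cells = 150, sensitivity = "resistant",
                    replicate_jitter = 0), seed = 13)
  pooled <- bootstrap_t_test(trip$drug, trip$vehicle, trip$reference,
                             n_boot = 500, seed = 3)
  per_arm <- bootstrap_t_test(trip$drug, trip$vehicle, trip$reference,
                              n_boot = 500, seed = 3,
                              null_resampling = "per_arm")
  expect_identical(pooled$theta, per_arm$theta)
  expect_gt(per_arm$se_boot, pooled$se_boot)
})

test_that("viability gating restricts event-driven tests to viable cells", {
  set.seed(31)
  n <- 120
  mk <- function(id, mass) data.frame(
    cell_id = paste0(id, seq_len(n)), sample_id = id,
    buoyant_mass = mass, viable = rep(c(TRUE, FALSE), length.out = n))
  ev <- as_smr_events(rbind(mk("ref", rlnorm(n, log(70), 0.2)),
                            mk("veh", rlnorm(n, log(70), 0.2)),
                            mk("drg", rlnorm(n, log(56), 0.2))))
  gated <- gate_viable(ev)
  expect_equal(nrow(gated), 3 * n / 2)
  r <- mass_response_from_events(
    ev, c(reference = "ref", vehicle = "veh", drug = "drg"),
    n_boot = 300, seed = 2)
  expect_equal(r$harmonized_n, n / 2)
  expect_error(
    mass_response_from_events(ev, c(reference = "ref", vehicle = "veh")),
    "roles")
})
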