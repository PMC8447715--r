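test_that("theoretical maximum of reducing ends follows the anhydro-unit mass", {
  expect_equal(theoretical_max_reducing_ends(2.0), 2.0 / 162.14 * 1000,
               tolerance = 1e-12)
  expect_equal(theoretical_max_reducing_ends(2.0), 12.335, tolerance = 1e-4)
  expect_equal(theoretical_max_reducing_ends(0.16214), 1.0, tolerance = 1e-9)
  expect_equal(theoretical_max_reducing_ends(1.0), 6.167, tolerance = 1e-4)
  # configurable unit mass (free galactose)
  expect_equal(theoretical_max_reducing_ends(1.8016, unit_mass = 180.16), 10)
  expect_error(theoretical_max_reducing_ends(0), "positive")
})

test_that("degree of hydrolysis is reducing ends over the theoretical maximum", {
  s <- digest_sample("s1", "e", 2.0, c(G1 = 0), reducing_ends = 1.2335)
  expect_equal(compute_doh(s), 10.0, tolerance = 1e-3)
  s0 <- digest_sample("s0", "e", 2.0, c(G1 = 0), reducing_ends = 0)
  expect_equal(compute_doh(s0), 0)
  tmax <- theoretical_max_reducing_ends(2.0)
  s100 <- digest_sample("s", "e", 2.0, c(G1 = 0), reducing_ends = tmax)
  expect_equal(compute_doh(s100), 100)
  over <- digest_sample("s", "e", 2.0, c(G1 = 0), reducing_ends = 1.02 * tmax)
  expect_warning(doh <- compute_doh(over), "clipping")
  expect_equal(doh, 100)
  expect_error(compute_doh(
    digest_sample("s", "e", 2.0, c(G1 = 0), reducing_ends = 1.2 * tmax)),
    "assay inconsistency")
})

test_that("G>5 estimation is the reducing-end / analyte mass balance", {
  s <- digest_sample("s", "e", 2.0, c(G1 = 1, G2 = 1.5, G3 = 1.0, G4 = 0.5),
                     reducing_ends = 5.0)
  expect_equal(estimate_g_gt5(s), 1.0)
  neg <- digest_sample("s", "e", 2.0, c(G1 = 2, G2 = 2.2),
                       reducing_ends = 4.0)
  expect_warning(g <- estimate_g_gt5(neg), "clipping")
  expect_equal(g, 0)
  # identity when no clipping fires
  prof <- degradation_profile(s)
  expect_equal(prof$g_gt5_mM + rowSums(s[, paste0("G", 1:5)]),
               s$reducing_ends)
})

test_that("G>5 estimates equal the simulator's true long-chain census", {
  ds <- simulate_endo_hydrolysis(digest_spec(
    n_chains = 80L, lengths = 15L, archetype = "iagal_like",
    times = c(0.02, 0.1, 0.5, 2, Inf), seed = 42L))
  est <- estimate_g_gt5(ds$samples)
  expect_equal(est, ds$truth$g_gt5_mM, tolerance = 1e-9)
})

test_that("endpoint ratios reduce to small integers, tolerating assay noise", {
  expect_equal(as.character(endpoint_ratio(
    data.frame(G1 = 1.5, G2 = 1.0, G3 = 3.0))), "3:2:6")
  expect_equal(as.character(endpoint_ratio(
    data.frame(G1 = 2.0, G2 = 1.0), species = c("G1", "G2"))), "2:1")
  expect_equal(as.character(endpoint_ratio(
    data.frame(G1 = 1.48, G2 = 1.02, G3 = 2.97))), "3:2:6")
  expect_equal(as.character(endpoint_ratio(
    data.frame(G1 = 4.05, G2 = 1.0), species = c("G1", "G2"))), "4:1")
  expect_error(endpoint_ratio(data.frame(G1 = 0, G2 = 0, G3 = 1)),
               "nonzero")
})

test_that("noise-free Michaelis-Menten data are inverted exactly", {
  k <- generate_kinetics(km = 0.47, kcat = 34, enzyme_conc = 1e-3,
                         enzyme_mw = 45000, noise_cv = 0, seed = 1L)
  fit <- fit_michaelis_menten(k$s, k$v, 1e-3, 45000)
  expect_equal(fit$km, 0.47, tolerance = 1e-6)
  expect_equal(fit$kcat, 34, tolerance = 1e-6)
  expect_equal(fit$efficiency, fit$kcat / fit$km, tolerance = 1e-9)
})

test_that("a noisy fit brackets the truth and keeps unit consistency", {
  k <- generate_kinetics(noise_cv = 0.05, seed = 5L)
  tr <- attr(k, "truth")
  fit <- fit_michaelis_menten(k$s, k$v, tr$enzyme_conc, tr$enzyme_mw)
  expect_gt(fit$ci95["km", "upper"], fit$ci95["km", "lower"])
  expect_true(fit$ci95["km", "lower"] < tr$km &&
                tr$km < fit$ci95["km", "upper"])
  expect_equal(fit$efficiency, fit$kcat / fit$km, tolerance = 1e-9)
})

test_that("degenerate kinetics inputs are rejected", {
  s <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  expect_error(fit_michaelis_menten(s, rep(5e-7, 5L), 1e-3, 45000),
               "identifiable")
  expect_error(fit_michaelis_menten(s[1:4], (s * 2)[1:4], 1e-3, 45000),
               "5 distinct")
  expect_error(fit_michaelis_menten(s, c(-1, 1, 2, 3, 4) * 1e-7, 1e-3, 45000),
               "positive")
})

test_that("profile-likelihood intervals are available and bracket the estimate", {
  k <- generate_kinetics(noise_cv = 0.05, seed = 9L)
  fit <- fit_michaelis_menten(k$s, k$v, 1e-3, 45000, ci_method = "profile")
  expect_lt(fit$ci95["km", "lower"], fit$km)
  expect_gt(fit$ci95["km", "upper"], fit$km)
})
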