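test_that("relative mutability ratio is calibrated in JC space", {
  expect_equal(crm_ratio(0.3, 0.3), 1)
  expect_equal(round(crm_ratio(0.583, 0.541), 4), 1.1756)
  expect_error(crm_ratio(0.3, 0), "uninformative")
})

test_that("expected strain distance scales the witness distance by rho", {
  expect_equal(expected_strain_distance(0.3, 0.3, 0.1), jc_correct(0.1))
  expect_equal(expected_strain_distance(0.3, 0.2, 0), 0)
  expect_equal(round(expected_strain_distance(0.583, 0.541, 0.008), 4),
               0.0095)
})

test_that("deviation bound and cutoff invert each other exactly", {
  for (delta in c(0.001, 0.01, 0.05, 0.5, 1)) {
    for (n in c(1, 10, 1472, 1e5)) {
      eps <- deviation_cutoff(delta, n)
      expect_equal(deviation_probability(eps, 0, n), delta,
                   tolerance = 1e-12)
    }
  }
  # scaling: quadrupling the sites halves the cutoff
  expect_equal(deviation_cutoff(0.05, 4000), deviation_cutoff(0.05, 1000) / 2)
  # delta -> 2 sends the cutoff to 0
  expect_equal(deviation_cutoff(2 - 1e-12, 100), 0, tolerance = 1e-6)
})

test_that("deviation bound decreases in |deviation| and in n, capped at 1", {
  eps <- seq(0, 0.2, by = 0.01)
  pb <- deviation_probability(0.3 + eps, 0.3, 500)
  uncapped <- pb < 1
  expect_true(all(diff(pb[uncapped]) < 0))
  expect_equal(deviation_probability(0.3, 0.3, 500), 1)  # raw bound 2, capped
  ns <- c(500, 1000, 5000, 20000)  # large enough that the cap is not hit
  expect_true(all(diff(deviation_probability(0.35, 0.3, ns)) < 0))
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_equal(bonferroni(0.01, 10), 0.1)
  expect_equal(bonferroni(0.3, 5), 1)
  expect_error(bonferroni(0.1, 0), ">= 1")
})

test_that("witness test chain reproduces the worked strain example", {
  # engA suspected between two E. coli strains, gmk as witness, two distant
  # references; the gene's strain divergence is consistent with vertical
  # descent at delta_r = 0.05
  res <- run_witness_test(h_g_S = 0.0237, h_g_R = 0.583, h_w_R = 0.541,
                          h_w_S = 0.008, n_sites = 1472, delta_r = 0.05)
  expect_equal(round(res$expected_d, 4), 0.0095)
  expect_equal(round(res$expected_h, 4), 0.0094)
  expect_equal(res$deviation, 0.0237 - res$expected_h)
  expect_equal(round(res$cutoff, 3), 0.035)
  expect_false(res$refuted)
  expect_equal(res$direction, "farther")
  expect_lt(abs(res$deviation), res$cutoff)
})

test_that("witness test refutes a clearly transferred gene as closer", {
  # observed strain distance 0 against an expectation of 0.2
  res <- run_witness_test(h_g_S = 0, h_g_R = 0.3, h_w_R = 0.3, h_w_S = 0.2,
                          n_sites = 2000, delta_r = 0.05)
  expect_equal(res$expected_h, 0.2, tolerance = 1e-12)
  expect_true(res$refuted)
  expect_equal(res$direction, "closer")
  # zero deviation can never refute
  res0 <- run_witness_test(h_g_S = 0.2, h_g_R = 0.3, h_w_R = 0.3,
                           h_w_S = 0.2, n_sites = 2000, delta_r = 0.05)
  expect_equal(res0$deviation, 0, tolerance = 1e-12)
  expect_false(res0$refuted)
})

test_that("uninformative witnesses are skipped, not errored", {
  res <- run_witness_test(h_g_S = 0.1, h_g_R = 0.3, h_w_R = 0, h_w_S = 0.1,
                          n_sites = 1000)
  expect_equal(res$status, "skipped_witness_zero")
  expect_false(res$refuted)
  sat <- run_witness_test(h_g_S = 0.1, h_g_R = 0.76, h_w_R = 0.3,
                          h_w_S = 0.1, n_sites = 1000)
  expect_equal(sat$status, "skipped_saturated")
})

test_that("bonferroni correction weakens refutation monotonically", {
  res1 <- run_witness_test(h_g_S = 0.05, h_g_R = 0.3, h_w_R = 0.3,
                           h_w_S = 0.1, n_sites = 800, num_tests = 1)
  res50 <- run_witness_test(h_g_S = 0.05, h_g_R = 0.3, h_w_R = 0.3,
                            h_w_S = 0.1, n_sites = 800, num_tests = 50)
  expect_gte(res50$p_bound_corrected, res1$p_bound_corrected)
})

test_that("type-I control under pure vertical evolution with CRM rates", {
  # quartets evolved with per-gene rates shared across lineages (CRM holds
  # exactly); the witness test should refute vertical descent in at most a
  # delta_r fraction of replicates -- the Chernoff bound is conservative
  set.seed(909)
  n_rep <- 500
  refuted <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- vertical_quartet_distances(gene_length = 1000)
    res <- run_witness_test(h_g_S = d$h_g_S, h_g_R = d$h_g_R,
                            h_w_R = d$h_w_R, h_w_S = d$h_w_S,
                            n_sites = d$n_sites, delta_r = 0.05)
    refuted[i] <- isTRUE(res$refuted) && res$status == "ok"
  }
  expect_lte(mean(refuted), 0.05)
})
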