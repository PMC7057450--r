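test_that("root genome generation is seeded and parameterized", {
  cfg <- sim_config(genome_size = 5, gene_length = 10, seed = 3)
  g <- generate_root(cfg)
  expect_length(g$genes, 5)
  expect_true(all(nchar(g$seqs) == 10))
  expect_identical(g$genes, names(g$seqs))
  expect_identical(generate_root(cfg), generate_root(cfg))
  # sd = 0 collapses every rate to the mean
  g0 <- generate_root(sim_config(genome_size = 5, gene_length = 10,
                                 rate_sd = 0, seed = 1))
  expect_true(all(g0$rates == 0.05))
  expect_true(all(g0$rates >= 0))
})

test_that("mutate_copy applies per-site substitution at the gene's rate", {
  cfg <- sim_config(genome_size = 4, gene_length = 1000, rate_mean = 0.5,
                    seed = 9)
  g <- generate_root(cfg)
  expect_identical(mutate_copy(g, factor = 0)$seqs, g$seqs)
  # rate * factor >= 1 forces a substitution at every site
  forced <- mutate_copy(g, factor = 10)
  for (gene in g$genes) {
    expect_equal(hamming(g$seqs[[gene]], forced$seqs[[gene]])$value, 1)
  }
  # binomial concentration: observed divergence near rate
  cfg2 <- sim_config(genome_size = 3, gene_length = 1000, rate_mean = 0.1,
                     rate_sd = 0, seed = 10)
  g2 <- generate_root(cfg2)
  child <- mutate_copy(g2, 1)
  h <- sapply(g2$genes, function(x) hamming(g2$seqs[[x]],
                                            child$seqs[[x]])$value)
  expect_true(all(abs(h - 0.1) < 3 * sqrt(0.1 * 0.9 / 1000)))
})

test_that("rearrangements swap disjoint circular blocks and log the truth", {
  cfg <- sim_config(genome_size = 50, gene_length = 20, n_events = 0,
                    seed = 2)
  g <- generate_root(cfg)
  # no events: untouched order, empty truth
  re0 <- apply_rearrangements(g, cfg)
  expect_identical(re0$genome$genes, g$genes)
  expect_length(re0$truth, 0)
  # single singleton swap: two genes exchanged
  cfg1 <- sim_config(genome_size = 50, gene_length = 20, n_events = 1,
                     event_size_mean = 1, event_size_sd = 0, seed = 2)
  set.seed(4)
  re1 <- apply_rearrangements(g, cfg1)
  expect_length(re1$truth, 2)
  moved <- g$genes != re1$genome$genes
  expect_equal(sum(moved), 2)
  expect_setequal(g$genes[moved], re1$truth)
  # gene content is conserved: always a permutation
  cfgN <- sim_config(genome_size = 50, gene_length = 20, n_events = 4,
                     event_size_mean = 3, event_size_sd = 1, seed = 2)
  set.seed(8)
  reN <- apply_rearrangements(g, cfgN)
  expect_setequal(reN$genome$genes, g$genes)
  expect_true(all(nchar(reN$genome$seqs) == 20))
})

test_that("oversized blocks are rejected by resampling until impossible", {
  cfg <- sim_config(genome_size = 6, gene_length = 5, n_events = 2,
                    event_size_mean = 40, event_size_sd = 0, seed = 1)
  g <- generate_root(cfg)
  expect_error(apply_rearrangements(g, cfg), "non-overlapping")
})

test_that("quartets are reproducible and conserve structure", {
  cfg <- sim_config(genome_size = 40, gene_length = 100, n_events = 2,
                    event_size_mean = 3, event_size_sd = 0, seed = 77)
  q1 <- simulate_quartet(cfg)
  q2 <- simulate_quartet(cfg)
  expect_identical(q1, q2)
  # witness genomes keep the root's gene order; GB is a permutation
  expect_identical(q1$GWA$genes, q1$GA$genes)
  expect_identical(q1$GWB$genes, q1$GA$genes)
  expect_setequal(q1$GB$genes, q1$GA$genes)
  # truth genes have lower mean SI than the background
  gs <- quartet_genomes(q1)
  si <- si_profile(gs$GA, gs$GB, k = 2)
  expect_lt(mean(si[q1$truth]), mean(si[setdiff(names(si), q1$truth)]))
})

test_that("translocated singletons land in foreign neighborhoods", {
  # a single swapped gene in an otherwise identical genome has SI ~ 0:
  # the chance that the destination overlaps the old k-neighborhood is
  # about 4k/n, so the mean SI over seeds stays below 2k * 4k / n
  set.seed(55)
  k <- 5; n <- 400
  si_moved <- replicate(60, {
    q <- simulate_quartet(sim_config(genome_size = n, gene_length = 1,
                                     n_events = 1, event_size_mean = 1,
                                     event_size_sd = 0, seed = NULL))
    gs <- quartet_genomes(q)
    mean(sapply(q$truth, synteny_index, g1 = gs$GA, g2 = gs$GB, k = k))
  })
  expect_lte(mean(si_moved), 2 * k * 4 * k / n)
})

test_that("false positives are counted against the truth set", {
  rep <- data.frame(gene_id = c("a", "b", "c"),
                    verdict = c("hgt", "hgt", "translocation-like"),
                    stringsAsFactors = FALSE)
  expect_equal(evaluate_false_positives(rep, truth = "a"), 1)
  expect_equal(evaluate_false_positives(rep, truth = c("a", "b")), 0)
  expect_equal(evaluate_false_positives(rep[0, ], truth = "a"), 0)
})
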