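test_that("genome construction validates identifiers", {
  g <- genome("G1", c("a", "b", "c"))
  expect_s3_class(g, "genome")
  expect_length(g, 3)
  expect_error(genome("G1", character(0)), "at least one gene")
  expect_error(genome("G1", c("a", "b", "a")), "duplicated")
  expect_error(genome("G1", c("a", NA)), "missing")
})

test_that("core set and symmetric difference follow set arithmetic", {
  g1 <- genome("G1", c("a", "b", "c"))
  g2 <- genome("G2", c("b", "c", "d"))
  expect_equal(core_set(g1, g2), c("b", "c"))
  expect_equal(core_set(g1, g1), c("a", "b", "c"))
  expect_equal(core_set(g1, genome("G3", c("x", "y"))), character(0))
  expect_equal(symmetric_difference_size(g1, g2), 2)
  expect_equal(symmetric_difference_size(g1, g1), 0)
})

test_that("singular probability is |symdiff| / (2n) with mean-size n", {
  # two size-1000 genomes with a core of 200 genes: |symdiff| = 1600, p = 0.8
  core <- sprintf("c%03d", 1:200)
  g1 <- genome("G1", c(core, sprintf("x%03d", 1:800)))
  g2 <- genome("G2", c(core, sprintf("y%03d", 1:800)))
  expect_equal(symmetric_difference_size(g1, g2), 1600)
  expect_equal(singular_probability(g1, g2), 0.8)
  expect_equal(singular_probability(g1, g1), 0)
  # unequal sizes: arithmetic-mean n, with a warning
  g3 <- genome("G3", c("a", "b", "c"))
  g4 <- genome("G4", c("a", "b", "c", "d", "e"))
  expect_warning(p <- singular_probability(g3, g4), "differ in size")
  expect_equal(p, 2 / 8)
})

test_that("k-neighborhood wraps circularly and saturates", {
  g <- genome("G", c("a", "b", "c", "d", "e", "f"))
  expect_setequal(k_neighborhood(g, "a", 1), c("f", "b"))
  expect_setequal(k_neighborhood(g, "d", 2), c("b", "c", "e", "f"))
  g3 <- genome("G3", c("a", "b", "c"))
  expect_setequal(k_neighborhood(g3, "a", 5), c("b", "c"))
  expect_error(k_neighborhood(g, "z", 1), "not present")
  expect_error(k_neighborhood(g, "a", 0), "positive integer")
})

test_that("synteny index matches worked neighborhoods", {
  g1 <- genome("G1", c("a", "b", "c", "d", "e", "f"))
  g2 <- genome("G2", c("a", "b", "c", "e", "d", "f"))
  expect_equal(synteny_index("b", g1, g2, k = 1), 2)  # {a,c} in both
  expect_equal(synteny_index("d", g1, g2, k = 1), 1)  # {c,e} vs {e,f}
  # identical genomes: SI = 2k for every gene
  g <- genome("G", letters[1:9])
  expect_true(all(si_profile(g, g, 2) == 4))
  # non-core gene: SI 0 by convention
  expect_equal(synteny_index("z", g1, g2, k = 1), 0)
})

test_that("SI is symmetric, rotation-invariant and bounded", {
  set.seed(42)
  for (rep in 1:20) {
    pr <- random_genome_pair(sample(5:30, 1), sample(0:10, 1),
                             sample(0:10, 1))
    k <- sample(1:4, 1)
    core <- core_set(pr$g1, pr$g2)
    rot <- sample(seq_along(pr$g2$genes), 1)
    g2_rot <- genome("G2r", c(pr$g2$genes[-seq_len(rot)],
                              pr$g2$genes[seq_len(rot)]))
    for (gene in core) {
      si <- synteny_index(gene, pr$g1, pr$g2, k)
      expect_identical(si, synteny_index(gene, pr$g2, pr$g1, k))
      expect_identical(si, synteny_index(gene, pr$g1, g2_rot, k))
      expect_gte(si, 0)
      expect_lte(si, min(2 * k, length(pr$g1) - 1, length(pr$g2) - 1))
    }
  }
})

test_that("si_profile agrees with the brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    pr <- random_genome_pair(sample(4:25, 1), sample(0:8, 1), sample(0:8, 1))
    for (k in 1:3) {
      prof <- si_profile(pr$g1, pr$g2, k)
      for (gene in names(prof)) {
        expect_identical(unname(prof[gene]),
                         brute_si(gene, pr$g1$genes, pr$g2$genes, k))
      }
    }
  }
})
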