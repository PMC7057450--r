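# Shared fixtures and independent oracles, all built in code.

# Independent brute-force synteny-index oracle: computes circular distances
# of every position to the focal gene by explicit min(|i-j|, n-|i-j|) scan
# and intersects the resulting neighbor sets. Deliberately avoids the
# package's offset-indexing route.
brute_si <- function(gene, genes1, genes2, k) {
  nb <- function(genes, gene, k) {
    n <- length(genes)
    i <- which(genes == gene)
    d <- abs(seq_len(n) - i)
    d <- pmin(d, n - d)
    genes[d >= 1 & d <= k]
  }
  if (!(gene %in% genes1) || !(gene %in% genes2)) return(0L)
  length(intersect(nb(genes1, gene, k), nb(genes2, gene, k)))
}

# Random circular genome pair sharing a core of the requested size, with
# extra private genes on each side, both orders shuffled.
random_genome_pair <- function(n_core, n_extra1 = 0, n_extra2 = 0) {
  core <- sprintf("c%03d", seq_len(n_core))
  e1 <- if (n_extra1 > 0) sprintf("x%03d", seq_len(n_extra1)) else character(0)
  e2 <- if (n_extra2 > 0) sprintf("y%03d", seq_len(n_extra2)) else character(0)
  list(g1 = genome("G1", sample(c(core, e1))),
       g2 = genome("G2", sample(c(core, e2))))
}

# A pair of sequences of length n with an exact Hamming fraction h: the
# differing sites occupy positions offset+1 .. offset+h*n.
seq_with_flips <- function(n, n_flips, offset = 0) {
  s <- rep("A", n)
  if (n_flips > 0) s[offset + seq_len(n_flips)] <- "C"
  paste0(s, collapse = "")
}

# Handmade four-genome detection fixture. Gene "f" is translocated in S2
# (SI 0 at k = 1, the only suspected gene); its strain sequences are
# engineered to a chosen Hamming distance h_f_S while the witness "c" and
# the reference distances imply an expected strain Hamming of 0.25.
# With h_f_S = 0 the expected verdict is hgt; with h_f_S = 0.25,
# translocation-like.
detection_fixture <- function(h_f_S = 0, n_sites = 2000,
                              with_witness = TRUE) {
  genes1 <- c("a", "b", "c", "d", "e", "f", "g", "h")
  genes2 <- c("a", "f", "b", "c", "d", "e", "g", "h")
  genomes <- list(S1 = genome("S1", genes1),
                  S2 = genome("S2", genes2),
                  R1 = genome("R1", genes1),
                  R2 = genome("R2", genes1))
  blank <- seq_with_flips(n_sites, 0)
  aln <- list(
    f = ortholog_alignment("f", c(
      S1 = blank,
      S2 = seq_with_flips(n_sites, round(h_f_S * n_sites)),
      R1 = seq_with_flips(n_sites, round(0.3 * n_sites)),  # h_f(R) = 0.3
      R2 = blank)))
  if (with_witness) {
    aln$c <- ortholog_alignment("c", c(
      S1 = blank,
      S2 = seq_with_flips(n_sites, round(0.25 * n_sites)),  # h_c(S) = 0.25
      R1 = seq_with_flips(n_sites, round(0.3 * n_sites), offset = 600),
      R2 = blank))                                          # h_c(R) = 0.3
  }
  list(genomes = genomes, alignments = aln)
}

# One seeded quartet under pure vertical evolution (no rearrangements) and
# the four observed Hamming distances of a gene/witness pair, used for
# type-I checks of the witness test.
vertical_quartet_distances <- function(gene_length = 1000) {
  q <- simulate_quartet(sim_config(genome_size = 2,
                                   gene_length = gene_length,
                                   n_events = 0, seed = NULL))
  g <- q$GA$genes[1]; w <- q$GA$genes[2]
  h <- function(id1, id2, gene) hamming(q[[id1]]$seqs[[gene]],
                                        q[[id2]]$seqs[[gene]])$value
  list(h_g_S = h("GA", "GB", g), h_g_R = h("GWA", "GWB", g),
       h_w_R = h("GWA", "GWB", w), h_w_S = h("GA", "GB", w),
       n_sites = gene_length)
}
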