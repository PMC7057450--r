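#' Circular gene-order genome
#'
#' A genome is modelled at the resolution of genes: an ordered sequence of
#' unique gene-family identifiers, interpreted circularly (the last gene is
#' adjacent to the first). Duplicate identifiers (paralogs) are rejected, as
#' the synteny model assumes at most one copy of each family per genome.
#'
#' @param genome_id Single string naming the genome.
#' @param genes Character vector of gene-family identifiers in genomic order.
#'
#' @return An object of class `genome`: a list with elements `genome_id` and
#'   `genes`.
#' @examples
#' g1 <- genome("G1", c("a", "b", "c", "d", "e", "f"))
#' length(g1)
#' @export
genome <- function(genome_id, genes) {
  if (length(genome_id) != 1L || is.na(genome_id)) {
    stop("'genome_id' must be a single non-missing string")
  }
  genes <- as.character(genes)
  if (length(genes) < 1L) {
    stop("genome '", genome_id, "' must contain at least one gene")
  }
  if (anyNA(genes)) {
    stop("genome '", genome_id, "' contains missing gene identifiers")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("genome '", genome_id, "' contains duplicated gene identifiers (",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "",
         "); paralogs are not supported")
  }
  structure(list(genome_id = as.character(genome_id), genes = genes),
            class = "genome")
}

#' @export
length.genome <- function(x) length(x$genes)

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", length(x$genes), " genes (circular)\n",
      sep = "")
  cat("  ", paste(utils::head(x$genes, 8L), collapse = " "),
      if (length(x$genes) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

.check_genome <- function(g, arg = "genome") {
  if (!inherits(g, "genome")) stop("'", arg, "' must be a genome object")
  g
}

#' Core set of two genomes
#'
#' The core set is the intersection of the gene contents of two genomes:
#' the genes present in both.
#'
#' @param g1,g2 `genome` objects.
#' @return Character vector of shared gene identifiers, sorted.
#' @examples
#' core_set(genome("A", c("a", "b", "c")), genome("B", c("b", "c", "d")))
#' @export
core_set <- function(g1, g2) {
  .check_genome(g1, "g1"); .check_genome(g2, "g2")
  sort(intersect(g1$genes, g2$genes))
}

#' Size of the symmetric difference of two gene contents
#'
#' Counts genes present in exactly one of the two genomes (the "singular"
#' genes). With core size `c`, this is `|G1| + |G2| - 2c`.
#'
#' @param g1,g2 `genome` objects.
#' @return Integer count.
#' @export
symmetric_difference_size <- function(g1, g2) {
  .check_genome(g1, "g1"); .check_genome(g2, "g2")
  length(setdiff(g1$genes, g2$genes)) + length(setdiff(g2$genes, g1$genes))
}

#' Probability of hitting a singular gene by chance
#'
#' For two genomes of (mean) size `n`, a uniformly drawn gene is singular
#' (present in only one of the two genomes) with probability
#' `p = |symmetric difference| / (2n)`. The model assumes equal genome sizes;
#' when they differ, `n` is taken as the arithmetic mean of the two sizes and
#' a warning is emitted.
#'
#' @param g1,g2 `genome` objects.
#' @return Probability in `[0, 1]`.
#' @examples
#' # identical gene content: no singular genes
#' singular_probability(genome("A", letters), genome("B", rev(letters)))
#' @export
singular_probability <- function(g1, g2) {
  .check_genome(g1, "g1"); .check_genome(g2, "g2")
  n1 <- length(g1$genes); n2 <- length(g2$genes)
  if (n1 != n2) {
    warning("genomes '", g1$genome_id, "' (", n1, " genes) and '",
            g2$genome_id, "' (", n2, " genes) differ in size; ",
            "using their arithmetic mean as n")
  }
  n <- (n1 + n2) / 2
  symmetric_difference_size(g1, g2) / (2 * n)
}

## Circular neighborhood of the gene at position `pos` (1-based) in `genes`:
## the up-to-2k genes within k positions up/downstream, excluding the gene.
.neighborhood <- function(genes, pos, k) {
  n <- length(genes)
  if (n - 1L <= 2L * k) return(genes[-pos])
  off <- c(-(k:1L), seq_len(k))
  genes[(pos - 1L + off) %% n + 1L]
}

#' k-neighborhood of a gene on a circular genome
#'
#' The set of genes at circular distance at most `k` from the focal gene
#' (at most `k` genes upstream or downstream), excluding the gene itself.
#' When the genome has no more than `2k + 1` genes, the neighborhood
#' saturates to all other genes.
#'
#' @param g A `genome`.
#' @param gene Gene identifier; must be present in `g`.
#' @param k Neighborhood radius (positive integer).
#' @return Character vector (a set) of at most `2k` gene identifiers.
#' @examples
#' g <- genome("G", c("a", "b", "c", "d", "e", "f"))
#' k_neighborhood(g, "a", 1) # circular wrap: f and b
#' @export
k_neighborhood <- function(g, gene, k) {
  .check_genome(g, "g")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  pos <- match(gene, g$genes)
  if (is.na(pos)) {
    stop("gene '", gene, "' is not present in genome '", g$genome_id, "'")
  }
  .neighborhood(g$genes, pos, k)
}

#' Synteny index of a gene between two genomes
#'
#' The synteny index (SI) of a core gene is the number of genes common to its
#' k-neighborhoods in the two genomes: `|N_k(G1, g) %intersect% N_k(G2, g)|`,
#' an integer in `[0, 2k]`. A gene outside the core set has SI 0 by
#' convention. SI near `2k` indicates a conserved local gene order; SI near 0
#' indicates the gene sits in a different neighborhood in the two genomes
#' (as after horizontal transfer, translocation, or duplication).
#'
#' @param gene Gene identifier.
#' @param g1,g2 `genome` objects.
#' @param k Neighborhood radius (positive integer).
#' @return Integer SI value.
#' @examples
#' g1 <- genome("G1", c("a", "b", "c", "d", "e", "f"))
#' g2 <- genome("G2", c("a", "b", "c", "e", "d", "f"))
#' synteny_index("b", g1, g2, k = 1) # 2: both neighborhoods are {a, c}
#' synteny_index("d", g1, g2, k = 1) # 1: {c, e} vs {e, f}
#' @export
synteny_index <- function(gene, g1, g2, k) {
  .check_genome(g1, "g1"); .check_genome(g2, "g2")
  p1 <- match(gene, g1$genes)
  p2 <- match(gene, g2$genes)
  if (is.na(p1) || is.na(p2)) return(0L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  length(intersect(.neighborhood(g1$genes, p1, k),
                   .neighborhood(g2$genes, p2, k)))
}

#' Synteny-index profile over the core set
#'
#' Computes the synteny index of every core gene of a genome pair.
#'
#' @param g1,g2 `genome` objects.
#' @param k Neighborhood radius (positive integer).
#' @return Named integer vector of SI values, one per core gene, ordered by
#'   gene identifier.
#' @export
si_profile <- function(g1, g2, k) {
  .check_genome(g1, "g1"); .check_genome(g2, "g2")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  core <- core_set(g1, g2)
  pos1 <- match(core, g1$genes)
  pos2 <- match(core, g2$genes)
  si <- integer(length(core))
  for (i in seq_along(core)) {
    si[i] <- length(intersect(.neighborhood(g1$genes, pos1[i], k),
                              .neighborhood(g2$genes, pos2[i], k)))
  }
  names(si) <- core
  si
}
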