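## Genome-quartet simulator used for specificity evaluation.
##
## A root genome GA (random gene order, IID uniform ACGT sequences, per-gene
## mutation rates drawn from a truncated normal) spawns three children: two
## witness genomes GWA and GWB with identical gene order, and GB, which after
## point mutation undergoes a series of circular block-swap rearrangements.
## Every gene in a swapped block is additionally hyper-mutated by a
## multiplicative HGT rate factor, mimicking the elevated divergence of
## transferred genes. The union of swapped-block genes is the truth set
## against which false positives are counted.

.SIM_BASES <- charToRaw("ACGT")

#' Simulator configuration
#'
#' Defaults reproduce the evaluation conditions of the quartet study:
#' genome size 1000 genes, gene length 1000 nt, 10 rearrangement events of
#' mean block size 7 genes, and an HGT mutation-rate factor of 10. Per-gene
#' mutation rates are per-site substitution probabilities per parent-to-child
#' copy, drawn from `Normal(rate_mean, rate_sd)` truncated below at 0.
#'
#' @param genome_size Number of genes (>= 2).
#' @param gene_length Nucleotides per gene (>= 1).
#' @param rate_mean,rate_sd Mean and sd of the per-gene substitution
#'   probability.
#' @param n_events Number of block-swap rearrangement events (>= 0).
#' @param event_size_mean,event_size_sd Mean and sd of the swapped block
#'   size, in genes (a size-`b` block is the focal gene plus
#'   `floor((b-1)/2)` genes upstream and the remainder downstream).
#' @param hgt_factor Multiplier (>= 1) applied to the rate of every gene in
#'   a swapped block.
#' @param seed Integer seed making the whole quartet reproducible, or `NULL`
#'   to use the caller's RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_size = 1000, gene_length = 1000,
                       rate_mean = 0.05, rate_sd = 0.01,
                       n_events = 10, event_size_mean = 7,
                       event_size_sd = 1, hgt_factor = 10, seed = NULL) {
  if (genome_size < 2) stop("'genome_size' must be >= 2")
  if (gene_length < 1) stop("'gene_length' must be >= 1")
  if (rate_mean <= 0 || rate_mean >= 1) stop("'rate_mean' must be in (0, 1)")
  if (rate_sd < 0) stop("'rate_sd' must be >= 0")
  if (n_events < 0) stop("'n_events' must be >= 0")
  if (event_size_mean < 1) stop("'event_size_mean' must be >= 1")
  if (event_size_sd < 0) stop("'event_size_sd' must be >= 0")
  if (hgt_factor < 1) stop("'hgt_factor' must be >= 1")
  structure(list(genome_size = as.integer(genome_size),
                 gene_length = as.integer(gene_length),
                 rate_mean = rate_mean, rate_sd = rate_sd,
                 n_events = as.integer(n_events),
                 event_size_mean = event_size_mean,
                 event_size_sd = event_size_sd,
                 hgt_factor = hgt_factor,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

.check_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("'cfg' must be a sim_config object")
  cfg
}

.gene_names <- function(n) {
  sprintf("g%0*d", max(4L, nchar(n - 1L)), seq_len(n) - 1L)
}

## draw-order: sequences (one uniform draw per site, gene by gene),
## then rates
.generate_root_impl <- function(cfg) {
  n <- cfg$genome_size; len <- cfg$gene_length
  ids <- .gene_names(n)
  chars <- c("A", "C", "G", "T")
  mat <- matrix(sample(chars, n * len, replace = TRUE), nrow = len)
  seqs <- apply(mat, 2L, paste0, collapse = "")
  names(seqs) <- ids
  rates <- pmax(0, stats::rnorm(n, cfg$rate_mean, cfg$rate_sd))
  names(rates) <- ids
  structure(list(genome_id = "GA", genes = ids, seqs = seqs, rates = rates),
            class = "sim_genome")
}

#' Generate the root genome of a simulated quartet
#'
#' Genes are named by their initial order (`g0000`, `g0001`, ...); each gene
#' gets an IID uniform ACGT sequence and a mutation rate drawn from
#' `Normal(rate_mean, rate_sd)` truncated below at 0.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_genome`: list with `genome_id`, `genes`
#'   (circular order), `seqs` (named character), `rates` (named numeric).
#' @export
generate_root <- function(cfg) {
  .check_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  .generate_root_impl(cfg)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", x$genome_id, ": ", length(x$genes), " genes x ",
      nchar(x$seqs[[1L]]), " nt\n", sep = "")
  invisible(x)
}

## substitute each site independently with probability p, to a uniformly
## chosen different base
.mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  x <- charToRaw(seq)
  hit <- which(stats::runif(length(x)) < p)
  if (length(hit) == 0L) return(seq)
  cur <- match(x[hit], .SIM_BASES)
  shift <- sample.int(3L, length(hit), replace = TRUE)
  x[hit] <- .SIM_BASES[(cur - 1L + shift) %% 4L + 1L]
  rawToChar(x)
}

#' Point-mutate a copy of a simulated genome
#'
#' Returns a copy of `parent` in which every site of every gene has been
#' substituted independently with probability `min(1, rate * factor)` to a
#' uniformly chosen different base (the Jukes-Cantor single-step kernel),
#' where `rate` is the gene's own mutation rate. Gene order and rates are
#' inherited unchanged.
#'
#' @param parent A `sim_genome`.
#' @param factor Non-negative rate multiplier (1 for an ordinary
#'   parent-to-child copy).
#' @param genome_id Identifier for the copy.
#' @return A `sim_genome`.
#' @export
mutate_copy <- function(parent, factor = 1, genome_id = parent$genome_id) {
  if (!inherits(parent, "sim_genome")) stop("'parent' must be a sim_genome")
  if (factor < 0) stop("'factor' must be >= 0")
  child <- parent
  child$genome_id <- genome_id
  if (factor > 0) {
    pr <- pmin(1, parent$rates * factor)
    for (i in seq_along(child$seqs)) {
      child$seqs[[i]] <- .mutate_seq(child$seqs[[i]], pr[[i]])
    }
  }
  child
}

## One rearrangement event: draw a focal position, a block size, and a
## partner position; resample the triple until the two equal-size circular
## blocks are disjoint from each other and from previously swapped positions.
## Swaps the blocks in the gene order and returns the positions involved.
.draw_event <- function(n, used, cfg, max_tries = 1000L) {
  half_max <- (n - 1L) %/% 2L
  for (try in seq_len(max_tries)) {
    focal <- sample.int(n, 1L)
    b <- as.integer(round(stats::rnorm(1L, cfg$event_size_mean,
                                       cfg$event_size_sd)))
    if (b < 1L) b <- 1L
    if (b > half_max) next
    partner <- sample.int(n, 1L)
    left <- (b - 1L) %/% 2L
    off <- seq.int(-left, b - 1L - left)
    block_a <- (focal - 1L + off) %% n + 1L
    block_b <- (partner - 1L + off) %% n + 1L
    pos <- c(block_a, block_b)
    if (anyDuplicated(pos) || any(used[pos])) next
    return(list(block_a = block_a, block_b = block_b))
  }
  stop("could not place non-overlapping rearrangement blocks after ",
       max_tries, " attempts; reduce n_events or event size")
}

#' Apply block-swap rearrangements to a simulated genome
#'
#' Performs `cfg$n_events` rounds. Each round draws a focal gene, a block
#' size from `Normal(event_size_mean, event_size_sd)` (rounded, floored at
#' 1), and a partner gene; the two equal-size circular blocks are swapped in
#' place. Blocks are kept disjoint within and across rounds by resampling on
#' collision. Every gene in either block is then hyper-mutated with
#' probability `min(1, rate * hgt_factor)` per site and recorded in the
#' truth set.
#'
#' @param g A `sim_genome`.
#' @param cfg A [sim_config()] (its `seed` is *not* applied here; seed the
#'   RNG upstream or use [simulate_quartet()]).
#' @return List with `genome` (the rearranged `sim_genome`) and `truth`
#'   (character vector of genes involved in any event).
#' @export
apply_rearrangements <- function(g, cfg) {
  if (!inherits(g, "sim_genome")) stop("'g' must be a sim_genome")
  .check_sim_config(cfg)
  n <- length(g$genes)
  used <- logical(n)
  truth <- character(0)
  for (ev in seq_len(cfg$n_events)) {
    e <- .draw_event(n, used, cfg)
    swapped <- g$genes[c(e$block_b, e$block_a)]
    g$genes[c(e$block_a, e$block_b)] <- swapped
    used[c(e$block_a, e$block_b)] <- TRUE
    for (gene in swapped) {
      p <- min(1, g$rates[[gene]] * cfg$hgt_factor)
      g$seqs[[gene]] <- .mutate_seq(g$seqs[[gene]], p)
    }
    truth <- c(truth, swapped)
  }
  list(genome = g, truth = sort(unique(truth)))
}

#' Simulate a genome quartet for specificity evaluation
#'
#' Builds the four-genome study design from one seeded random stream:
#' root `GA`; witness genomes `GWA` and `GWB`, each an independently
#' point-mutated copy of `GA` with identical gene order; and `GB`, a
#' point-mutated copy of `GA` subjected to block-swap rearrangements with
#' hyper-mutation of the swapped genes. Draw order (root sequences, root
#' rates, GWA, GWB, GB mutation, rearrangement events) is fixed, so a given
#' seed yields a byte-identical quartet.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_quartet`: list with `GA`, `GB`, `GWA`,
#'   `GWB` (`sim_genome`s), `truth` (genes involved in any rearrangement),
#'   and `config`.
#' @examples
#' q <- simulate_quartet(sim_config(genome_size = 30, gene_length = 60,
#'                                  n_events = 1, event_size_mean = 3,
#'                                  event_size_sd = 0, seed = 1))
#' q$truth
#' @export
simulate_quartet <- function(cfg) {
  .check_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ga <- .generate_root_impl(cfg)
  gwa <- mutate_copy(ga, 1, genome_id = "GWA")
  gwb <- mutate_copy(ga, 1, genome_id = "GWB")
  gb0 <- mutate_copy(ga, 1, genome_id = "GB")
  re <- apply_rearrangements(gb0, cfg)
  structure(list(GA = ga, GB = re$genome, GWA = gwa, GWB = gwb,
                 truth = re$truth, config = cfg),
            class = "sim_quartet")
}

#' @export
print.sim_quartet <- function(x, ...) {
  cat("<sim_quartet> ", length(x$GA$genes), " genes x ",
      x$config$gene_length, " nt; ", x$config$n_events,
      " rearrangement event(s); |truth| = ", length(x$truth), "\n", sep = "")
  invisible(x)
}

#' Extract plain genomes from a simulated quartet
#'
#' @param q A `sim_quartet`.
#' @return Named list of four [genome()] objects (`GA`, `GB`, `GWA`, `GWB`).
#' @export
quartet_genomes <- function(q) {
  if (!inherits(q, "sim_quartet")) stop("'q' must be a sim_quartet")
  ids <- c("GA", "GB", "GWA", "GWB")
  stats::setNames(lapply(ids, function(id) genome(id, q[[id]]$genes)), ids)
}

#' Extract ortholog alignments from a simulated quartet
#'
#' Simulated sequences contain no indels, so the per-gene copies across the
#' four genomes are already an alignment.
#'
#' @param q A `sim_quartet`.
#' @return Named list of ortholog alignments keyed by gene id, as consumed
#'   by [si_hgt()].
#' @export
quartet_alignments <- function(q) {
  if (!inherits(q, "sim_quartet")) stop("'q' must be a sim_quartet")
  ids <- c("GA", "GB", "GWA", "GWB")
  genes <- q$GA$genes
  out <- lapply(genes, function(g) {
    seqs <- vapply(ids, function(id) q[[id]]$seqs[[g]], character(1))
    ortholog_alignment(g, seqs)
  })
  stats::setNames(out, genes)
}

#' Count false-positive HGT calls against a simulation truth set
#'
#' @param calls An `si_hgt` object or its report data frame.
#' @param truth Character vector of genes genuinely involved in a
#'   rearrangement event.
#' @return Integer: genes with verdict `hgt` that are not in `truth`.
#' @export
evaluate_false_positives <- function(calls, truth) {
  report <- if (inherits(calls, "si_hgt")) calls$report else calls
  if (!is.data.frame(report) || !all(c("gene_id", "verdict") %in%
                                     names(report))) {
    stop("'calls' must be an si_hgt object or a report data frame")
  }
  sum(report$verdict == "hgt" & !(report$gene_id %in% truth))
}
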