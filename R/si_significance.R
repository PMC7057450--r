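#' Chernoff threshold for a synteny index arising by chance
#'
#' Between distantly related genomes (large singular-gene probability `p`),
#' a low synteny index can arise without any transfer, simply because most
#' neighborhood genes are singular. Among the `2k` neighborhood genes the
#' number that fail to be shared concentrates around its mean, and a Chernoff
#' bound yields: with probability at most `delta_si`, a core gene shows by
#' chance
#'
#'   `SI < 2k(1 - p) - sqrt(-k * log(delta_si))`
#'
#' (natural log). An SI strictly below this threshold is "SI HGT suspected"
#' at level `delta_si`. The threshold may be negative, in which case no SI
#' value can be called suspected at that `k` (see [min_k()]).
#'
#' @param k Neighborhood radius (positive integer).
#' @param p Singular-gene probability, `|G1 sym.diff G2| / (2n)`; see
#'   [singular_probability()].
#' @param delta_si Significance level in `(0, 1]`.
#' @return Real-valued threshold (possibly negative).
#' @examples
#' si_random_threshold(k = 10, p = 0.8, delta_si = 0.05) # -1.47: k too small
#' si_random_threshold(k = 30, p = 0.8, delta_si = 0.05) # 2.5
#' @export
si_random_threshold <- function(k, p, delta_si) {
  if (any(k < 1)) stop("'k' must be >= 1")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  if (any(delta_si <= 0 | delta_si > 1)) {
    stop("'delta_si' must be in (0, 1]; the bound diverges at 0")
  }
  2 * k * (1 - p) - sqrt(-k * log(delta_si))
}

#' Chernoff tail bound for a centered sum of m indicators
#'
#' Upper bound `min(1, exp(-2 a^2 / m))` on the probability that a sum of
#' `m` bounded independent terms exceeds its mean by more than `a`. In the
#' synteny-index application `m = 2k` (the neighborhood size) and
#' `a = 2k - SI - 2kp` is the centered count of non-shared neighbors, so the
#' bound shrinks exponentially as SI grows: larger SI deficits carry
#' exponentially stronger evidence.
#'
#' @param a Deviation from the mean (real).
#' @param m Number of summed indicator terms (positive integer).
#' @return Probability bound in `[0, 1]`.
#' @examples
#' # inverting the bound at a = sqrt(-k log(delta)) with m = 2k returns delta
#' chernoff_tail(sqrt(-10 * log(0.05)), m = 20)
#' @export
chernoff_tail <- function(a, m) {
  if (any(m < 1)) stop("'m' must be >= 1")
  pmin(1, exp(-2 * a^2 / m))
}

#' Minimum neighborhood radius for a usable chance threshold
#'
#' The chance threshold of [si_random_threshold()] is non-negative only when
#' `k >= -log(delta_si) / (4 (1 - p)^2)`. Below that radius every SI value,
#' including 0, is compatible with chance at level `delta_si`, so the scan is
#' powerless. This returns the smallest integer `k` satisfying the bound.
#'
#' @param p Singular-gene probability in `[0, 1)`.
#' @param delta_si Significance level in `(0, 1)`.
#' @return Smallest usable integer `k` (at least 1).
#' @examples
#' min_k(p = 0.8, delta_si = 0.05) # 19
#' min_k(p = 0.9, delta_si = 0.05) # 75: k = 60 would not suffice
#' @export
min_k <- function(p, delta_si) {
  if (any(p < 0) || any(p >= 1)) {
    stop("'p' must be in [0, 1); at p = 1 no finite k suffices")
  }
  if (any(delta_si <= 0 | delta_si >= 1)) stop("'delta_si' must be in (0, 1)")
  bound <- -log(delta_si) / (4 * (1 - p)^2)
  # tiny slack so that exact integer boundaries are not pushed up by
  # floating-point noise in log()
  pmax(1L, as.integer(ceiling(bound - 1e-9)))
}

#' Flag SI-suspected genes against the chance threshold
#'
#' Applies the Chernoff chance threshold to a vector of per-gene synteny
#' indices. Refuses to run when `k` is below the minimum of [min_k()], since
#' the threshold would then be negative and no gene could ever be flagged;
#' silently returning an empty suspect list in that regime would be
#' misleading.
#'
#' @param si Named numeric vector of synteny indices (one per core gene).
#' @param k Neighborhood radius used to compute `si`.
#' @param p Singular-gene probability of the genome pair.
#' @param delta_si Significance level in `(0, 1)`.
#' @return A data frame with columns `gene_id`, `si`, `threshold`,
#'   `suspected` (suspected iff `si` is strictly below the threshold).
#' @export
flag_suspected <- function(si, k, p, delta_si) {
  k <- as.integer(k)
  kmin <- min_k(p, delta_si)
  if (k < kmin) {
    stop(sprintf(paste0(
      "neighborhood radius k=%d is too small for p=%.4g at delta_si=%g: ",
      "the chance threshold is negative, so no gene could be flagged; ",
      "the minimum usable radius is k=%d"), k, p, delta_si, kmin))
  }
  thr <- si_random_threshold(k, p, delta_si)
  ids <- names(si)
  if (is.null(ids)) ids <- as.character(seq_along(si))
  data.frame(gene_id = ids,
             si = as.numeric(si),
             threshold = rep(thr, length(si)),
             suspected = as.numeric(si) < thr,
             stringsAsFactors = FALSE)
}
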