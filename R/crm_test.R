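## Constant-relative-mutability (CRM) witness test.
##
## A gene flagged for low synteny may have been transferred horizontally --
## or merely translocated/duplicated within its genome. The two are separated
## by sequence divergence: a translocated gene has lived in its genome since
## the strains diverged, so its strain distance should match what other genes
## predict. Under the universal-pacemaker view, two genes maintain an
## (approximately) constant ratio rho between their mutation rates across
## lineages. Calibrating rho on a witness gene w and two reference organisms
## R1, R2 in Jukes-Cantor distance space yields an expected strain distance
## for the suspected gene g; a Chernoff bound on the deviation of the
## observed Hamming distance then gives a refutation test for vertical
## descent.

#' Relative mutability of a suspected gene versus a witness
#'
#' Ratio of Jukes-Cantor-corrected distances of the suspected gene and the
#' witness gene, both measured between the two reference organisms:
#' `rho = corr(h_g(R)) / corr(h_w(R))`. Under constant relative mutability
#' this ratio is the ratio of the two genes' mutation rates, and carries over
#' to any other pair of organisms.
#'
#' @param h_g_R Hamming distance of the suspected gene between the
#'   references, in `(0, 3/4)`.
#' @param h_w_R Hamming distance of the witness gene between the references,
#'   in `(0, 3/4)`.
#' @return Positive ratio `rho`.
#' @examples
#' crm_ratio(0.583, 0.541)  # 1.1756
#' @export
crm_ratio <- function(h_g_R, h_w_R) {
  h_g_R <- .h_value(h_g_R); h_w_R <- .h_value(h_w_R)
  if (any(h_w_R <= 0)) {
    stop("witness is uninformative: its reference-pair Hamming distance is 0")
  }
  jc_correct(h_g_R) / jc_correct(h_w_R)
}

#' Expected strain distance of a suspected gene under vertical descent
#'
#' Predicts the evolutionary distance of the suspected gene between the two
#' strains from the witness gene's strain distance, scaled by the relative
#' mutability calibrated on the references:
#' `d_g(S) = corr(h_g(R)) / corr(h_w(R)) * corr(h_w(S))`.
#'
#' @param h_g_R,h_w_R Reference-pair Hamming distances of gene and witness.
#' @param h_w_S Strain-pair Hamming distance of the witness, in `[0, 3/4)`.
#' @return Expected evolutionary distance (substitutions per site).
#' @examples
#' expected_strain_distance(0.583, 0.541, 0.008)  # 0.0095
#' @export
expected_strain_distance <- function(h_g_R, h_w_R, h_w_S) {
  crm_ratio(h_g_R, h_w_R) * jc_correct(h_w_S)
}

#' Chernoff bound on a Hamming-distance deviation
#'
#' Upper bound on the probability that the observed Hamming distance of a
#' gene of `n_sites` aligned sites deviates from its expectation by more than
#' the observed amount: `min(1, 2 exp(-2 n eps^2))` with
#' `eps = |observed - expected|`. Sites are modelled as independent
#' Bernoulli trials, so the bound is two-sided Hoeffding/Chernoff.
#'
#' @param observed_h Observed Hamming distance.
#' @param expected_h Expected Hamming distance (from [jc_invert()] of the
#'   expected evolutionary distance).
#' @param n_sites Number of aligned sites used (positive integer).
#' @return Probability bound in `[0, 1]`.
#' @export
deviation_probability <- function(observed_h, expected_h, n_sites) {
  if (any(n_sites < 1)) stop("'n_sites' must be >= 1")
  eps <- abs(.h_value(observed_h) - .h_value(expected_h))
  pmin(1, 2 * exp(-2 * n_sites * eps^2))
}

#' Deviation cutoff for refuting vertical descent
#'
#' The smallest deviation that is significant at level `delta_r` for a gene
#' of `n_sites` sites: `eps(delta_r) = sqrt(-log(delta_r / 2) / (2 n))`,
#' the exact inversion of [deviation_probability()]. An absolute deviation
#' strictly above this cutoff refutes the null hypothesis of vertical
#' descent at level `delta_r`.
#'
#' @param delta_r Significance level in `(0, 2)` (values at or above 2 would
#'   invert a capped bound).
#' @param n_sites Number of aligned sites used (positive integer).
#' @return Cutoff on the Hamming-distance deviation.
#' @examples
#' deviation_cutoff(0.05, 1472)  # 0.035
#' @export
deviation_cutoff <- function(delta_r, n_sites) {
  if (any(delta_r <= 0 | delta_r >= 2)) stop("'delta_r' must be in (0, 2)")
  if (any(n_sites < 1)) stop("'n_sites' must be >= 1")
  sqrt(-log(delta_r / 2) / (2 * n_sites))
}

#' Bonferroni correction of a probability bound
#'
#' Multiplies a per-test probability bound by the number of tests performed
#' for the same gene, capping at 1.
#'
#' @param p_bound Probability bound(s) in `[0, 1]`.
#' @param num_tests Number of completed tests (positive integer).
#' @return Corrected bound(s) in `[0, 1]`.
#' @export
bonferroni <- function(p_bound, num_tests) {
  if (any(num_tests < 1)) stop("'num_tests' must be >= 1")
  pmin(1, p_bound * num_tests)
}

## Vectorized witness-test core shared by run_witness_test() and the
## pipeline: all arguments except gene-level scalars may be vectors over
## (witness, reference-pair) combinations. Returns a data.frame; `status`
## records skipped tests (uninformative witness, JC saturation, missing
## distance) which do not count toward the Bonferroni total.
.witness_tests <- function(h_g_S, n_sites, delta_r,
                           witness_id, ref1, ref2,
                           h_g_R, h_w_R, h_w_S) {
  m <- length(witness_id)
  status <- rep("ok", m)
  status[is.na(h_g_R) | is.na(h_w_R) | is.na(h_w_S)] <- "skipped_missing"
  sat <- function(h) !is.na(h) & h >= .JC_MAX_H
  status[status == "ok" &
           (sat(h_g_R) | sat(h_w_R) | sat(h_w_S))] <- "skipped_saturated"
  status[status == "ok" & h_w_R <= 0] <- "skipped_witness_zero"
  ok <- status == "ok"

  expected_d <- expected_h <- deviation <- p_bound <- rep(NA_real_, m)
  if (any(ok)) {
    rho <- jc_correct(h_g_R[ok]) / jc_correct(h_w_R[ok])
    expected_d[ok] <- rho * jc_correct(h_w_S[ok])
    expected_h[ok] <- jc_invert(expected_d[ok])
    deviation[ok] <- h_g_S - expected_h[ok]
    p_bound[ok] <- pmin(1, 2 * exp(-2 * n_sites * deviation[ok]^2))
  }
  n_ok <- sum(ok)
  p_corr <- rep(NA_real_, m)
  if (n_ok > 0) p_corr[ok] <- bonferroni(p_bound[ok], n_ok)
  data.frame(witness_id = witness_id, ref1 = ref1, ref2 = ref2,
             status = status,
             h_g_R = h_g_R, h_w_R = h_w_R, h_w_S = h_w_S, h_g_S = h_g_S,
             n_sites = n_sites,
             expected_d = expected_d, expected_h = expected_h,
             deviation = deviation,
             p_bound = p_bound, p_bound_corrected = p_corr,
             cutoff = deviation_cutoff(delta_r, n_sites),
             refuted = !is.na(p_corr) & p_corr < delta_r,
             direction = ifelse(is.na(deviation), NA_character_,
                                ifelse(deviation < 0, "closer", "farther")),
             stringsAsFactors = FALSE)
}

#' Run one CRM witness test
#'
#' Executes the full witness-test chain for one (gene, witness, reference
#' pair) combination: expected strain distance via [expected_strain_distance()],
#' expected Hamming distance via [jc_invert()], signed deviation of the
#' observed strain Hamming distance, Chernoff probability bound, optional
#' Bonferroni correction, and the refutation decision at level `delta_r`.
#' The sign of the deviation is reported as a direction: `"closer"`
#' (observed below expectation, the signature of a recent transfer between
#' the strains) or `"farther"` (a CRM violation elsewhere, e.g. a transfer
#' involving a reference lineage).
#'
#' @param h_g_S Observed strain-pair Hamming distance of the suspected gene.
#' @param h_g_R,h_w_R,h_w_S Calibration Hamming distances (gene and witness
#'   between the references; witness between the strains).
#' @param n_sites Aligned sites used for the suspected gene between the
#'   strains.
#' @param delta_r Refutation significance level in `(0, 1)`.
#' @param num_tests Bonferroni denominator: completed tests for this gene
#'   (default 1).
#' @param gene_id,witness_id Optional identifiers carried into the result.
#' @return A one-row data frame (class `witness_test`) with columns
#'   `status`, `expected_d`, `expected_h`, `deviation`, `p_bound`,
#'   `p_bound_corrected`, `cutoff`, `refuted`, `direction`, plus the inputs.
#'   A test with an uninformative witness (`h_w_R = 0`) or a saturated
#'   distance is returned with a `skipped_*` status rather than an error.
#' @examples
#' # worked strain/reference example: engA suspected, gmk as witness
#' run_witness_test(h_g_S = 0.0237, h_g_R = 0.583, h_w_R = 0.541,
#'                  h_w_S = 0.008, n_sites = 1472, delta_r = 0.05)
#' @export
run_witness_test <- function(h_g_S, h_g_R, h_w_R, h_w_S, n_sites,
                             delta_r = 0.05, num_tests = 1,
                             gene_id = NA_character_,
                             witness_id = NA_character_) {
  if (length(h_g_S) != 1L) stop("'h_g_S' must be a single value")
  if (any(delta_r <= 0 | delta_r >= 1)) stop("'delta_r' must be in (0, 1)")
  res <- .witness_tests(h_g_S = .h_value(h_g_S),
                        n_sites = as.integer(n_sites), delta_r = delta_r,
                        witness_id = as.character(witness_id),
                        ref1 = NA_character_, ref2 = NA_character_,
                        h_g_R = .h_value(h_g_R), h_w_R = .h_value(h_w_R),
                        h_w_S = .h_value(h_w_S))
  # re-apply the caller's Bonferroni denominator
  if (!is.na(res$p_bound)) {
    res$p_bound_corrected <- bonferroni(res$p_bound, num_tests)
    res$refuted <- res$p_bound_corrected < delta_r
  }
  res$gene_id <- as.character(gene_id)
  class(res) <- c("witness_test", "data.frame")
  res
}
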