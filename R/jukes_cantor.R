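## Hamming distances between aligned gene copies and the Jukes-Cantor
## correction pair. Sites carrying a non-ACGT character (ambiguity code, gap,
## N) in either sequence are masked pairwise, keeping the per-site Bernoulli
## interpretation used by the deviation bounds.

# saturation guard: the JC correction diverges at h = 3/4
.JC_MAX_H <- 0.75 - 1e-9

#' Hamming distance between two aligned sequences
#'
#' Fraction of differing sites between two equal-length aligned nucleotide
#' sequences. Sites with a non-ACGT character (case-insensitive) in either
#' sequence are excluded from both numerator and denominator.
#'
#' @param seq1,seq2 Single strings of equal length (nucleotides, possibly
#'   with ambiguity characters or gaps).
#' @return An object of class `hamming_distance`: list with `value` (fraction
#'   in `[0, 1]`) and `n_sites_used` (sites remaining after masking).
#' @examples
#' hamming("ACGT", "ACGA")$value        # 0.25
#' hamming("ACNT", "ACGA")$value        # 1/3: site 3 masked
#' @export
hamming <- function(seq1, seq2) {
  if (length(seq1) != 1L || length(seq2) != 1L) {
    stop("'seq1' and 'seq2' must each be a single string")
  }
  b1 <- charToRaw(toupper(seq1))
  b2 <- charToRaw(toupper(seq2))
  if (length(b1) != length(b2)) {
    stop("sequences have unequal lengths (", length(b1), " vs ", length(b2), ")")
  }
  acgt <- charToRaw("ACGT")
  used <- (b1 %in% acgt) & (b2 %in% acgt)
  n_used <- sum(used)
  if (n_used == 0L) {
    stop("no usable sites: every position is masked in at least one sequence")
  }
  structure(list(value = sum(b1[used] != b2[used]) / n_used,
                 n_sites_used = n_used),
            class = "hamming_distance")
}

#' @export
print.hamming_distance <- function(x, ...) {
  cat(sprintf("<hamming_distance> %.6g over %d sites\n", x$value,
              x$n_sites_used))
  invisible(x)
}

.h_value <- function(h) {
  if (inherits(h, "hamming_distance")) h$value else as.numeric(h)
}

#' Jukes-Cantor distance correction
#'
#' Converts a normalized Hamming distance `h` into the expected number of
#' substitutions per site under the Jukes-Cantor model:
#' `d = -(3/4) log(1 - (4/3) h)`. The Hamming distance underestimates the
#' substitution count because multiple hits at a site are unobserved; the
#' correction inflates it accordingly. `h` must be below the saturation
#' point 3/4.
#'
#' @param h Hamming distance value(s) in `[0, 3/4)`, or a
#'   `hamming_distance` object.
#' @return Evolutionary distance(s), substitutions per site, `>= h`.
#' @examples
#' jc_correct(0)      # 0
#' jc_correct(0.583)  # 1.1266
#' @export
jc_correct <- function(h) {
  h <- .h_value(h)
  if (any(h < 0)) stop("'h' must be non-negative")
  if (any(h >= .JC_MAX_H)) {
    stop("Hamming distance ", format(max(h)), " is at or beyond the ",
         "Jukes-Cantor saturation point 3/4; the correction diverges")
  }
  -0.75 * log(1 - (4 / 3) * h)
}

#' Inverse Jukes-Cantor correction
#'
#' Converts an evolutionary distance back to the expected Hamming distance:
#' `h = (3/4)(1 - exp(-(4/3) d))`, a value in `[0, 3/4)`.
#'
#' @param d Non-negative evolutionary distance(s) (substitutions per site).
#' @return Expected Hamming distance(s).
#' @examples
#' jc_invert(jc_correct(0.3))  # 0.3: mutual inverses
#' @export
jc_invert <- function(d) {
  d <- as.numeric(d)
  if (any(d < 0)) stop("'d' must be non-negative")
  0.75 * (1 - exp(-(4 / 3) * d))
}
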