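#' Neutral fixation probability under fluctuating population size
#'
#' For a haploid (mtDNA-like) locus in a population of constant size N the
#' fixation probability of a new neutral variant is 1/N.  When the size
#' changes between generations, the probability becomes
#' `(N1 / N0) * (1 / N0)`: a growing population fixes new variants more
#' readily relative to its initial size, a shrinking one less.  The relation
#' is a first-order approximation, so values above 1 (possible under extreme
#' growth with tiny N0) are clamped to 1 with a warning.
#'
#' @param N0 initial effective size (> 0).
#' @param N1 effective size of the next generation (> 0).
#' @return a probability in (0, 1].
#' @examples
#' fixation_probability(1000, 2000)  # 2/1000
#' fixation_probability(1000, 500)   # 1/2000
#' @export
fixation_probability <- function(N0, N1) {
  if (any(N0 <= 0) || any(N1 <= 0)) stop("population sizes must be positive")
  q <- (N1 / N0) / N0
  if (any(q > 1)) {
    warning("fixation probability > 1 under extreme growth; clamped to 1")
    q <- pmin(q, 1)
  }
  q
}

#' Neutral substitution rate under fluctuating population size
#'
#' With constant size the neutral substitution rate equals the mutation rate
#' (new mutations per generation, N*mu, times fixation probability 1/N).
#' When the size fluctuates, the rate scales with the ratio of consecutive
#' sizes: `theta = (N1 / N0) * mu`.  Because coalescent dating looks backward
#' from the present, the `backward = TRUE` flag inverts the ratio
#' (`(N0 / N1) * mu`), the form used to counteract recent population growth
#' when estimating ancestral ages.
#'
#' @inheritParams fixation_probability
#' @param mu mutation rate (any per-time units; the output shares them).
#' @param backward invert the size ratio for backward-in-time scaling.
#' @return the substitution rate in the units of `mu`.
#' @examples
#' fluctuating_substitution_rate(1000, 2000, 2.15e-4)        # doubled
#' fluctuating_substitution_rate(1000, 2000, 2.15e-4, TRUE)  # halved
#' @export
fluctuating_substitution_rate <- function(N0, N1, mu, backward = FALSE) {
  if (any(N0 <= 0) || any(N1 <= 0)) stop("population sizes must be positive")
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (backward) (N0 / N1) * mu else (N1 / N0) * mu
}
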