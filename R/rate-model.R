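#' Mutation-rate configuration
#'
#' The clock is specified as a whole-molecule rate scalar in years per
#' mutation.  The default, one germline mutation every 4651 years, is the
#' published full-length human mtDNA rate derived from a per-site rate of
#' 1.3e-8 mutations/site/year over 16569 bases.  When only a per-site rate is
#' given, the scalar is derived as `1 / (mu * sequence_length)`.
#'
#' @param years_per_mutation positive scalar; years for one mutation to
#'   accumulate on the whole molecule.
#' @param mu_per_site_per_year optional per-site per-year rate, used to derive
#'   `years_per_mutation` when that is not supplied explicitly.
#' @param sequence_length molecule length in bases (human mtDNA default).
#' @param generation_time_years generation time, carried as metadata only:
#'   the rate scalar is already expressed in years.
#' @param rounding one of `"table"` (reproduce hand-calculation rounding:
#'   scale factors to 2 decimals, scaled rates to 3 significant figures,
#'   years-per-mutation and period years to integers) or `"exact"` (no
#'   intermediate rounding).
#' @return an object of class `rate_model`.
#' @export
rate_model <- function(years_per_mutation = NULL,
                       mu_per_site_per_year = NULL,
                       sequence_length = MTDNA_LENGTH,
                       generation_time_years = 20,
                       rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  if (is.null(years_per_mutation)) {
    years_per_mutation <- if (is.null(mu_per_site_per_year)) 4651
      else 1 / (mu_per_site_per_year * sequence_length)
  }
  if (is.null(mu_per_site_per_year))
    mu_per_site_per_year <- 1 / (years_per_mutation * sequence_length)
  stopifnot(years_per_mutation > 0, mu_per_site_per_year > 0,
            sequence_length > 0, generation_time_years > 0)
  structure(list(years_per_mutation = years_per_mutation,
                 mu_per_site_per_year = mu_per_site_per_year,
                 sequence_length = as.integer(sequence_length),
                 generation_time_years = generation_time_years,
                 rounding = rounding),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Mutation rate model\n")
  cat(sprintf("  one mutation every %.6g years (%.3g /site/year over %d bp)\n",
              x$years_per_mutation, x$mu_per_site_per_year, x$sequence_length))
  cat("  rounding mode:", x$rounding, "\n")
  invisible(x)
}

# round half away from zero: the convention of the hand-calculated tables
.round_half_up <- function(x) floor(x + 0.5)
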