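# Parent-offspring (trio) mutation-rate estimation with a
# three-component uncertainty model: genotyping (binomial counting),
# birth-date, and biological (between-offspring) variability, combined as
# a quadratic sum.

#' Per-year mutation rate from parent-offspring mutation counts
#'
#' Per offspring, rate = count / denominator / years; the point estimate
#' is the mean of the per-offspring rates. The denominator is either the
#' full (e.g. triploid) genome size in nt — a lower bound, since not all
#' sites are callable — or the number of callable sites (upper bound).
#'
#' @param counts De novo mutation counts per offspring.
#' @param denominator_nt Genome nt or callable sites (> 0).
#' @param years Elapsed years per offspring (> 0, recycled if scalar).
#' @return List of class `rate_estimate`: `rate` (mutations/nt/year),
#'   `per_offspring` data frame, `denominator_nt`.
#' @export
trio_rate <- function(counts, denominator_nt, years) {
  stopifnot(all(counts >= 0), denominator_nt > 0, all(years > 0))
  years <- rep_len(years, length(counts))
  per <- counts / denominator_nt / years
  structure(list(
    rate = mean(per),
    per_offspring = data.frame(count = counts, years = years, rate = per),
    denominator_nt = denominator_nt
  ), class = "rate_estimate")
}

#' Three-component uncertainty of the trio mutation rate
#'
#' Components, all in rate units (mutations/nt/year):
#' * genotyping: binomial SD of each count, sqrt(n p (1-p)) with the
#'   plug-in p = count / denominator, propagated through the rate formula
#'   and averaged over offspring in quadrature;
#' * birth date: SD of the elapsed time taken as one third of the birth
#'   window, propagated via d(rate)/d(years) = -rate / years;
#' * biological: SD of the per-offspring rates (requires >= 2 offspring;
#'   flagged NA otherwise).
#' The total SD is the quadratic sum of the three.
#'
#' @param counts,denominator_nt,years As in [trio_rate()].
#' @param birth_window_years Total uncertainty window on each birth date
#'   (years; default 1, recycled).
#' @return List: `sd_genotyping`, `sd_birth_date`, `sd_biological`,
#'   `sd_total`, `rate`.
#' @export
rate_uncertainty <- function(counts, denominator_nt, years,
                             birth_window_years = 1) {
  est <- trio_rate(counts, denominator_nt, years)
  years <- rep_len(years, length(counts))
  birth_window_years <- rep_len(birth_window_years, length(counts))
  k <- length(counts)

  p <- counts / denominator_nt
  sd_count <- sqrt(counts * (1 - p))
  sd_geno_i <- sd_count / denominator_nt / years
  sd_geno <- sqrt(sum(sd_geno_i^2)) / k # SD of the mean over offspring

  sd_t <- birth_window_years / 3
  sd_birth_i <- est$per_offspring$rate * sd_t / years
  sd_birth <- sqrt(sum(sd_birth_i^2)) / k

  sd_bio <- if (k >= 2) sd(est$per_offspring$rate) else NA_real_
  if (k < 2) warning("single offspring: biological component undefined")

  comps <- c(sd_geno, sd_birth, if (!is.na(sd_bio)) sd_bio)
  list(rate = est$rate,
       sd_genotyping = sd_geno, sd_birth_date = sd_birth,
       sd_biological = sd_bio,
       sd_total = sqrt(sum(comps^2)))
}
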