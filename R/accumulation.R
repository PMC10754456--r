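# Mutation-accumulation curve M(1/f).
#
# Sorting mutations by ascending inverse allele frequency u = 1/f and
# counting cumulatively yields M(u); under neutral exponential growth M is
# linear in u with slope proportional to the per-division mutation rate,
# so changes of slope flag changes of evolutionary parameters.

#' Build the mutation-accumulation curve M(1/f)
#'
#' @param records Variant table with a `freq` column in (0, 1\], or a bare
#'   numeric vector of allele frequencies. Records are expected to be
#'   already filtered (QUAL >= 30, depth >= 10, alt depth >= 3 by default).
#' @return Object of class `maf_curve`: `u` (strictly ascending 1/f grid),
#'   `m` (cumulative counts; ties on u share one grid point and jump M by
#'   the tie count), `n` (total variants), `f` (the raw frequencies).
#' @export
build_maf_curve <- function(records) {
  f <- if (is.data.frame(records)) records$freq else records
  f <- f[!is.na(f)]
  if (length(f) == 0) stop("no variants")
  if (any(f <= 0 | f > 1)) stop("allele frequencies must lie in (0, 1]")
  u_all <- sort(1 / f)
  u <- unique(u_all)
  m <- cumsum(tabulate(match(u_all, u), nbins = length(u)))
  structure(list(u = u, m = m, n = length(f), f = sort(f, decreasing = TRUE)),
            class = "maf_curve")
}

#' @export
print.maf_curve <- function(x, ...) {
  cat("M(1/f) curve:", x$n, "mutations, u in [",
      signif(min(x$u), 4), ",", signif(max(x$u), 4), "]\n")
  invisible(x)
}

# Left-closed bins of half-width hw centred at multiples of 2*hw on u.
curve_bin_index <- function(u, halfwidth = 0.25) {
  floor(u / (2 * halfwidth) + 0.5)
}

#' Bootstrap 95% confidence bands for the accumulation curve
#'
#' Mutations are binned on u with half-width 0.25 (bin centres at
#' multiples of 0.5, left-closed). All mutations are resampled with
#' replacement B times; per bin the 2.5%/97.5% quantiles of the bootstrap
#' counts give the band, and the same replicates propagated cumulatively
#' give a band on M at the bin centres.
#'
#' @param curve A [build_maf_curve()] result.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param halfwidth Bin half-width on u.
#' @return The curve with a `bins` data frame added: centre, count,
#'   ci_lo/ci_hi (per-bin count band), m, m_ci_lo/m_ci_hi (cumulative
#'   band).
#' @export
bootstrap_curve_ci <- function(curve, B = 1000, seed = 1,
                               halfwidth = 0.25) {
  stopifnot(inherits(curve, "maf_curve"), B >= 100)
  set.seed(seed)
  u_all <- rep(curve$u, diff(c(0, curve$m)))
  idx <- curve_bin_index(u_all, halfwidth)
  centres <- seq(min(idx), max(idx)) * 2 * halfwidth
  lev <- seq(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(lev))
  n <- length(u_all)
  boot_counts <- matrix(0L, nrow = B, ncol = length(lev))
  for (b in seq_len(B)) {
    res <- idx[sample.int(n, n, replace = TRUE)]
    boot_counts[b, ] <- tabulate(res - min(idx) + 1L, nbins = length(lev))
  }
  qs <- apply(boot_counts, 2, quantile, probs = c(0.025, 0.975))
  cum <- t(apply(boot_counts, 1, cumsum))
  qcum <- apply(cum, 2, quantile, probs = c(0.025, 0.975))
  curve$bins <- data.frame(
    centre = centres, count = counts,
    ci_lo = qs[1, ], ci_hi = qs[2, ],
    m = cumsum(counts), m_ci_lo = qcum[1, ], m_ci_hi = qcum[2, ]
  )
  curve$bootstrap <- list(B = B, seed = seed, halfwidth = halfwidth)
  curve
}
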