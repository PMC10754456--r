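# Longitudinal mutational-signature exposures.
#
# Mutations are binned along u = 1/f (bin half-width 0.5, i.e. unit-width
# tiling bins), each bin's 96-channel spectrum is decomposed on a
# signature catalog by non-negative least squares (Lawson-Hanson), and
# bootstrap resampling of mutations yields exposure confidence intervals.
# Exposures are fitted on raw counts so that they carry mutation units:
# the time integral downstream treats them as a mutation flux.

#' Bin mutations along the inverse-allele-frequency axis
#'
#' Contiguous left-closed bins of width `2 * halfwidth` with centres at
#' integer multiples of the width, covering the observed (or supplied)
#' u range; every contextful mutation falls in exactly one bin. Records
#' without a trinucleotide context are excluded with a warning.
#'
#' @param records Variant table with `freq` and `context`.
#' @param halfwidth Bin half-width on u (default 0.5).
#' @param u_range Optional numeric range to cover (e.g. the accepted range
#'   from [trim_outer_phases()]).
#' @return Object of class `binned_spectra`: matrix `counts` (bins x 96),
#'   vector `centers`, `totals`, and `n_no_context`.
#' @export
bin_spectra <- function(records, halfwidth = 0.5, u_range = NULL) {
  has_ctx <- !is.na(records$context) & records$context %in% sbs_channels()
  n_no <- sum(!has_ctx)
  if (n_no > 0) warning(n_no, " record(s) lack a valid context; excluded")
  rec <- records[has_ctx, , drop = FALSE]
  u <- 1 / rec$freq
  if (!is.null(u_range)) {
    inr <- u >= u_range[1] & u <= u_range[2]
    rec <- rec[inr, , drop = FALSE]
    u <- u[inr]
  }
  if (length(u) == 0) stop("no contextful mutations to bin")
  width <- 2 * halfwidth
  idx <- floor(u / width + 0.5) # left-closed: edge u = c + hw goes right
  lev <- seq(min(idx), max(idx))
  ch <- match(rec$context, sbs_channels())
  counts <- unclass(table(factor(idx, levels = lev),
                          factor(ch, levels = seq_len(96))))
  dimnames(counts) <- list(NULL, sbs_channels())
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, centers = lev * width,
                 halfwidth = halfwidth, totals = rowSums(counts),
                 n_no_context = n_no),
            class = "binned_spectra")
}

#' Fit non-negative signature exposures to a 96-channel spectrum
#'
#' Solves min || catalog %*% theta - counts ||_2 subject to theta >= 0
#' (Lawson-Hanson NNLS via `pracma::lsqnonneg`). Exposures are in
#' mutation-count units.
#'
#' @param spectrum Numeric 96-vector of channel counts (or a
#'   `binned_spectra` row index pair: see [exposure_series()]).
#' @param catalog 96 x S normalized catalog.
#' @return List: `theta` (named exposures), `residual_norm`, `flagged`
#'   (TRUE for an all-zero spectrum).
#' @export
fit_exposures <- function(spectrum, catalog) {
  stopifnot(length(spectrum) == nrow(catalog))
  if (sum(spectrum) == 0) {
    return(list(theta = setNames(rep(0, ncol(catalog)), colnames(catalog)),
                residual_norm = 0, flagged = TRUE))
  }
  fit <- pracma::lsqnonneg(catalog, as.numeric(spectrum))
  theta <- setNames(pmax(fit$x, 0), colnames(catalog))
  list(theta = theta,
       residual_norm = sqrt(sum((catalog %*% theta - spectrum)^2)),
       flagged = FALSE)
}

#' Per-bin exposures along the frequency axis
#'
#' @param bins A [bin_spectra()] result.
#' @param catalog 96 x S catalog.
#' @param min_count Bins with fewer mutations are flagged low-confidence.
#' @return Data frame: bin_center, signature, exposure, residual, total,
#'   low_confidence.
#' @export
exposure_series <- function(bins, catalog, min_count = 10) {
  stopifnot(inherits(bins, "binned_spectra"))
  rows <- lapply(seq_along(bins$centers), function(i) {
    fit <- fit_exposures(bins$counts[i, ], catalog)
    data.frame(
      bin_center = bins$centers[i],
      signature = names(fit$theta),
      exposure = unname(fit$theta),
      residual = fit$residual_norm,
      total = bins$totals[i],
      low_confidence = bins$totals[i] < min_count,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence intervals for per-bin exposures
#'
#' Mutations are resampled with replacement, re-binned and re-fitted B
#' times; per bin and signature the 2.5%/97.5% percentiles give the CI.
#' Sets larger than `subsample_threshold` mutations are first subsampled
#' without replacement to `subsample_to`, and the resulting exposures are
#' rescaled back to the full-count scale.
#'
#' @param records Variant table with `freq` and `context`.
#' @param catalog 96 x S catalog.
#' @param B Bootstrap replicates (>= 100; 1000 for production use).
#' @param halfwidth Bin half-width on u.
#' @param u_range Optional accepted u range.
#' @param seed Integer seed.
#' @param subsample_threshold,subsample_to Large-set subsampling bounds.
#' @return Data frame: bin_center, signature, exposure (point fit on the
#'   full data), ci_lo, ci_hi.
#' @export
bootstrap_exposures <- function(records, catalog, B = 1000, halfwidth = 0.5,
                                u_range = NULL, seed = 1,
                                subsample_threshold = 1e5,
                                subsample_to = 5e4) {
  stopifnot(B >= 100)
  set.seed(seed)
  scale <- 1
  rec <- records[!is.na(records$context), , drop = FALSE]
  if (nrow(rec) > subsample_threshold) {
    keep <- sample.int(nrow(rec), subsample_to)
    scale <- nrow(rec) / subsample_to
    rec <- rec[keep, , drop = FALSE]
  }
  point <- exposure_series(bin_spectra(rec, halfwidth, u_range), catalog)
  point$exposure <- point$exposure * scale

  centers <- sort(unique(point$bin_center))
  sigs <- colnames(catalog)
  boot <- array(NA_real_, dim = c(B, length(centers), length(sigs)),
                dimnames = list(NULL, centers, sigs))
  n <- nrow(rec)
  for (b in seq_len(B)) {
    res <- rec[sample.int(n, n, replace = TRUE), , drop = FALSE]
    bs <- suppressWarnings(bin_spectra(res, halfwidth, u_range))
    for (i in seq_along(bs$centers)) {
      ci <- as.character(bs$centers[i])
      if (!ci %in% as.character(centers)) next
      th <- fit_exposures(bs$counts[i, ], catalog)$theta * scale
      boot[b, ci, ] <- th
    }
  }
  qs <- apply(boot, c(2, 3), function(v) {
    v[is.na(v)] <- 0 # a bin absent from a replicate has exposure 0
    quantile(v, c(0.025, 0.975))
  })
  point$ci_lo <- NA_real_
  point$ci_hi <- NA_real_
  for (r in seq_len(nrow(point))) {
    ci <- as.character(point$bin_center[r])
    point$ci_lo[r] <- qs[1, ci, point$signature[r]]
    point$ci_hi[r] <- qs[2, ci, point$signature[r]]
  }
  point
}
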