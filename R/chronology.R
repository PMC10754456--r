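# Clock-signature chronometry.
#
# With theta(u) the exposure of clock-like signatures (SBS1, SBS5) along
# u = 1/f, and the arrow of time identified with increasing u, time in
# arbitrary units is
#     t_a.u.(u) = integral from u_min to u of theta * (1/u') du',
# the factor f = 1/u' normalizing the exposure by the population size
# (N is proportional to 1/f up to an unknown constant). Calibration to
# real units rescales t_a.u. so its maximum matches a known duration.

#' Time course in arbitrary units from clock-like exposures
#'
#' Cumulative trapezoidal integral of `theta / u` over the ascending u
#' grid; t_a.u.(u_min) = 0. With constant theta the result is exactly
#' logarithmic: t_a.u.(u) = theta * log(u / u_min).
#'
#' @param u Strictly ascending inverse-allele-frequency grid.
#' @param theta Clock-like exposure at each grid point (summed over the
#'   configured clock set); nonnegative.
#' @return Object of class `time_course`: data frame `u`, `t_au`;
#'   attribute `no_clock_signal` is TRUE when theta is all zero.
#' @export
time_arbitrary <- function(u, theta) {
  stopifnot(length(u) == length(theta), length(u) >= 2)
  if (is.unsorted(u, strictly = TRUE)) stop("u must be strictly ascending")
  if (any(theta < 0)) stop("theta must be nonnegative")
  t_au <- pracma::cumtrapz(u, theta / u)[, 1]
  out <- data.frame(u = u, t_au = t_au)
  class(out) <- c("time_course", "data.frame")
  attr(out, "no_clock_signal") <- all(theta == 0)
  if (all(theta == 0)) warning("no clock signal: all exposures are zero")
  out
}

#' Time course from a per-bin exposure series
#'
#' Sums the exposures of the clock-like signature set per bin and
#' integrates them over the bin-centre grid.
#'
#' @param exposures Data frame from [exposure_series()] or
#'   [bootstrap_exposures()].
#' @param clock Character vector of clock-like signature names
#'   (`c("SBS1", "SBS5")` for clonal organisms, `"SBS1"` for tumors).
#' @param u_eval Optional evaluation grid: typically the sorted u = 1/f
#'   values of the mutations themselves, so that the time course has one
#'   point per observed 1/f value. The per-bin clock exposure is treated
#'   as a piecewise-constant density on u (exposure divided by bin width)
#'   and looked up at each evaluation point; `NULL` integrates on the
#'   bin-centre grid.
#' @return A `time_course`.
#' @export
clock_time_course <- function(exposures, clock = c("SBS1", "SBS5"),
                              u_eval = NULL) {
  sub <- exposures[exposures$signature %in% clock, , drop = FALSE]
  if (nrow(sub) == 0) stop("no exposures for the clock set")
  agg <- rowsum(sub$exposure, sub$bin_center)
  u <- as.numeric(rownames(agg))
  o <- order(u)
  u <- u[o]
  theta <- agg[o, 1]
  if (is.null(u_eval)) return(time_arbitrary(u, theta))
  u_eval <- sort(unique(u_eval))
  width <- if (length(u) > 1) min(diff(u)) else 1
  # exact integral of the piecewise-constant density theta/width over
  # 1/u: robust on evaluation grids much sparser than the bins
  lo <- pmax(u - width / 2, .Machine$double.xmin)
  hi <- u + width / 2
  dens <- theta / width
  full <- dens * log(hi / lo)            # full-bin contributions
  cum <- c(0, cumsum(full))              # integral up to each bin start
  j <- findInterval(u_eval, lo)          # bin containing (or left of) u
  t_raw <- ifelse(j == 0, 0,
                  cum[pmax(j, 1)] +
                    dens[pmax(j, 1)] * log(pmin(u_eval, hi[pmax(j, 1)]) /
                                             lo[pmax(j, 1)]))
  t_au <- t_raw - t_raw[1]
  out <- data.frame(u = u_eval, t_au = t_au)
  class(out) <- c("time_course", "data.frame")
  attr(out, "no_clock_signal") <- all(theta == 0)
  out
}

#' Calibrate an arbitrary-unit time course to a known duration
#'
#' @param tc A `time_course`.
#' @param T_total Known real duration (e.g. time to recurrence, months).
#' @return The time course with a `t_real` column; max(t_real) = T_total.
#' @export
calibrate_recurrence <- function(tc, T_total) {
  stopifnot(inherits(tc, "time_course"), T_total > 0)
  mx <- max(tc$t_au)
  if (mx <= 0) stop("max(t_au) is zero: cannot calibrate")
  tc$t_real <- tc$t_au * T_total / mx
  tc
}

#' Mutation flux and mean 1/f in a boundary window
#'
#' The boundary windows are the first 5% of time points (start of
#' recurrence) or the last 5% (end of primary). dM is the mutation count
#' whose u falls in the window's u range, dt the time spanned.
#'
#' @param tc A `time_course` (calibrated or not).
#' @param u_variants u = 1/f values of the mutations of the same sample.
#' @param side `"primary-end"` or `"recurrence-start"`.
#' @param window_frac Window fraction of the time points (default 0.05).
#' @param time Which time column to use: `"t_real"` when available, else
#'   `"t_au"`.
#' @return List: `dMdt`, `u_mean` (window mean of the mutation u values,
#'   falling back to the grid mean if no mutation lies inside), `dM`,
#'   `dt`, `u_range`.
#' @export
boundary_flux <- function(tc, u_variants,
                          side = c("primary-end", "recurrence-start"),
                          window_frac = 0.05, time = NULL) {
  side <- match.arg(side)
  tcol <- time %||% if (!is.null(tc$t_real)) "t_real" else "t_au"
  n <- nrow(tc)
  nw <- max(2L, ceiling(window_frac * n))
  idx <- if (side == "recurrence-start") seq_len(nw) else seq(n - nw + 1L, n)
  u_lo <- min(tc$u[idx]); u_hi <- max(tc$u[idx])
  dt <- tc[[tcol]][max(idx)] - tc[[tcol]][min(idx)]
  if (dt <= 0) stop("boundary window spans zero time")
  inw <- u_variants >= u_lo & u_variants <= u_hi
  dM <- sum(inw)
  # window mean of 1/f taken as the reciprocal of the window-mean allele
  # frequency (harmonic mean of u): consistent with the dt ~ du/u
  # quadrature of the time course, so the survival-ratio identity is
  # exact for a uniform-flux window
  u_mean <- if (dM > 0) 1 / mean(1 / u_variants[inw]) else
    1 / mean(1 / tc$u[idx])
  list(dMdt = dM / dt, u_mean = u_mean, dM = dM, dt = dt,
       u_range = c(u_lo, u_hi))
}

#' Propagate real time from the recurrence into the primary tumor
#'
#' The real-time span of the primary's terminal boundary window is
#'     dt_P = dM_P / ( (u_P / u_R) * gamma_PR * (dM/dt)_R ),
#' with gamma_PR = gamma_P / gamma_R the assumed survival ratio at
#' resection (default 1/300). The primary's arbitrary-unit timeline is
#' rescaled so its terminal window spans dt_P.
#'
#' @param tc_primary Primary `time_course`.
#' @param u_variants_primary u values of the primary's mutations.
#' @param dMdt_R Recurrence-start mutation flux (real-time units).
#' @param uR Recurrence-start window mean of u.
#' @param gamma_PR Assumed gamma_P / gamma_R (> 0).
#' @param window_frac Boundary window fraction.
#' @return List: `tc` (primary time course with `t_real`), `dt_P`,
#'   `dM_P`, `uP`, `scale` (real units per arbitrary unit).
#' @export
propagate_primary <- function(tc_primary, u_variants_primary, dMdt_R, uR,
                              gamma_PR = 1 / 300, window_frac = 0.05) {
  stopifnot(dMdt_R > 0 || !is.na(dMdt_R), gamma_PR > 0, uR > 0)
  if (dMdt_R == 0) stop("recurrence flux zero")
  bf <- boundary_flux(tc_primary, u_variants_primary, "primary-end",
                      window_frac, time = "t_au")
  dt_P <- bf$dM / ((bf$u_mean / uR) * gamma_PR * dMdt_R)
  scale <- dt_P / bf$dt
  tc_primary$t_real <- tc_primary$t_au * scale
  list(tc = tc_primary, dt_P = dt_P, dM_P = bf$dM, uP = bf$u_mean,
       scale = scale)
}

#' Tumor-cell survival ratio at resection
#'
#' gamma_R / gamma_P = (u_P / u_R) * (dM/dt)_R / (dM/dt)_P, with boundary
#' fluxes in the same real-time units.
#'
#' @param dMdt_R,dMdt_P Boundary mutation fluxes (> 0).
#' @param uR,uP Boundary window means of u (> 0).
#' @return The ratio (scalar).
#' @export
survival_ratio <- function(dMdt_R, uR, uP, dMdt_P) {
  if (any(c(dMdt_R, dMdt_P, uR, uP) <= 0)) {
    stop("survival_ratio requires positive fluxes and u means")
  }
  (uP / uR) * dMdt_R / dMdt_P
}

#' Survival-ratio estimates for a primary/recurrent pair
#'
#' Runs the full boundary-window recipe: the recurrence time course is
#' calibrated to the known time to recurrence, its start-window flux and
#' mean u are measured, the primary timeline is scaled so its total
#' duration equals each assumed primary duration in turn, and
#' [survival_ratio()] is evaluated per assumption. The defaults (24 and
#' 84 months) correspond to tumor emergence 2 or 7 years before primary
#' resection; the shorter duration yields the lower ratio estimate.
#'
#' @param tc_primary,tc_recurrent `time_course` objects.
#' @param u_primary,u_recurrent Mutation u values per sample.
#' @param T_recurrence Time to recurrence in months.
#' @param assumed_primary_months Assumed primary durations (months).
#' @param window_frac Boundary window fraction.
#' @return Object of class `survival_ratio_result`: data frame `estimates`
#'   (duration, ratio) plus boundary diagnostics.
#' @export
survival_ratio_pair <- function(tc_primary, tc_recurrent, u_primary,
                                u_recurrent, T_recurrence,
                                assumed_primary_months = c(24, 84),
                                window_frac = 0.05) {
  tc_r <- calibrate_recurrence(tc_recurrent, T_recurrence)
  bf_r <- boundary_flux(tc_r, u_recurrent, "recurrence-start", window_frac)
  ratios <- vapply(assumed_primary_months, function(D) {
    tc_p <- tc_primary
    tc_p$t_real <- tc_p$t_au * D / max(tc_p$t_au)
    bf_p <- boundary_flux(tc_p, u_primary, "primary-end", window_frac)
    survival_ratio(bf_r$dMdt, bf_r$u_mean, bf_p$u_mean, bf_p$dMdt)
  }, numeric(1))
  structure(list(
    estimates = data.frame(assumed_primary_months = assumed_primary_months,
                           gamma_ratio = ratios),
    dMdt_R = bf_r$dMdt, uR = bf_r$u_mean,
    T_recurrence = T_recurrence, window_frac = window_frac
  ), class = "survival_ratio_result")
}

#' Expansion profile omega * gamma * N as a function of time
#'
#' From d(1/f) proportional to omega * gamma * N * dt, the expansion flux
#' is the derivative du/dt (central finite differences), known up to the
#' constant pi / K of the underlying model. Optional 3-point running
#' median smoothing.
#'
#' @param tc A `time_course`; time must be strictly increasing over at
#'   least 3 points.
#' @param time Time column (`"t_real"` if present else `"t_au"`).
#' @param smooth Apply 3-point median smoothing.
#' @return Object of class `expansion_profile`: data frame `t`, `wgn`
#'   (omega*gamma*N, arbitrary scale).
#' @export
expansion_profile <- function(tc, time = NULL, smooth = TRUE) {
  tcol <- time %||% if (!is.null(tc$t_real)) "t_real" else "t_au"
  t <- tc[[tcol]]
  u <- tc$u
  if (any(diff(t) < 0)) stop("nonmonotone time")
  keep <- c(TRUE, diff(t) > 0) # drop exact ties (zero-flux plateaus)
  t <- t[keep]; u <- u[keep]
  if (length(t) < 3) stop("need at least 3 strictly increasing time points")
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  n <- length(t)
  wgn <- numeric(n)
  wgn[1] <- (u[2] - u[1]) / (t[2] - t[1])
  wgn[n] <- (u[n] - u[n - 1]) / (t[n] - t[n - 1])
  wgn[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  if (smooth && n >= 3) wgn <- runmed(wgn, 3)
  out <- data.frame(t = t, wgn = wgn)
  class(out) <- c("expansion_profile", "data.frame")
  attr(out, "scale_note") <- "known up to the constant pi/K"
  out
}

#' Regress time to recurrence on the survival ratio
#'
#' fit1: OLS of time on log10(ratio); fit2: OLS of time on
#' log10(log10(ratio)) (points with ratio <= 1 are excluded from fit2
#' with a warning). Slope p-values are Bonferroni-adjusted for the two
#' fits.
#'
#' @param ratios gamma_R / gamma_P estimates (> 0).
#' @param times Times to recurrence (same length, >= 3 pairs).
#' @return List with `fit1`, `fit2` (each: intercept, slope, se, p_adj,
#'   n) and the underlying `lm` objects.
#' @export
recurrence_time_regression <- function(ratios, times) {
  stopifnot(length(ratios) == length(times))
  if (length(ratios) < 3) stop("need at least 3 ratio/time pairs")
  if (any(ratios <= 0)) stop("ratios must be positive")
  summarize <- function(fit, n) {
    sm <- summary(fit)$coefficients
    p_raw <- if (nrow(sm) > 1 && !is.nan(sm[2, 4])) sm[2, 4] else NA_real_
    list(intercept = sm[1, 1], slope = sm[2, 1],
         se_intercept = sm[1, 2], se_slope = sm[2, 2],
         p_adj = min(1, 2 * p_raw), n = n)
  }
  f1 <- lm(times ~ log10(ratios))
  res1 <- summarize(f1, length(ratios))
  ok2 <- ratios > 1
  if (any(!ok2)) warning(sum(!ok2), " point(s) with ratio <= 1 excluded ",
                         "from the double-log fit")
  if (sum(ok2) < 3) {
    res2 <- NULL; f2 <- NULL
  } else {
    f2 <- lm(times[ok2] ~ log10(log10(ratios[ok2])))
    res2 <- summarize(f2, sum(ok2))
  }
  list(fit1 = res1, fit2 = res2, lm1 = f1, lm2 = f2)
}
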