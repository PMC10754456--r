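# Canonical simulation experiments with known ground truth, shared by the
# test suite and the acceptance script.

#' One replicate of the survival-ratio recovery experiment
#'
#' Simulates a primary tumor under a constant low survival rate and its
#' post-resection recurrence under `gamma_ratio` times that survival,
#' then runs the full estimation pipeline (sequencing noise, filters,
#' binned clock exposures, time courses on the observed 1/f grid,
#' boundary fluxes) feeding the true durations, and returns the estimated
#' gamma_R / gamma_P.
#'
#' Study conditions: budding division mode with a small per-generation
#' division probability (omega = 0.05) so that the discrete generations
#' approximate the continuous model; mu = 20 mutations/genome/division;
#' diploid; 100 founder cells; 200 primary and 80 recurrent generations;
#' resection keeps half the cells; mean depth 10^4 with the standard
#' QUAL >= 30 / depth >= 10 / alt >= 3 filters; recurrence restricted to
#' de novo mutations (the inherited-mutation bias mode is exercised
#' separately).
#'
#' @param seed Integer seed for this replicate.
#' @param gamma_ratio True survival ratio gamma_R / gamma_P.
#' @param de_novo_only Restrict the recurrence to de novo mutations
#'   (default TRUE; FALSE reproduces the inherited-mutation bias).
#' @return Estimated gamma ratio (NA if the simulated pair went extinct).
#' @export
survival_ratio_recovery <- function(seed, gamma_ratio = 30,
                                    de_novo_only = TRUE) {
  cfg <- sim_config(
    mu = 20, ploidy_pi = 2, omega = 0.05, gamma = 0.03, n0 = 100,
    n_generations = 200, offspring_model = "budding", seed = seed,
    coding_fraction = 0, depth = 1e4
  )
  pair <- simulate_primary_recurrent(cfg, gamma_ratio = gamma_ratio,
                                     resection_fraction = 0.5,
                                     n_generations_recurrent = 80)
  if (pair$status != "ok") return(NA_real_)
  clock <- c("SBS1", "SBS5")
  cat2 <- cfg$catalog[, clock]
  prep <- function(v) {
    apply_filters(attach_sequencing_noise(v, cfg$depth, cfg$ploidy_pi,
                                          seed = seed + 1000L),
                  filter_spec())
  }
  prim <- prep(pair$primary$variants)
  rec <- prep(pair$recurrent$variants)
  if (de_novo_only) rec <- rec[rec$de_novo, , drop = FALSE]
  if (nrow(prim) < 50 || nrow(rec) < 50) return(NA_real_)
  u_p <- 1 / prim$freq
  u_r <- 1 / rec$freq
  tc_p <- clock_time_course(exposure_series(bin_spectra(prim, 0.5), cat2),
                            clock, u_eval = u_p)
  tc_r <- clock_time_course(exposure_series(bin_spectra(rec, 0.5), cat2),
                            clock, u_eval = u_r)
  sr <- survival_ratio_pair(tc_p, tc_r, u_p, u_r,
                            T_recurrence = 80,
                            assumed_primary_months = 200)
  sr$estimates$gamma_ratio[1]
}

#' Neutral-growth M(1/f) slope versus the frequency-class oracle
#'
#' Simulates a neutral fission expansion, builds the accumulation curve
#' through the package path (variant table -> M(1/f)), and compares its
#' mid-range slope with the slope computed directly from the truth
#' ledger's carrier counts (exact mutation counts per frequency class).
#'
#' @param seed Integer seed.
#' @param mu Mutations per genome per division.
#' @return List: `slope_curve`, `slope_oracle`, `ratio`, `n_variants`.
#' @export
neutral_slope_experiment <- function(seed, mu = 0.3) {
  cfg <- sim_config(mu = mu, ploidy_pi = 2, omega = 1, gamma = 0.95,
                    n0 = 20, n_generations = 11, seed = seed,
                    coding_fraction = 0)
  sim <- simulate_clonal_expansion(cfg)
  if (sim$status != "ok" || nrow(sim$variants) < 1000) return(NULL)
  curve <- build_maf_curve(sim$variants)
  # mid-frequency range: u between the 10% and 60% quantiles
  qs <- quantile(curve$u, c(0.1, 0.6))
  mid <- curve$u >= qs[1] & curve$u <= qs[2]
  slope_curve <- unname(coef(lm(curve$m[mid] ~ curve$u[mid]))[2])
  # oracle: exact per-frequency-class counts from the truth ledger
  n_final <- tail(sim$truth$N, 1)
  carr <- sim$truth$events$carriers
  u_oracle <- cfg$ploidy_pi * n_final / carr
  u_grid <- sort(unique(u_oracle))
  m_oracle <- vapply(u_grid, function(uu) sum(u_oracle <= uu), numeric(1))
  midg <- u_grid >= qs[1] & u_grid <= qs[2]
  slope_oracle <- unname(coef(lm(m_oracle[midg] ~ u_grid[midg]))[2])
  list(slope_curve = slope_curve, slope_oracle = slope_oracle,
       ratio = slope_curve / slope_oracle, n_variants = curve$n)
}
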