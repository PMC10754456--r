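# clonechron

Time-resolved analysis of clonally evolving genomes from the allele
frequencies of their somatic mutations.

`clonechron` is aimed at researchers studying clonal expansions — tumors
(e.g. paired primary/recurrent glioblastoma genomes) or clonally
reproducing organisms (e.g. the apomictic marbled crayfish) — who have a
table of somatic single-base substitutions with allele frequencies and
want to reconstruct *when* things happened: phases of changing mutation
rate, the time course of the expansion, the survival ratio of tumor cells
across a resection, and the shape of the expansion itself.

## The model in brief

For a mutation observed at allele frequency *f*, write *u* = 1/*f*. Under
exponential growth with per-division mutation rate μ, ploidy π, division
rate ω and cell survival probability γ, the number of cells *N* is
proportional to 1/*f*, and the cumulative mutation count is linear in the
inverse frequency:

    dM ∝ μ · d(1/f)

so the curve **M(1/f)** — mutations counted cumulatively over ascending
*u* — has slope proportional to the per-division mutation rate, and
changes of slope mark phases of changing evolutionary parameters.
`clonechron` detects them by continuous piecewise-linear (segmented)
regression with Davies' significance test and 10-fold cross-validation,
then restricts downstream analysis to the range between the first and
last breakpoints (clonal mutations below, detection-limited mutations
above).

Within that range the package computes:

* **dN/dS(u)** — windowed nonsynonymous/synonymous counts normalized by
  the codon-opportunity baseline of a coding-sequence set (≈1 under
  neutrality);
* **signature exposures θ(u)** — non-negative least-squares decomposition
  of the 96-channel trinucleotide spectrum per *u*-bin on a COSMIC-style
  catalog, with bootstrap confidence intervals;
* **time in arbitrary units** from the clock-like exposures (SBS1, SBS5),

      t_a.u.(u) = ∫ θ_clock · f · d(1/f),

  the factor *f* normalizing the exposure by population size (N ∝ 1/f);
* **calibration and propagation**: the recurrence timeline is rescaled to
  the known time to recurrence T (t = t_a.u. · T / max T_a.u.); the
  primary timeline is propagated backwards through the resection using
  the boundary mutation fluxes
  (dt_P = dM_P / [(u_P/u_R) · (γ_P/γ_R) · (dM/dt)_R], default
  γ_P/γ_R = 1/300);
* **the tumor-cell survival ratio** at resection,

      γ_R/γ_P = (u_P/u_R) · (dM/dt)_R / (dM/dt)_P,

  reported for assumed primary durations of 2 and 7 years;
* **expansion profiles** ωγN(t) = d(1/f)/dt (up to a model constant) and
  their classification into Convex / Peak / Increase / Paused Start
  shapes by k-means with Calinski–Harabasz model selection;
* **trio mutation rates** (mutations/nt/year) from parent–offspring
  counts with a three-component uncertainty model (genotyping,
  birth-date, biological), combined as a quadratic sum.

A Galton–Watson style simulator (`simulate_clonal_expansion`,
`simulate_primary_recurrent`) generates synthetic expansions with a full
ground-truth ledger — true allele frequencies, origin generations,
signature mixtures, a known γ_R/γ_P — so that every stage of the
pipeline can be validated against a recoverable target.

## Worked example

```r
library(clonechron)

cfg <- sim_config(mu = 2, n0 = 10, n_generations = 8, gamma = 0.9,
                  depth = 1000, seed = 4,
                  signature_weights = c(SBS1 = 0.6, SBS5 = 0.4))
sim <- simulate_clonal_expansion(cfg)
obs <- attach_sequencing_noise(sim$variants, depth = 1000, seed = 4)
flt <- apply_filters(obs, filter_spec())      # QUAL>=30, depth>=10, alt>=3

curve <- build_maf_curve(flt)
#> M(1/f) curve: 787 mutations, u in [ 17.65 , 364.7 ]
fit <- fit_segmented(curve, target_adj_r2 = 0.995)
#> Segmented fit: 2 breakpoint(s) at 289.83, 315.93
#>   adjusted R^2 = 0.995429
davies_test(curve)
#> [1] 0  (a slope change is overwhelmingly supported)

bins <- bin_spectra(flt, halfwidth = 0.5)
expo <- exposure_series(bins, cfg$catalog[, c("SBS1", "SBS5")])
tc   <- clock_time_course(expo, clock = c("SBS1", "SBS5"))
max(tc$t_au)
#> [1] 6.123   # total elapsed time, arbitrary units
prof <- expansion_profile(calibrate_recurrence(tc, 18))  # 18-month course
range(prof$wgn)
#> [1]    2.78 1310   # omega*gamma*N, up to a constant
```

The 4,344 simulated mutations collapse to 787 after sequencing noise and
the standard filters — the rest sit below the detection limit, which is
exactly why the accumulation curve is trimmed at its outer breakpoints.
The fitted exposures split the filtered mutations roughly 60/40 between
the two clock-like signatures, matching the configured mixture.

For a paired design, `simulate_primary_recurrent()` plus
`survival_ratio_pair()` run the whole chronometry;
`survival_ratio_recovery()` packages the canonical validation experiment
(true γ_R/γ_P = 30).

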