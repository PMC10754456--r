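---
title: "Chronometry of clonal expansions from allele-frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronometry of clonal expansions from allele-frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonechron)
```

## The model

A clonally expanding population of `N` cells with ploidy `pi` accrues
somatic single-base substitutions at `mu` mutations per genome per
division. A neutral mutation arising in one cell when the population has
size `N(t)` has expected final frequency `f = 1/(pi * N(t))` (the
expected descendant count of any cell equals the total growth factor
from `t` onward), so the inverse frequency `u = 1/f` of a mutation is a
proxy for the population size at its birth — and, through growth, for
its birth *time*. Three consequences organize the package:

1. **Accumulation.** Counting mutations cumulatively over ascending `u`
   yields `M(1/f)`, linear under constant evolutionary parameters with
   slope proportional to `mu` per division. Slope changes mark phases.
2. **Time.** The exposure `theta(u)` of clock-like mutational signatures
   (SBS1, SBS5 — processes whose burden grows with elapsed time rather
   than with divisions) integrates to a time course in arbitrary units,
   `t_a.u.(u) = integral theta * f d(1/f)`; multiplying by `f` divides
   out the population size, which is proportional to `1/f` up to an
   unknown constant. One known real duration (time to recurrence, or an
   assumed primary duration) fixes the scale.
3. **Expansion.** Since `d(1/f) ~ omega * gamma * N * dt`, the
   derivative of `u` against reconstructed time traces the effective
   expansion flux `omega * gamma * N`, up to the constant `pi/K` of the
   model — enough to compare *shapes* across samples and to form
   survival-rate *ratios* in which the constants cancel.

### Assumptions worth keeping in view

* Neutrality within the analyzed frequency range: selection is not
  observable in `M(1/f)` under this model; the windowed dN/dS statistic
  is the package's check that the assumption is tenable.
* Constant ploidy; one mutated copy per event (single-strand origin);
  infinite sites (each mutation hits a fresh coordinate).
* The arrow of time is the arrow of increasing `1/f`.
* Clock-like signature exposures are proportional to elapsed time per
  cell. Human signature profiles stand in for taxa where none have been
  derived, on the grounds that the underlying chemistry (CpG
  deamination for SBS1) is conserved.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| variant filters | QUAL ≥ 30, depth ≥ 10, alt ≥ 3 | phred, reads | standard accumulation-curve filter; a strict profile (QUAL ≥ 35, 50 ≤ depth ≤ 200) suits rate lower bounds — depths ≥ 200 show a distorted SNP distribution (repeats) |
| curve CI bins | half-width 0.25 on `u` | — | bootstrap bands on per-bin counts, 2.5/97.5 percentiles |
| segmentation target | adjusted R² 0.995 (0.9995 for very dense tumor curves) | — | smallest breakpoint count reaching the target, at most 20 |
| adjusted R² denominator | n − 2(k+1) | — | k breakpoints + k+1 slopes + 1 intercept, continuity constrained |
| signature bins | half-width 0.5 on `u`, tiling | — | tiling (not sliding) assumed; each mutation in exactly one bin |
| bootstrap | B = 1000 (tests scale to 100–300) | replicates | sets > 100,000 mutations subsampled to 50,000 and rescaled |
| clock set | SBS1+SBS5 (clonal organisms), SBS1 (tumors) | — | configurable in every chronology function |
| dN/dS window | half-width 1.0 on `u`, ≥ 20 mutations | — | smoothed by running median (5) then moving average (3) |
| boundary windows | first/last 5% of time points | — | time points = the observed `1/f` values; windows over time points, not over time span |
| `gamma_P/gamma_R` | 1/300 | — | assumed survival drop at the end of the primary, used only for time propagation; the survival-ratio estimator inverts the logic and needs no such assumption |
| assumed primary durations | 24 and 84 months | months | produce the lower and upper survival-ratio estimates |
| k-means | k ∈ 2..6, 5 restarts | — | Euclidean distance on 1000-point standardized curves |
| trio-rate denominator | genome nt (lower bound) or callable sites (upper bound) | nt | birth-date SD = window/3; total SD = quadratic sum of three components |

## The simulator

`simulate_clonal_expansion()` runs discrete non-overlapping generations.
Each cell divides with probability `min(1, omega)`; every surviving
daughter acquires `Poisson(mu)` mutations on one of `pi` copies, each
with a trinucleotide channel drawn from the configured signature mixture
and a synonymous/nonsynonymous label (nonsynonymous events are thinned
by the selection factor `s` at origination — selection affects counts,
not demography, which suffices for direction tests). Two division modes
are provided:

* **fission** (default): a division replaces the parent by two
  daughters, each surviving with probability `gamma`. Growth per
  generation is `1 − p + 2·p·gamma`; `gamma = 0` drives extinction,
  reported as an explicit `"extinct"` status.
* **budding**: the parent persists and each division adds one daughter
  surviving with probability `gamma` (growth `1 + p·gamma`). This mode
  represents survival-limited expansions — a treated tumor can have
  very small `gamma` yet still grow — which fission cannot reach
  (fission requires `gamma > 1/2` for growth, so a survival ratio of 30
  between two viable tumors is unrepresentable in it).

Discreteness matters quantitatively: the per-generation clock flux is
`gamma/(1 + p·gamma)` rather than `gamma`, so large per-generation
growth suppresses the clock in fast phases. The recovery experiments
therefore use `omega = 0.05` per generation, making the dynamics
near-continuous (suppression < 5%). `simulate_primary_recurrent()`
grows a primary, subsamples cells at resection, and regrows under
`gamma_R = gamma_ratio * gamma_P`, flagging de novo recurrence
mutations in the truth ledger.

What the simulator does **not** emulate: copy-number change, ploidy
evolution, indels, mutation hotspots and recurrent sites, mapping and
calling artifacts beyond Poisson/binomial read sampling, and
contamination by normal tissue. Passing tests therefore demonstrate the
*estimators'* correctness under the generative model, not robustness to
every artifact of real sequencing data.

## Numerical choices

* **Time integration.** On a bin-centre grid the integral of
  `theta/u` uses the cumulative trapezoid. When a time course is
  evaluated on the observed mutation `u` values (`clock_time_course`'s
  `u_eval`), the per-bin exposure is treated as a piecewise-constant
  density and integrated in closed form (`theta_b * log` of the covered
  bin fraction): a trapezoid on an evaluation grid sparser than the
  bins systematically over-integrates the high-`u` tail.
* **Boundary `1/f` means.** The window "mean of 1/f" is the reciprocal
  of the window-mean allele frequency (the harmonic mean of `u`). Under
  the `dt ~ du/u` quadrature this makes the survival-ratio identity
  exact for a uniform-flux window; the arithmetic mean leaves a bias of
  order the squared coefficient of variation of `u` in the window.
* **Segmented fitting.** Muggeo-style iterative linearization with
  deterministic quantile-grid restarts (plus warm starts from the
  (k−1)-breakpoint solution, which guarantees the nested-model error
  ordering). A fit only counts if every segment holds at least
  `max(3, 0.2% of n)` points: a "k-breakpoint" model whose breakpoints
  collapse onto each other or the data boundary is not an identifiable
  k-breakpoint model.
* **CV model choice.** The CV table reports held-out (test) and
  training (validation) MSE and their difference; a non-increasing
  difference when adding a phase argues against overfitting. For
  selecting the phase count, `cv_select_k` applies the one-standard-error
  rule: past the true count, nested candidates are near-tied (held-out
  differences of order `2*sigma^2*p/n`, far below fold noise), so a raw
  argmin flips essentially at random between them, while the 1-SE rule
  is stable. Candidates unsupported in half the folds are reported NA.
* **Davies' test.** Hinge-term t statistics over a 10-point quantile
  grid; `p = 2(Phi(−M) + V·exp(−M²/2)/sqrt(8π))` with `M` the maximum
  absolute statistic and `V` the total variation over the grid. Null
  simulations put the empirical size at 4–5% at the 5% level.
* **NNLS.** Lawson–Hanson via `pracma::lsqnonneg`, fitted on counts so
  exposures carry mutation units (the time integral treats them as a
  flux). KKT conditions are asserted in tests. All-zero spectra return
  zero exposures, flagged.
* **Ties and degenerate inputs.** Identical frequencies share one `u`
  grid point with `M` jumping by the tie count; bin edges are
  left-closed (an edge value goes right); constant curves yield
  `p = 1` in Davies' test and an error in the segmenter; windows
  without synonymous mutations are masked (NA), never infinite;
  zero-flux time plateaus are dropped (ties), but time reversals are
  errors.

## Design choices at genuinely open points

* The eligibility rule for trio rates ("alternate allele private to one
  line") is applied per site, with the per-allele variant left to the
  caller.
* Cross-validation operates on `M` (the curve), not its derivative.
* Stop codons contribute no mutational opportunities: mutations out of
  a stop are outside the somatic SNV universe considered.
* Splice effects are out of the toy annotator's scope; precomputed
  effect labels override it, so splice-aware annotations can be carried
  through.
* The recurrence flux may optionally be restricted to de novo
  mutations; the default keeps all mutations, matching the propagation
  formula as published, and the inherited-mutation bias (it inflates
  the recurrence-start flux and hence the ratio) is demonstrated in the
  test suite with the simulator's truth flags.
* Per-curve (not pooled) standardization precedes curve clustering;
  cluster names are assigned by correlation with analytic templates
  (convex parabola, half-sine peak, line, hinge) rather than by eye.

## Problem sizes used by the validation suite

Neutral-law checks: 20 replicates of ~1–2 × 10⁴ mutations. Survival
ratio: 20 replicates of a 200-generation primary (100 founders) with an
80-generation recurrence at depth 10⁴. Segmentation: 100 replicates of
n = 2000, noise SD 5; CV on 25 of them. Davies size: 1000 null curves
of n = 100. Exposure coverage: 200 replicates of 10⁴ mutations with
B = 200. Classification: 50 seeds of 4 shapes × 10 noisy curves.
Trio rate: 200 Poisson replicates. These sizes make the full suite and
the acceptance script complete in a few minutes while keeping every
binomial proportion's Monte-Carlo error well below the asserted margins.

## Known limitations

* The chronometry inherits the model's identifiability limits: absolute
  time requires an external anchor (T or an assumed duration), and
  expansion profiles are known only up to `pi/K`.
* With shallow sequencing the observable `u` range is truncated at the
  detection limit; calibration then attributes the full known duration
  to the observable range. Deep data (or the simulator's high-depth
  mode) mitigates this.
* Breakpoint uncertainty is not propagated into the accepted range.
* dN/dS windows are not multiplicity-corrected; intervals, not adjusted
  tests, are reported.
* The survival-ratio estimator assumes `mu` and `omega` are equal
  across the resection and `gamma` constant within each tumor near the
  boundary; fluctuating growth near the boundary biases it in ways the
  budding-mode experiments quantify (median 24.8 recovered for a true
  ratio of 30 under the documented conditions).
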