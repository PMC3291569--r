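---
title: "Inferring the bacterial cell cycle from marker frequency and replication run-out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the bacterial cell cycle from marker frequency and replication run-out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicycle)
```

## The model and its assumptions

replicycle implements the Cooper–Helmstetter description of the
bacterial cell cycle at steady state. Its assumptions, all load-bearing:

1. **Steady-state exponential growth.** The population's age structure
   is time-invariant, with density `age_pdf(a) = 2 ln2 · 2^(-a)` over
   ages `a` in `[0, 1)` and CDF `age_cdf(a) = 2(1 - 2^(-a))`. Newborns
   outnumber dividers two-to-one because every division creates two
   cells.
2. **Fixed C and D periods.** Every replication round takes C minutes;
   division follows termination after D minutes. Cell-to-cell
   variability in C or D is not modeled.
3. **Synchronous initiation.** All origins in a cell fire together, so a
   replication run-out (initiation and division blocked, ongoing forks
   finish) leaves each cell with a power-of-two number of complete
   chromosomes equal to its origin count at drug addition.
4. **Symmetric division, exponential single-cell growth.** Size grows as
   `2^a` within the cycle; the growth law is not measured by the input
   data, and exponential is the choice consistent with balanced mass
   doubling.

From these follow the identities the inference inverts: the
marker-frequency ratio `ori/ter = 2^(C/tau)`, the mean origins per cell
`2^((C+D)/tau)`, the initiation age `a_i = ceiling(r) - r` with
`r = (C+D)/tau`, and the uninitiated fraction `F = age_cdf(a_i)`. The
per-age forward model (`state_at_age()`) enumerates the rounds active in
a cell: the round serving the division `k` generations ahead has
progress `f_k = ((C+D) - (1 - a + k) tau)/C` and replicates `2^k`
chromosome units, giving `genome_equivalents = 1 + sum_k 2^k clamp(f_k)`
— continuous in age and exactly doubling across division. Its population
mean has the closed form
`(tau/(C ln2)) (2^((C+D)/tau) - 2^(D/tau))`, which the test suite checks
against quadrature and Monte-Carlo sampling.

Ages are *circular*: when `(C+D)/tau` sits near an integer, initiation
wraps across division, and an initiation age of 0.93 in one analysis and
0.08 in another describe nearly the same physiology. All model-vs-data
age comparisons therefore use `age_distance()`, the distance on the unit
circle.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `tau` | min | 24 | fast growth in rich medium; matches the measured generation times (~24–26 min) of the strains the pipeline is built around |
| `c_period` | min | 43.8 | wild-type rich-medium C period recovered by marker frequency |
| `d_period` | min | 23.7 | wild-type D period from origins per cell |
| `fluorescence_cv` | — | 0.06 | per-class CV of run-out peaks typical of well-gated bacterial DNA histograms |
| `size_birth_mean` | µm² | 4.0 | birth cross-sectional area implied by a ~4.5 µm² size at initiation age ~0.19 |
| `size_birth_cv` | — | 0.15 | log-normal cell-to-cell size variation typical of balanced cultures |
| `cq_sd` | cycles | 0.05 | per-well Cq repeatability of a modern qPCR instrument |
| `dnaa_concentration` | molecules/µm² | 250 | ~1400 DnaA molecules in an average (5.5 µm²) cell, consistent with ~200 per origin at 7 origins |

Amplification efficiencies are user inputs in `(1, 2]` with default 2
(perfect doubling); standard-curve estimation is out of scope. The
absolute DnaA-per-cell baseline needed for `dnaa_per_ori()` is likewise
a required user input — it comes from independent literature
calibrations and is never hardcoded.

## The run-out mixture fit

`fit_ploidy_mixture()` models the histogram as a Gaussian mixture whose
component means are pinned to `n · u` for integer chromosome numbers
`n` (default `{2, 4, 8, 16}`) and one shared unit fluorescence `u`, with
one shared CV. Numerical choices:

- **Objective.** Least squares between the *bin-integrated* mixture
  density (`pnorm` differences divided by bin width) and the
  count-normalized histogram. Integrating over bins, rather than
  evaluating the density at bin centers, keeps the fitted mass of a
  component correct even when its width falls below one bin — the
  degenerate noiseless-spike case reduces to exact mass matching.
- **Variable projection.** At each candidate `(u, cv)` the class
  weights are solved by non-negative least squares
  (`pracma::lsqnonneg`); `(u, cv)` are then refined by Nelder–Mead on
  the log scale, started from the tallest smoothed histogram peak
  assigned to each allowed chromosome number in turn, with CV starts
  {0.03, 0.06, 0.12} and CV bounded to [5e-4, 0.6].
- **Pruning.** Classes below 1% of fitted mass are dropped and the rest
  renormalized before any downstream two-peak check, so shoulder
  artifacts never masquerade as a third peak.
- **Scale ambiguity and tie-break.** A histogram fixes peak positions
  only up to a common scale: peaks at `u` and `2u` fit identically as
  classes (2,4) or (4,8). Class *fractions* — and therefore the
  uninitiated fraction and initiation age — are invariant to this
  choice, but absolute origins per cell (hence D) are not. When no
  calibration is given, the first-found assignment is kept
  deterministically (candidates improve only on strictly better fits);
  when absolute ploidy matters, pass `unit_fluorescence` from an
  instrument calibration with standards of known genome content, which
  reduces the optimization to CV and weights.

The uninitiated fraction is taken from *fitted peak areas*, not raw
event counts: the fitted fractions are the maximum-use summary of
overlapping peaks, and the two conventions agree as peak overlap
vanishes. Profiles with more than two retained classes raise a
dedicated error rather than returning a meaningless F — a
three-peak profile means initiation straddles more than one doubling
class and a single uninitiated fraction does not exist.

## From fraction to age, size, and delay

`initiation_age_from_fraction()` inverts `F = age_cdf(a_i)`; this is the
unique steady-state inversion when every cell initiates exactly once per
cycle. `initiation_size()` maps `a_i` onto an empirical size sample by
rank order — under steady-state growth the size quantile at probability
`age_cdf(a_i)` estimates the size of cells at age `a_i` — using the
standard type-7 quantile with linear interpolation. This assumes sizes
increase monotonically with age within the sample (size ranks stand in
for age ranks); birth-size variability makes the mapping approximate,
which is visible in the worked example (4.46 µm² recovered vs 4.56
analytic).

`initiation_delay()` compares two strains in *absolute time from birth*,
`a_mut·tau_mut − a_wt·tau_wt`, rather than `delta_a · tau` of either
strain. With near-equal generation times the conventions agree to within
printed rounding; the absolute-time form is the physiologically
meaningful one when generation times differ.

## qPCR quantification

`pfaffl_ori_ter_ratio()` is the efficiency-corrected relative
quantification against a calibrator whose true ori:ter ratio is 1
(run-out-treated cells or spore DNA, both fully replicated):
`E_ori^dCq_ori / E_ter^dCq_ter` with `dCq = Cq_cal − Cq_sample`.
Replicates are averaged on the Cq scale before the ratio is formed — Cq
is the log-domain quantity, so averaging there weights wells equally in
fold-change. The tidy entry point `pfaffl_ratios()` takes one row per
well and returns one ratio per sample. At perfect efficiency the ratio
reduces exactly to `2^(dCq_ori − dCq_ter)`, and it is invariant to any
constant shift of all Cq values.

## What the generator emulates — and what it does not

`simulate_population()` draws ages by inverse CDF, birth sizes
log-normally, computes replication state from the forward model, and
assigns DnaA in proportion to size at fixed concentration (constant
initiator concentration across sizes is the regime the DnaA accounting
is designed to probe). `simulate_runout_histogram()` sets each cell's
run-out DNA equal to its origin count (complete run-out, no
re-initiation under the drugs) and applies multiplicative Gaussian
measurement noise, which is what makes the per-class CV constant — the
same structure the mixture fit assumes. `simulate_qpcr()` generates Cq
values consistent with the declared efficiencies, the true
marker-frequency ratio, and per-well Gaussian Cq noise, in a 3
biological × 3 technical layout. All generators take an explicit seed
and are bit-reproducible.

Not emulated: initiation asynchrony between sister origins, division
asymmetry and division-timing noise, cell-to-cell C-period variability,
debris/doublet events and detector nonlinearity in the cytometer, and
incomplete run-out kinetics. Passing tests on synthetic data therefore
demonstrate correctness of the inversion chain under the model's own
assumptions — they do not certify robustness to the gating and
asynchrony artifacts of real cytometry, which the caller must handle
upstream.

The blot simulator models the loading control as ideal (constant per
lane). A control protein whose per-cell amount scales with size would
cancel the very size effect a per-cell comparison measures; treating the
control as loading-fidelity only is what makes the per-cell readout
reproduce the expected ~0.70 level in 30%-smaller cells at equal
concentration.

## Degenerate inputs and edge handling

`c_period = 0` (instantaneous replication) is permitted for testing and
warns; ori:ter ratios below 1 and efficiencies outside `(1, 2]` are
measurement errors; a negative inferred D (mutually inconsistent ratio
and origin measurements) is *flagged*, never silently clipped, and
`infer_c_and_d()` carries a `status` column (`ok` / `degenerate` /
`negative_d`). Empty histograms, non-increasing bins, fewer than 8 bins,
and empty size samples all raise typed errors
(`replicycle_domain_error`, `replicycle_parse_error`, ...) that
`run_report()` propagates with the offending file named.

## Problem sizes

The test suite and examples use populations of 5,000–50,000 cells,
run-out histograms of 64–512 bins, 10^5-draw Monte-Carlo checks of the
closed-form DNA content, 1,000-replicate Pfaffl bias checks, and
full-chain parameter recovery at n = 20,000 cells across three seeds —
sizes at which the sampling error of every estimator is comfortably
below the assertion tolerances (e.g. the binomial error of an
uninitiated fraction at n = 20,000 is ~0.003 against a ±0.02 check).

## Known limitations

- Absolute ploidy (and therefore D) requires an external fluorescence
  calibration; the histogram alone cannot distinguish (2,4) from (4,8)
  classes.
- The uninitiated-fraction formalism applies only to two-peak profiles;
  growth conditions producing three run-out peaks yield origins per
  cell but no initiation age.
- The size-at-initiation mapping ignores birth-size/age correlation
  structure beyond rank order.
- All inference assumes steady state; shifts, stationary-phase entry,
  and stringent-response transients violate the age distribution the
  entire chain rests on.
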