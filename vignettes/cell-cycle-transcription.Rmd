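---
title: "Modeling cell-cycle-resolved transcription from smFISH counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell-cycle-resolved transcription from smFISH counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleFISH)
```

## The problem: time courses from fixed cells

Single-molecule RNA FISH counts individual mRNA molecules in fixed cells, so
it delivers exact copy-number distributions but no time axis. For processes
locked to the cell cycle there is a way out: an asynchronous, exponentially
growing culture contains cells at every point of the cycle, and morphological
markers (bud presence and size, spindle-pole-body number and orientation,
Whi5 localization, nuclear shape) assign each cell to one of seven phases —
early G1, late G1, S, G2, prometa-/metaphase, anaphase, and
telophase/cytokinesis. If each phase's duration is proportional to the
fraction of cells observed in it, phase labels become time windows on the
cycle and the per-phase count distributions become a discretized time course.
This *in silico synchronization* avoids the artifacts of chemical or
physical synchronization. `cycleFISH` implements the full computational side
of this approach for the budding-yeast G1/S regulators *SIC1*, *CLN2* and
*CLB5*, with a 129-min cycle as the reference parameterization.

## The transcription model

Each gene is an independent birth–death process
$$\varnothing \xrightarrow{k(t)} \mathrm{mRNA} \xrightarrow{p}
\varnothing,$$
where degradation is first order with rate constant $p$ (min$^{-1}$) and the
transcription rate $k(t)$ is piecewise constant over the cycle: $k_{high}$
inside one or two deterministic *high-expression windows*
$[t_{start}, t_{end})$, and a basal $k_{low} > 0$ outside them. Two points
distinguish this from the common two-state (telegraph) promoter model:
switching times are deterministic functions of cycle position, not random,
and the off state is replaced by low but non-zero transcription, because
measured distributions show expressing cells in every phase. The ratio
$100\,k_{low}/k_{high}$ is the *relative promoter activity*
(`promoter_activity()`); with the shipped constants it is about 7.8% for
*SIC1*, 0.5% for *CLN2* and 15% for *CLB5*.

Because the process is linear (monomolecular), the chemical master equation
with a Poisson initial condition has an exact solution: the copy number at
any time is Poisson distributed with mean $m(t)$ obeying
$$\frac{dm}{dt} = k(t) - p\,m(t),$$
solved in closed form segment by segment
(`mean_trajectory()`). The cycle-to-cycle map of $m$ is affine with
contraction factor $e^{-pT}$, so a unique cycle-periodic mean exists and is
computed analytically (`periodic_mean()`); all phase-resolved distributions
are evaluated at this periodic solution, which removes any dependence on an
arbitrary simulation start.

A phase is an interval of cycle time, and cells are assumed uniformly
distributed in time within it (consistent with duration ∝ occupancy). The
phase-resolved count distribution is therefore a uniform mixture of Poisson
laws, $\frac{1}{|I|}\int_I \mathrm{Pois}(m(t))\,dt$, computed by midpoint
quadrature at 0.1-min resolution (`phase_count_distribution()`). The mixture
is over-dispersed (variance ≥ mean), which is how deterministic rate
modulation masquerades as extra noise in pooled data. The exponential age
structure of a growing population (young cells slightly over-represented)
is deliberately not modeled; it would re-weight the within-phase mixture by
at most a factor $2^{-t/T}$ and is indistinguishable at realistic sample
sizes.

## Parameter estimation

For one gene, the data reduce to per-phase count histograms
(`phase_histograms()`); cells are exchangeable within a phase. The
log-likelihood sums `n(count) * log pmf(count)` over phases and count values,
with the pmf truncated at `n_max = 200` and the tail mass folded into the
last bin (this also guards `log 0`; plausible counts stay below ~40).

`fit_gene()` maximizes this likelihood with a multi-start cyclic coordinate
descent, each coordinate minimized by a golden-section line search
(`stats::optimize()`). Three numerical choices matter:

* **Coordinates.** Rates enter as $(\log(k_{high}/p), \log(k_{low}/p),
  \log p)$ — steady-state means plus the degradation rate — and each window
  as (center, width) on the circular cycle. In raw $(k, p)$ coordinates the
  likelihood has a long diagonal ridge (only $k/p$ is pinned by low-phase
  data) along which axis-parallel searches zig-zag; the mean
  parameterization removes it. After each sweep one extra line search runs
  along the sweep's aggregate displacement (a pattern move), which follows
  the remaining curved ridge between window position and $p$.
* **Starts.** The first start is moment-based (phase means set the levels,
  the highest-mean phase seeds the window); three more come from a coarse
  profile of the window coordinates at those levels; the remainder are
  Latin-hypercube draws within the bounds (rates in $[10^{-4}, 100]$
  min$^{-1}$, widths in $[1, 60]$ min; restart degradation rates are drawn
  in the physically plausible $[0.005, 2]$ min$^{-1}$). Twelve starts are
  the default; on all problems we tested, the best optimum is reached well
  before that many.
* **Convergence.** A start stops when the relative log-likelihood change
  per sweep falls below $10^{-8}$ or after 200 sweeps.

Model complexity — one versus two high-expression windows (5 versus 7 free
parameters) — is decided by the Akaike information criterion
(`aic()`, `select_model()`), with exact ties resolved toward fewer
parameters. When the fitted $k_{high}$ and $k_{low}$ agree within 1% the
window placement carries no information and the fit is flagged
non-identifiable. On synthetic data at the shipped constants (2000 cells),
the fitter recovers *SIC1*'s $k_{high}$ and $p$ to within a few percent and
window edges to within ~1 min, and AIC reliably picks the two-window model
for *CLN2*-like data; the acceptance script and test suite recompute these
numbers.

## Stochastic simulation

`simulate_cell()`/`simulate_population()` run the exact Gillespie algorithm
(SSA) for the time-varying schedule. Rates are piecewise constant, so the
simulation segments time at window boundaries; a tentative event beyond the
current segment is discarded and the clock re-drawn from the boundary, which
is exact by memorylessness of the exponential. Populations start at
anaphase of the previous cycle (cycle time 114 of 129, a 15-min offset
between simulation and cycle time) with initial counts drawn Poisson at the
basal mean $k_{low}/p$ — the natural pre-anaphase state, since all three
genes' windows have long ended or not begun by then. Snapshots are taken
every minute; per-cell RNG streams are derived from the master seed by a
counter scheme, so results do not depend on evaluation order. Population
noise is summarized as the coefficient of variation across cells per minute
(`population_noise_timecourse()`) and per cell across one cycle
(`per_cell_temporal_cv()`); `phase_binned_counts()` reverses in silico
synchronization by sampling one phase-uniform minute per simulated cell,
mimicking fixed-cell sampling.

## Osmotic stress

Hyperosmotic shock transiently represses *CLN2* and *CLB5* transcription
and delays cell-cycle progression; *SIC1* transcription is essentially
unaffected. The model reduces this to one parameter per cyclin: a
repression duration $t_d$ after stress onset during which the gene's rate
is forced to $k_{low}$ (not zero — basal expression persists under stress).
Scheduled high-window time is not consumed while repressed: the gene's
schedule clock freezes whenever it points into a window, so an interrupted
window resumes after $t_d$ with its remaining duration preserved and later
windows shift accordingly (`apply_stress_schedule()`). Cells are hit at a
uniformly random cycle position; sampling times follow the experimental
design (0/15/30/45/60/90 min after 0.4 M NaCl; `stress_config()`).

Phase labels at the sampling times must account for the stress-induced
cycle delay. Three rules are available in
`simulate_stress_population()`: a shared fixed delay of $\max t_d$ for
every cell (default), a per-cell delay equal to the cell's own largest
window deferral, and no delay. The fixed rule is the default because the
per-cell rule makes every gene's phase label depend on the most-deferred
gene, so the downstream distribution distance becomes discontinuous in
$t_d$ and the grid search unstable at 200 simulations per grid point; the
fixed rule preserves the essential phenomenology (delayed phases, peak
broadening) with a smooth distance surface.

$t_d$ is fitted by exhaustive grid search (`grid_search_td()`) over integer
minutes 5–30 per cyclin (676 combinations), 200 simulated cells per
combination, minimizing the total squared distance between simulated and
observed relative count frequencies per gene, phase and sampling time
(counts binned 0–30 plus a >30 tail; `distribution_distance()`). All
combinations share one master seed, so onsets and per-gene event randomness
are common random numbers across the grid: distance differences between
neighboring $t_d$ values then reflect the schedule change rather than
resampling noise, which is what makes an argmin at 200 simulations per
point reproducible. On synthetic data generated at $t_d = (28, 12)$ min
with 2000 observed cells, the search recovers both durations within the
grid resolution.

## Synthetic data

`generate_cell_table()` draws phases ∝ duration, a uniform age within the
phase, and counts either from the analytic periodic Poisson law (default)
or by running the SSA to the sampled age; the two paths sample the same law
and the suite checks them against each other. `generate_spot_table()`
inverts spot quantification for round-trip testing: every mRNA becomes a
single-molecule spot except that transcription-site (TS) carrying cells
concentrate `3 + Poisson(1)` molecules into one nuclear spot; intensities
are multiplied by lognormal noise with unit median (sdlog 0.25 by default),
so median normalization is exactly self-consistent and the zero-noise round
trip is the identity. TS emission is a synthetic convention: a cell shows a
TS with probability proportional to its instantaneous transcription rate
(peak 0.5), which makes TS fractions peak in the high-expression phases.
What passing these tests shows is that the pipeline's inference is
self-consistent under its own generative assumptions; real smFISH data add
segmentation errors, probe efficiency, optical crowding and age-structure
effects that the generator does not emulate.

## Spot quantification

`molecules_per_spot()` divides each spot intensity by the median intensity
of the gene's spot population and rounds half away from zero, flooring at
one molecule (upstream detection is assumed to have removed sub-threshold
noise; whether sub-median spots should instead be discarded is not
decidable from count data, and flooring keeps the round trip exact).
Molecule calls are invariant to any overall intensity scale and to
renormalization. A transcription site is a nuclear spot with at least three
molecules; cytoplasmic spots never qualify. `phase_summary()` reports per
phase and gene the mean, median, SEM, CV (sample standard deviation over
mean — small per-phase cell numbers make the $n-1$ denominator the right
choice), the fraction of expressing cells and the TS-positive fraction.

## Default phase map

The default seven-phase partition uses occupancy fractions 0.211 (eG1),
0.18 (lG1), 0.18 (S), 0.166 (G2), 0.147 (P/M), 0.086 (Ana), 0.03 (T/C).
Early G1, G2 and T/C are reported unstressed occupancy values; the
remaining fractions are package defaults chosen so anaphase plus
telophase/cytokinesis spans ~15 min, matching the simulator's
anaphase-to-cycle-start offset. Any partition can be supplied via
`build_phase_map()` (from observed counts) or `phase_map()` (from
durations).

## Problem sizes and limitations

The suite and the acceptance script use 2000-cell synthetic datasets for
estimation (matching the simulated-population size used throughout), five
replicate fits for the recovery medians, and 200 simulations per grid point
for the stress search; these sizes reproduce the shipped constants to well
within the documented tolerances. Known limitations: mother/daughter
asymmetry, cell-volume effects and division bookkeeping are not modeled;
genes are fitted independently (their molecules never interact in the
model); the stress module does not model Hog1 signaling mechanistically;
and window placements are only identifiable when $k_{high}$ exceeds
$k_{low}$ appreciably.

```{r example, eval = FALSE}
model <- g1s_model()
cells <- generate_cell_table(model, n_cells = 2000, seed = 1)
fit <- fit_gene(phase_histograms(cells, "SIC1"), model$phase_map,
                n_windows = 1, seed = 2)
fit
```
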