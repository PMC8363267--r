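---
title: "Modelling ERK activation pathways during L-LTP induction"
author: "erkltp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ERK activation pathways during L-LTP induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkltp)
```

## The scientific problem

Induction of late-phase long-term potentiation (L-LTP) in hippocampal CA1
spines requires activation of the extracellular signal-regulated kinase
(ERK). Several biochemical routes converge on ERK: calcium acting through
CaMKII (which controls the Ras/Rap GAP SynGap) and through the Ras GEF
RasGRF; cAMP acting directly through the Rap1 GEF Epac and indirectly
through PKA; and the Gi beta-gamma subunit, released when PKA-phosphorylated
beta-adrenergic receptors switch coupling from Gs to Gi, recruiting Src.
Which route dominates depends on the *temporal pattern* of synaptic input:
tetanic trains given massed (intertrain intervals of 3–40 s) or spaced
(80–300 s) engage the pathways differently.

`erkltp` implements this question as a reusable pipeline: a mass-action
reaction-network container with knockout and quantity-scaling transforms, a
stochastic simulator (exact Gillespie and adaptive tau-leaping) with a
deterministic ODE oracle, the stimulation protocols (single pulses, 100 Hz
trains, file-based input time series), and the statistical stage — AUC
summaries, linear/log/Hill dose–response selection, combination-versus-
summation ANCOVA, temporal-sensitivity summaries, and random-forest ranking
of parameter-perturbation robustness.

## Model structure and assumptions

The model is a single well-mixed compartment (default 4 µm³; spine-sized
0.1–0.8 µm³ volumes are selectable). All reactions are elementary mass
action with at most two reactant molecules; enzymatic steps are written
explicitly (binding, conversion) or as catalytic bimolecular steps.
Concentrations are nanomolar; the stochastic engines work on molecule
counts, with `concentration_to_count()` bridging the two
(1 nM in 4 µm³ ≈ 2.4 molecules, so a 4 µm³ compartment keeps copy-number
noise modest while a 0.1 µm³ spine head makes it prominent).

Three input species — `calcium`, `cAMP`, `Gibg` — carry all stimulation.
Upstream receptor and channel biology is deliberately outside the model
boundary: protocols state what the free input concentration does, not what
the synapse did to produce it.

### Stimulus realization

Published protocols state peak input concentrations (e.g. "1 µM calcium
pulses"), not injection fluxes. Each pulse is therefore a *clamp window*:
the free input species relaxes toward the stated target with a fast time
constant (τ = 10 ms) and is released to the network's own clearance
afterwards. This reproduces stated peaks independently of clearance
parameters. Within a 1 s, 100 Hz train the 10 ms pulses tile the second
contiguously, so the clamp is effectively maintained for the train — the
10 ms inter-pulse gaps are far below clearance timescales. A consequence,
tested in `test-protocols.R`, is that total injected exposure is linear in
pulse count and per-pulse amplitude.

File-based protocols (`load_timeseries_protocol()`) replay a
piecewise-constant `(time, species, value)` series the same way, which is
how the bath-ISO-style conditions are consumed.

### The fixture network

The full published parameter tables are distributed as supplementary model
files and are not bundled here; the package is exercised end to end on a
reduced *fixture* network (`build_fixture_network()`, 12 species, 14
reactions) engineered to reproduce the structural features that drive the
full model's behaviour:

* **Ultrasensitive kinase switch.** CaMKII is seeded by calcium,
  autophosphorylates (`pCaMKII + CaMKII -> 2 pCaMKII`), and is reset by a
  fixed PP1 pool. The fixture sits in the regime
  `k_auto · CaMKII_total > k_PP1 · PP1`, so the phosphorylated state
  self-sustains once triggered: a saturating calcium pulse drives the
  switch above half phosphorylation and it stays there long after the
  input ends, while the off state is absorbing without input.
* **Linear cAMP branch.** cAMP activates a GEF that drives ERK
  phosphorylation gradedly — the non-switch route.
* **Competition for a shared substrate.** The GEF branch and the
  Gibg–Src branch both draw on one finite ERK pool. Because the steady
  ppERK level is a saturating (strictly concave) function of the summed
  drive, co-stimulation always yields less than the sum of the single
  responses — the mechanism behind sublinear pathway combination.

Rate constants are documented constants of the fixture chosen once for
minute-scale dynamics at nanomolar concentrations; they are not fitted to
any published quantity, and fixture results are structural, not
quantitative, statements about the full model. Networks are tagged with a
`parameterization` attribute, and suites whose outputs only make sense
against published numbers (`run_validation_suite()`) refuse fixture
networks outright.

What the fixture deliberately does *not* emulate: Raf dimerization and its
bypass variant, SynGap phosphorylation/dispersion kinetics, the
PKA/phosphodiesterase feedback on cAMP, and realistic basal concentrations
(the fixture's unstimulated state is quiescent rather than a balanced
turnover steady state). Tests passing on the fixture therefore demonstrate
correctness of the machinery — conservation, solver agreement, statistics —
not biological predictions of the full model.

## Numerical methods

### Stochastic engines

`ssa_exact` is the Gillespie direct method with cached propensities
refreshed through a reaction dependency graph. `tau_leap_adaptive`
(the default, tolerance 0.1) selects leap lengths so the expected relative
propensity change per leap stays within the tolerance (bounding each
species' drift and diffusion per leap); reactions within ten firings of
exhausting a reactant are *critical* and fire one at a time through the
exact algorithm, and when the candidate leap is not worth its overhead the
engine takes a burst of exact steps instead. Leaps apply integer firing
counts through the stoichiometry, so conserved totals are exact in both
stochastic engines — asserted per trajectory in the suite. Leaps never
cross a clamp-window boundary or an output grid point.

Time-varying stimulation is handled by segmenting the timeline at clamp
edges; within a segment all rate constants are constant. Output is sampled
on a uniform grid (default 1 s), which bounds the state-recording error of
leaps and keeps AUC quadrature stable under refinement (tested to 0.5%).

Determinism contract: (network, protocol, config, seed) fully determines a
stochastic trajectory, bit for bit. All randomness flows through R's RNG.

### Deterministic oracle

The `ode` method integrates the same mass-action system in concentration
units with `deSolve::lsoda` (relative tolerance 1e-8), segment by segment.
It serves three roles: the large-volume limit against which the stochastic
engines are validated (at 1000 µm³ the 50-seed SSA mean matches the ODE
within 2% relative RMS on every species), a fast exact reference for
fixture fixed points, and the engine for strict-inequality checks
(sublinearity) where stochastic noise would blur the comparison.

### Steady states

`run_to_steady_state()` simulates at least 3600 s without stimulation and
requires the per-species mean over the final 600 s window to differ from
the preceding window by less than 1% relative, flooring the denominator at
one molecule so near-empty species do not dominate; it reports the worst
species on failure.

## Statistical stage

**AUC.** Kinase activity is total activity above the unstimulated level:
basal is the mean over a pre-stimulus window (≥ 300 s, or an explicitly
supplied steady-state value) and the AUC integrates the positive part of
the basal-subtracted signal by trapezoid from stimulation onset. The
window end defaults to the trajectory end; experiment drivers standardize
it per scan. Because the exact integration window is a convention, all
window-dependent quantities in this package are reported alongside their
window. `time_to_basal` needs a usable criterion when basal ≈ 0, so it is
defined as the first post-peak time at which the signal stays within 5% of
its peak excursion of basal for 60 s.

**Dose–response selection.** Linear `a + bx`, logarithmic
`a + b·log10(x)`, and Hill `ymax·xⁿ/(xⁿ + hⁿ)` least-squares fits, each
reporting adjusted R² and AIC. The AIC convention is
`n·ln(RSS/n) + 2k` with `k` counting coefficients plus the residual
variance — only comparisons matter, so the convention is fixed and stated.
Classification: *linear* iff the linear adjusted R² ≥ 0.9, which
short-circuits the AIC comparison; otherwise the lowest-AIC converged
model decides. The Hill fit starts at `ymax = max(y)`, `h` at the
interpolated half-max, `n = 2`, multi-starting over `n ∈ {1, 2, 4}`; a
non-convergent Hill fit is flagged and excluded. A flat (zero-variance)
response is classified linear by convention.

**Combination vs summation.** A two-way ANCOVA (`lm`) of AUC on the
continuous covariate (duration or ITI) and the categorical type factor
(measured combination vs sum of singles), five trials per group. A
significant (p < 0.05) negative type effect is *sublinear*, positive
*supralinear*, otherwise *linear*. Under the null with the package's
multiplicative noise model the type p-value is uniform to within what a
500-repetition KS test can detect, and a planted offset of three
per-observation SDs is detected essentially always — both run in the
suite.

**Temporal sensitivity and robustness.** An ITI scan is summarized by the
mean AUC over the five ITIs, the max−min *temporal sensitivity*, and the
argmax ITI (ties resolve to the larger, i.e. more spaced, interval).
Robustness perturbs molecule concentrations by up to ±10% — singly, or
collectively with uniform draws — reruns the ITI scan per draw, and ranks
molecules by random-forest importance (100 trees; weights normalized to
sum to one, which the implementation asserts to 1e-9). The unperturbed
control is always included as the reference for percent changes. A
constant response leaves importances undefined and is an error rather than
a silent zero vector.

**Synthetic data.** Every statistic has a seeded generator with stored
ground truth (`synthetic_spec()` / `generate_synthetic()`): Hill and
linear dose–response curves, ANCOVA group structures, ITI profiles,
planted-feature regression designs, and ISO-style input time series
(labelled synthetic, including in their file names). Noise is
multiplicative Gaussian because stochastic-simulation AUC spread scales
with signal. The recovery suite pins pre-registered tolerances: e.g. Hill
data generated at `h = 6.7, n = 2.5` with 2% noise on the standard
duration grid are recovered within ±1.0 and ±0.5 respectively in ≥ 90% of
100 seeded repetitions.

## Problem sizes and defaults

Experiment drivers default to five trials (seeds 2021–2025), the
tau-leaping engine at tolerance 0.1, a 300 s pre-stimulus window, and
analysis windows of several hundred seconds past stimulation end; the
fixture's dynamics settle well within these windows. The solver-agreement
check uses a 1000 µm³ volume, a 20 nM/2 s cAMP pulse and 50 seeds, sizes
at which Monte Carlo error sits comfortably below the 2% acceptance band.
The robustness suite defaults to 50–100 random draws over the five
non-input molecule pools. All sizes are arguments, so larger studies are a
matter of changing a call.

## Design decisions that were genuinely open

* **Clamp versus flux injection** for stimuli: clamping was chosen because
  the protocols are stated as peak concentrations (see above); a flux
  formulation would make peaks depend on clearance parameters.
* **Whether within-train pulses fuse**: fused (the clamp holds across the
  10 ms gaps), consistent with trains behaving like sustained pulses on
  clearance timescales.
* **Dispersed phospho-SynGap** in the full parameterization is treated as
  irreversible on simulated timescales (no return path to the spine); the
  knockout interface reserves the `K_Syn3` label for the conversion, and
  `dispersion = FALSE` zeroes it.
* **Raf dimerization off** grants the monomeric Raf–RasGTP complex the
  dimer's catalytic rate (labels `K_dimer`, `K_cat_dimer`, `K_cat_mono`),
  so the variant isolates the dimerization requirement rather than
  removing Raf activity.
* **Uniform output grid** rather than a stimulation-dependent one: the
  trajectory contract (uniform spacing) and AUC grid-stability were judged
  worth more than the storage saved by coarse sampling between trains.
* **`time_to_basal`** uses the 5%-of-excursion/60 s criterion because a
  percent-of-basal rule degenerates when basal is near zero.

## Known limitations

* The package is single-compartment by design: no diffusion, no spatial
  microdomains, no multi-voxel morphology.
* The published rate-constant tables are not bundled; quantitative
  comparisons against published concentrations and timings require loading
  those tables via `load_network()`, and `run_validation_suite()` is the
  entry point that insists on them.
* The tau-leap variant is validated against the exact SSA in distribution,
  not against any external simulator's stepping scheme.
* Fixture conclusions are structural. In particular its bistable CaMKII
  switch is a caricature: real CaMKII ultrasensitivity is graded by PP1
  saturation, which the two-reaction switch does not resolve.

## A worked example

```{r example, eval = FALSE}
net <- build_fixture_network()
validate_network(net)

scan <- run_single_pathway_scan(net, "cAMP", "duration",
                                grid = c(1, 4, 10, 30),
                                seeds = 2021:2023, post_window = 200)
scan$fit

lltp <- run_lltp_scan(net, c(cAMP = 500), seeds = 2021:2022,
                      readouts = "ppERK", post_window = 400)
lltp
```
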