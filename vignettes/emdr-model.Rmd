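---
title: "A hybrid discrete-continuum model of environmentally mediated drug resistance"
author: "emdrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid discrete-continuum model of environmentally mediated drug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdrsim)
```

## The problem

Molecularly targeted therapies (ALK, EGFR or BRAF inhibitors, for example)
often produce a strong initial response followed by relapse from residual
disease. One driver of relapse that does not require genetic change is
*environmentally mediated drug resistance* (EMDR): under treatment stress,
cancer cells recruit nearby cancer-associated fibroblasts (CAFs), whose
paracrine signalling restores the pro-growth signals the drug suppresses.
Because CAF activation is reversible when the drug is withdrawn, intermittent
scheduling (delivery periods alternating with holidays) can in principle
limit EMDR while still controlling tumour burden.

`emdrsim` simulates this interplay on a two-dimensional tissue cross-section
and provides the spatial readouts needed to characterise where residual
disease survives: EMDR-driven *survival niches*, drug-starved *persistence
niches*, and *eradication niches* in between.

## Model structure

The tissue is a square lattice (default 300 x 300 sites at `dx` = 10 um, one
cell per site). Three agent classes occupy sites exclusively: static blood
**vessels**, **stroma** (a passive majority and a reactive subset,
proportion `piReactive`, capable of CAF activation), and **cancer** cells.
Two continuum fields live on the same lattice, both scaled to [0, 1]:

* the inhibitor **drug** d(x, t), with dynamics
  `dd/dt = Dd laplacian(d) - mu v(x) d`, where `v(x)` indicates vessel sites.
  During delivery, d is clamped to 1 at vessels (Dirichlet sources); at all
  times vessels also clear the drug at rate `mu`. Boundaries are zero-flux.
  The field is advanced by forward Euler with a 5-point Laplacian on a finer
  time grid (`chooseSubsteps()`, see below).
* the **proliferation signal** p(x, t), the local net balance of pro-growth
  versus pro-apoptotic signalling:
  `dp/dt = (beta + gamma A(x)) H(1 - p) s(x) - delta d p`,
  with `s(x) = 1` at cancer sites (autocrine production), `A(x)` the number
  of activated CAFs in the Moore neighbourhood (paracrine production), a
  Heaviside saturation cap at p = 1, and drug-driven degradation at rate
  `delta`. The signal does not diffuse: the chemokines it represents are
  consumed locally or anchored to the extracellular matrix.

Cancer-cell fate is a pure threshold readout of the local signal: death
below `hd`, proliferation at or above `hp`, quiescence (cell-cycle clock
paused) in between. Each cell carries a clock and an intermitotic time
I ~ U[0.9, 1.1] days; a proliferative cell whose clock reaches I divides
into a uniformly random empty Moore site (no contact inhibition for cancer),
and both daughters restart their clocks, draw fresh I, and receive a signal
birth floor `p0`. Stroma turns over at rate `pT`, divides under contact
inhibition (aborted when more than `nCI` Moore neighbours are occupied), and
ignores the signal. Reactive stroma activates at probability rate `pA` when
the local drug is at or above `hr` *and* a cancer cell is adjacent
(contact-mediated recruitment); it deactivates immediately once the drug
falls below `hr`.

Because `beta / delta = 0.187 < hd = 0.2`, a lone cancer cell under full
drug always dies, while `(beta + gamma) / delta = 0.822 > hp = 0.8`, so a
single activated CAF neighbour is enough to rescue it to the proliferative
state. These two arithmetic facts are the engine of every niche phenomenon
the model produces, and they are pinned down directly by the test-suite.

## Parameters

`simParams()` returns the reference parameterisation (units in days, cm):

```{r}
simParams()
```

The drug clearance `mu = 500`/day is stiff relative to the macro step
`dt = 0.044 h`, so the drug equation is advanced on a finer grid:
`chooseSubsteps()` picks the smallest substep count with diffusion CFL
`4 Dd dt_sub / dx^2 <= 0.25` and clearance factor `mu dt_sub <= 0.1` (10
substeps at reference values). The clearance bound is an accuracy choice for
the stiff sink term, not a stability necessity; it keeps the per-substep
decrement under 10%.

Per-step probabilities use the linear conversion `rate * dt` (valid here
since every `rate * dt` is far below 1; the exponential alternative differs
by less than 1e-9).

## Update cycle

Each macro step applies, in a fixed order: (1) drug field (delivery flag
evaluated at the step's start time); (2) signal field from the current cell
configuration; (3) CAF activation/deactivation; (4) cancer death, clocks,
divisions; (5) stroma turnover and divisions; (6) time += dt. Agents are
visited in a fresh uniform random permutation every step to avoid
lattice-scan bias. All stochastic draws — vessel packing, reactive/passive
assignment, intermitotic times, turnover, activation, daughter placement and
the permutations — flow from R's single seeded RNG, so a seed fixes the
whole trajectory bitwise.

Two conventions worth noting, chosen where the rules left room:

* a cancer cell whose division is blocked (no empty neighbour) holds its
  clock at I and retries each step — treatment-induced deaths free space
  mid-cycle and regrowth depends on it;
* a stroma cell whose division aborts (contact inhibition or no space)
  consumes its cycle: clock reset, fresh I. This prevents synchronised
  retry storms and stabilises tissue homeostasis;
* activation reads the drug at the stroma cell's own site (the rule text
  is ambiguous between the stroma and cancer side of the contact);
* a quiescent cell whose clock already reached I divides one step after
  re-entering the proliferative state, not instantly.

## Experiment pipeline

```{r, eval = FALSE}
params <- simParams()
vessels <- placeVesselsPacked(c(300, 300), params@sigmaMean,
                              params@sigmaMin, params@dxCm)
tissue <- equilibrateStroma(vessels, params, duration = 100)
tumour <- seedAndGrowTumour(tissue)   # runs drug-free to 1e4 cells
traj <- runSim(tumour, treatmentSchedule("intermittent", 50, 20),
               horizon = 590, snapshotCadence = 1, seed = 1)
```

`equilibrateStroma()` fills every non-vessel site with stroma (reactive with
probability `piReactive`), staggers the initial clocks uniformly over each
cell's cycle, and runs drug- and cancer-free. Turnover against strict
contact inhibition (`nCI = 2` on the Moore neighbourhood) settles into a
*dynamic equilibrium well below full occupancy*: with the reference rates
the stationary occupied fraction is roughly 0.5, reached slowly (the decay
rate is `pT`), which is why the default 100-day burn-in still drifts and
the function warns when the final tenth of the burn-in is not stationary.
The quantitative experiments in this package equilibrate for 300 days,
after which the occupied fraction holds a band of about +-2% over the next
100 days. Deleted tissue blocks are recolonised toward that ambient density
on the `1/pT` timescale (wound healing); they cannot exceed it.

`seedAndGrowTumour()` lodges one cancer cell on a random Moore neighbour of
the most central vessel (displacing any stroma there) and grows the tumour
drug-free to the detection count.

## Analysis readouts

* `tumourBurden()`, `relativeTumourBurden()` and `cumulativeDrugDays()`
  quantify the trade-off between burden control and days on drug across
  schedules.
* `longitudinalOccupancy()` maps the fraction of daily snapshots in a time
  window (default [150, 590] days, discarding the transient) in which each
  site hosts a given class; co-located high cancer and high activated-stroma
  occupancy marks EMDR.
* `activationWindow()` returns the last 60% of each delivery period — the
  part of the cycle when activated stroma is present.
* `neighbourhoodDistribution()` histograms Moore-neighbour compositions
  around focal cells, pooled over snapshots; across replicates it reports
  either per-run means with a standard error across runs (runs are the
  independent unit; cells within a run are not independent) or fully pooled
  cells. Both modes are exposed because the pooling convention materially
  changes the standard error.
* `thresholdHighlight()` masks sites by `d >= hr`, `p >= hp`, `p < hd` and
  the like, for drug- and signal-window maps over a treatment cycle.
* `classifyNiches()` operationalises niche identification from two
  occupancy maps: survival (cancer and activated stroma both high),
  persistence (cancer high, activation absent), eradication otherwise. The
  thresholds `thetaC = 0.5`, `thetaA = 0.1` are declared heuristics —
  niches are identified visually in the source analyses, so these defaults
  are a reproducible stand-in, not calibrated values.

## Scaled-down study conditions

The reference experiments (300 x 300 lattice, 590 days, 30 replicates) are
cluster-scale. The package's quantitative test-suite and the acceptance
script reproduce the qualitative phenomena on a 60 x 60 lattice (0.06 cm
side) with the same parameterisation, scaled once as follows and not
revisited: a regular vessel grid at spacing 16 lattice units (sigma_mean
expressed in lattice units; the centred 3 x 3 grid carries 9 vessels),
detection at 400 cancer cells (the same detected fraction of the domain as
1e4 cells on the full tissue), 300-day stromal burn-in, 5 replicates per
regime (3 in the acceptance script). Under these conditions the model reproduces: monotone
untreated growth; the continuous-treatment EMDR signature (collapse to a
nadir, then CAF-driven regrowth above it); the schedule ranking in which
tau_T = 10 / tau_H = 20 fails to control burden while tau_T = 50 / tau_H =
20 holds it below detection; and the vessel-density transition from
poor-perfusion failure (spacing 30: no bulk death, no activation) through
eradication (spacing 16) to EMDR (spacing 12: bulk death followed by
rescued regrowth).

## What the generator does and does not emulate

The synthetic tissues capture the spatial logic of the reference system:
perfusion-limited drug build-up around a static vasculature, contact-gated
reversible CAF activation, and threshold-driven cancer fate. They do not
emulate angiogenesis or vessel remodelling, 3D or oblique vasculature,
ECM-mediated drug protection, non-contact crosstalk, immune involvement,
cell motility, or evolving drug sensitivity — all outside this model's
scope. Passing tests on the scaled tissue therefore demonstrate internal
correctness of the implemented mechanism, not quantitative fidelity to any
particular tumour.

## Numerical choices and degenerate inputs

* Forward Euler / central differences as specified; zero-flux boundaries by
  ghost-node reflection (mass-conserving in the absence of vessels).
* Signal values are clipped to [0, 1] after each step; with a stable step
  the clip binds only at saturation.
* Heaviside convention H(0) = 0: production is fully off at p = 1.
* The delivery predicate uses half-open cycles (delivery first), so
  `t = tau_T` is already holiday and no step is double-counted.
* Vessel counts floor the ratio `|Omega| / sigma_mean^2` (the target density
  is never exceeded); a tolerance of 1e-9 guards exact ratios against
  round-off. Circle packing is uniform rejection sampling with a retry cap
  and restarts — the published packing algorithm is not described in enough
  detail to reproduce, and only the minimum-distance constraint is
  testable.
* Degenerate inputs fail loudly: infeasible packings, unstable substep
  counts, mismatched grids, `hp > 1` growth timeouts and corrupted or
  version-mismatched snapshots all raise descriptive errors.

## Known limitations

Single 2D cross-section; one drug; fixed cancer phenotype (no resistance
evolution); stroma homeostasis equilibrates well below confluence under the
strict Moore-neighbourhood contact-inhibition rule, so tissue-density
statements are relative to that ambient level; run-to-run variability at
60 x 60 is substantially larger than at full scale, which is why the
dynamics tests assert patterns (orderings, signs) rather than magnitudes.
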