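---
title: "Potential landscapes and noise-driven sharpening of gene expression boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential landscapes and noise-driven sharpening of gene expression boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sharpland)
```

## The problem

During tissue patterning, a graded morphogen signal is read out by gene
regulatory circuits that commit cells to discrete fates. The mixed zone
separating two expression domains is initially several cell diameters wide
and becomes sharp over developmental time. `sharpland` implements a
stochastic modelling framework for this phenomenon built on three pillars:

1. a two-gene circuit whose deterministic dynamics are bistable over part of
   the morphogen range, simulated as a multiplicative-noise SDE per cell on
   a 2-D grid;
2. the probabilistic potential landscape `U = -ln(Pss)` obtained by solving
   the stationary Fokker-Planck (probability evolution) equation, with
   attractors, saddles, and barrier heights quantifying how hard it is to
   switch fate;
3. mean first passage times (MFPT) between the two expression states,
   estimated from trajectories, which link barrier heights to the observed
   sharpening speed.

Four circuit variants are provided. In all of them X and Y decay linearly
at rate `k` and regulatory interactions are Hill terms with shared threshold
`S` and coefficient `n`:

* **MRSA** -- mutual repression plus self-activation: each gene activates
  itself (`X^n/(S^n+X^n)`) and represses the other through the factor
  `1 - R + R*S^n/(S^n+Y^n)`; a single morphogen M activates both genes
  through `a1*M^n/(S^n+M^n)`. The asymmetry ratio `A >= 1` weakens X's
  basal synthesis (`b/A` against `b`), making the Y state the favoured one.
* **SA** -- self-activation only on Y (with gain `k_selfact`), X keeps the
  repression input from Y; bistability lives entirely in the Y axis.
* **MR** -- the classic mutual-repression toggle without self-activation.
* **MRSA_CROSS** -- the symmetric MRSA circuit (`A = 1`) driven by two
  opposed gradients, M1 activating X and M2 activating Y.

## Deterministic backbone: regimes along the morphogen axis

The shipped parameter sets are *calibrated*: the constants printed with the
switching-time analyses (MRSA: `k = 0.7`, `b = 0.7`, `R = 0.6`, `A = 1.4`;
MR: `R = 1`, `k = 1`, `b = 1`) are fixed verbatim, and the remaining
constants (`a`, `a1`, `S`, `n`, and SA's `b1`, `b2`) were selected once, by
the seeded screen in `scripts/calibrate_params.R`, against three structural
requirements:

```{r regimes}
p <- default_params("MRSA")
p
bifurcation_scan(p, reference_m_levels("MRSA"))
```

* **Regime sequence.** Balanced bistability at the low reference morphogen
  level, biased bistability at the intermediate level, a single Y state at
  the high level (for MRSA the reference levels are M = 0.5 / 0.8 / 1.2).
  The bistable fold of the calibrated MRSA sits at M of about 1.1, safely
  above the intermediate anchor so that the shallow X basin is still a
  genuine basin there.
* **Fate commitment.** The canonical initial state
  `(X0, Y0) = (0.5 + s*N(0,1), 0.01)` must flow to the X attractor wherever
  the circuit is bistable. This is a real constraint: with a large Hill
  threshold the race from low expression is decided purely by basal rates,
  which favour Y (`b > b/A`), and the whole tissue turns red regardless of
  noise. Committing the initial state to X requires the threshold to sit
  near the initial X level (S of about 0.5), so that X's half-engaged
  self-activation and its repression of Y decide the race.
* **A switchable band.** Just below the fold the X basin must be shallow
  enough that gene-expression noise `d = 0.01` anneals it within the
  simulated horizon, while further from the fold the X state must hold.

The Hill coefficient settled at `n = 6`. With `n = 4` the screen produced
regime-correct circuits whose basins were either too deep to switch at the
study noise levels or too shallow to hold the low-morphogen domain; the
steeper Hill functions sharpen the contrast between the deep bistable bulk
and the marginal band near the fold, which is exactly the structure the
sharpening mechanism needs. `n` remains an explicit config parameter.

## The noise model

Cells obey the Langevin equation `x' = F(x) + d*x*zeta` with
`<zeta(t) zeta(t')> = 2 D_zeta delta(t - t')`. Two constants control the
stochastic behaviour:

* `d` -- the per-gene noise amplitude, the quantity varied across the study
  conditions (`d = 0, 0.01, 0.02`);
* `noise_psd` (`D_zeta`) -- the spectral level of the driving white noise.
  The Wiener amplitude of the simulated SDE is `d*x*sqrt(2*noise_psd)`.

`D_zeta` is not a per-experiment dial; it is part of the noise convention
and was calibrated once, jointly with the circuit screen, to
`noise_psd = 50`. The value is identifiable from the phenomenology: with
`D_zeta` of order 1 the effective fluctuations at `d = 0.01` are about 1% of
the expression level per unit time, which cannot cross any Hill-scale
barrier within the simulated horizon (t = 1000, with relaxation rate
k = 0.7) -- no noise level in the study range would sharpen anything. With
`noise_psd = 50` the three study conditions bracket the sharpening window:
`d = 0.01` anneals exactly the marginal band below the fold, `d = 0.02`
destabilizes a much wider region, and `d = 0` leaves frozen roughness
(below).

The Fokker-Planck solver uses a constant scalar diffusion `D`, decoupled
from `d` as an explicit config value, because a constant-D landscape is the
object being studied even though the trajectory noise is multiplicative.
For cross-checks between the two the package uses
`D = (d_eff * x_ref)^2 / 2` with `x_ref = 0.5` and
`d_eff = d*sqrt(2*noise_psd)`, e.g. `D = 1.25e-3` at `d = 0.01`.

## The morphogen generator

`parametric_gradient()` produces the default study input: a linear profile
rising from 0 to 1.5 across the tissue (so the calibrated circuits traverse
their full regime sequence), with multiplicative noise of amplitude `eps`.
The reaction-diffusion generator `simulate_ra_gradient()` (extracellular /
intracellular pools, no-flux anterior boundary, leaky posterior boundary,
space-time white noise) is available as an alternative; the parametric
generator is the default because the circuit-level claims depend only on a
monotone noisy gradient, not on specific gradient-formation kinetics.

**Per-cell quenched sensing.** `simulate_tissue()` defaults to
`morphogen_noise = "per_cell"`: each cell senses its column's deterministic
morphogen level with its own multiplicative factor `max(0, 1 + eps*xi)`,
redrawn whenever the field advances to a new saved time. With the default
single-time field (`times = 0`) the factors are *quenched* -- static
cell-to-cell variability in morphogen interpretation, as produced by
receptor-abundance differences. This choice is forced by the zero-noise
phenotype: if all rows of a column shared one morphogen realization, a
deterministic column could never split into a mixed column, and the rough
frozen boundary observed at `d = 0` could not exist. Quenched per-cell
sensing produces it naturally: cells whose private threshold-crossing
disagrees with their column's mean freeze on the wrong side of the fate
boundary and, without gene-expression noise, stay there forever. The
default amplitude is `eps = 0.12` (12% cell-to-cell sensing spread) for the
noise-window experiments; the amplitude-ratio experiments set `eps = L*d`
explicitly.

## Why there is a noise window

Putting the pieces together, the three study conditions behave as follows
on the reference 10 x 30 tissue (20 seeds, linear 0-1.5 gradient):

* `d = 0`: columns whose quenched sensing spread straddles the fate
  threshold freeze as mixed; terminal mean SI about 8.
* `d = 0.01`: the same stragglers sit in basins shallow enough to be
  annealed -- each wrong-side cell eventually escapes to Y and the mixed
  band resolves; terminal mean SI about 5.5, *below* the zero-noise value.
* `d = 0.02`: the effective noise now destabilizes the X state over a wide
  morphogen range; cells switch incompletely and at random times throughout
  the bistable bulk, and the boundary blurs; terminal mean SI about 11.

The sharpening index counts every mixed column (no boundary window), the
simplest unambiguous reading of "columns with mixed expression around the
boundary".

Two timing facts matter for interpreting SI traces. First, the boundary
*forms* during roughly the first 50 time units (the monostable right side
relaxes to Y and the marginal band begins to mix), so the SI trace rises
from its initial near-zero value to a peak around t = 50 before the
sharpening decline; "SI decreases with time" refers to the sharpening phase
after the peak. Second, the decline flattens toward t = 1000 -- the trace
almost reaches a steady value rather than hitting zero, because a thin
active front (columns whose cells' switching times are comparable to the
horizon) is always present.

## Landscapes, barriers and switching times

`solve_fokker_planck()` discretizes the stationary probability-evolution
equation by an exponentially-fitted finite-volume scheme
(Scharfetter-Gummel fluxes, drift evaluated at face midpoints, zero-flux
boundaries). The scheme conserves probability to machine precision and is
*exact* for linear drift, which the test suite exploits
(Ornstein-Uhlenbeck stationary density reproduced to near machine
precision at 200 x 200). The steady state is obtained by pinning one cell
of the (exactly singular) balance operator and solving the sparse system;
the anchor is placed at the domain centre and moved to the resulting
probability peak if the first solve is ill-conditioned, with an implicit
pseudo-time fallback. Default domain `[0, 3]^2` at 200 x 200 contains every
calibrated trapping box.

```{r landscape, eval = FALSE}
ls <- solve_fokker_planck(p, m = 0.7,
                          fp_config(D = 1.25e-3, domain = c(2.5, 2.5)))
find_attractors(ls)
```

Attractors are strict 8-neighbourhood minima of `U` filtered by topographic
prominence (minimax barrier to any deeper minimum at least 0.5 potential
units -- well below any basin scale of interest, far above discretization
ripple). The saddle between two attractors is computed *exactly* on the
discrete landscape by activating cells in increasing `U` under union-find
connectivity; the barrier for the X-to-Y transition is
`U(saddle) - U(X attractor)`.

`mfpt()` estimates switching times by the same integrator as the tissue
(single cell, multiplicative noise), from the X fixed point into a max-norm
ball of radius 0.1 around the Y fixed point. The radius is uncritical:
between 0.05 and 0.2 the estimates vary by far less than the barrier-driven
effects (a test asserts this). Censored runs (horizon `t_max`) are excluded
from the mean and reported. The 1-D quartic double well with additive noise
serves as the analytic anchor: at barrier-to-noise ratio 5 the simulated
mean escape time matches the Kramers closed form within a factor of two.

## Topology comparison under parameter perturbation

`compare_models()` perturbs every kinetic constant (not the integer Hill
coefficient) by `p -> p*max(0.01, 1 + sigma*xi)`, `sigma = 0.1`, clips `R`
to [0, 1], and runs paired tissues: identical grid, morphogen seeds, gene
noise seeds and save times across models, so that only the circuit (and its
own perturbation draw) differs. Replicates whose perturbed set loses
bistability at the variant's intermediate reference level are flagged and
kept -- losing bistability under perturbation is precisely the fragility
the comparison is meant to expose.

An honest caveat belongs here. Under the calibrated study conditions the
terminal-SI ordering across topologies does *not* favour the combined
(MRSA) circuit, and the reason is instructive: the sharpening index counts
mixed columns, so it penalizes only failures that *roughen* the tissue.
Perturbed MRSA and MR circuits fail rough -- the initial state loses the
race to the X attractor in part of the tissue, or basins become shallow
enough for two-way switching, leaving frozen or flickering speckle.
Perturbed SA circuits fail *clean*: when the Y self-activation bistability
collapses or the fate boundary slides off the domain, every column becomes
homogeneous and the SI drops to zero. A robustness metric built on SI
therefore structurally favours the topology whose failure mode is collapse,
and no combination of comparison conditions we examined (gene noise 0.005
to 0.02, sensing noise 0.03 to 0.12, either morphogen span, perturbing all
constants or synthesis-rate subsets) reverses this. The switching-time
comparison is unaffected: at the matched intermediate reference levels the
MRSA circuit has the shortest X-to-Y mean first passage time of the three
topologies, which `scripts/acceptance.R` recomputes.

## Numerical choices, in one place

* Euler-Maruyama with `dt = 0.01`, states clamped at 0 (multiplicative
  noise keeps exact paths positive; clamping only absorbs discretization
  overshoot). Save times `{10, 50, 100, 200, 500, 1000}`.
* Initial conditions `(0.5 + 0.05*N(0,1), 0.01)` (X-high) or mirrored
  (Y-high); jitter `s = 0.05`.
* Root finding: damped Newton from a jittered 8 x 8 start grid, roots
  merged at 1e-4 max-norm, stability from numerically differentiated
  Jacobian eigenvalues; validated against a dense sign-change grid scan.
* Fixed tissue geometry for tests: 10 rows x 30 columns (the headline grid
  is 10 x 100); rows only add replication within a column, and doubling
  them changes terminal SI by under 2 columns.
* Replication: 20 seeds / replicates in tests and acceptance runs, 100 for
  headline figures.
* Problem sizes in the acceptance script: 200 x 200 landscape grids,
  MFPT sweeps with 100-200 runs per condition and horizons of 2e4 time
  units, tissue ensembles of 20 seeds. These reproduce every ordering and
  monotonicity claim with comfortable Monte-Carlo margins.

## What the generator does and does not emulate

The synthetic tissue captures: a monotone noisy morphogen input; quenched
cell-to-cell sensing variability; intrinsic multiplicative expression
noise; independent cells (no division, movement, rearrangement or
juxtacrine coupling -- mechanisms the framework deliberately excludes so
that fate switching is the *only* available sharpening mechanism). Passing
tests therefore demonstrate the internal consistency of the noise-induced
switching explanation, not that real boundaries sharpen this way; in
embryos, cell sorting and signalling feedback operate alongside it.

## Known limitations

* Absolute switching times depend on the calibrated `noise_psd` and are not
  comparable to wall-clock developmental time; only orderings and
  monotonicities are meaningful.
* The Fokker-Planck landscape uses constant additive diffusion while the
  trajectories carry multiplicative noise; attractor positions agree to a
  few grid cells at the default `D`, but barrier *values* are convention-
  dependent (again: orderings are the robust content).
* The exchange-kinetics morphogen model ships with generic rate constants;
  it demonstrates the mechanism (monotone noisy gradient from a posterior
  source) rather than fitting any measured gradient.
* At morphogen levels far below the fold the MFPT is astronomically long
  and censored; sweeps are restricted to the measurable window.
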