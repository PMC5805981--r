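---
title: "Stochastic cycling in titration-based oscillators: models, engines and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic cycling in titration-based oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmposc)
```

## The scientific problem

Gene regulation is usually modelled under the *adiabatic* assumption:
transcription-factor (TF) binding and unbinding at the promoter is taken to
be much faster than protein production and turnover, so the promoter state
can be averaged out into an effective transcription rate. Single-cell
experiments show this assumption often fails — promoter switching can be as
slow as, or slower than, protein dynamics (the *non-adiabatic* regime), and
the discreteness of promoter states then dominates the dynamics.

This package studies that regime on two minimal two-gene circuits built
around *titration*: a TF `X` and an inhibitor `Y` that sequesters `X`
stoichiometrically and irreversibly into an inactive complex
(rate `alpha`).

* **ATC** (activator-titration circuit): `X` is constitutively produced and
  activates the inhibitor gene Y (production jumps from `beta_f_Y = 0` to
  `beta_b_Y = 10` as soon as any of the `nb` sites of the Y promoter is
  occupied).
* **RTC** (repressor-titration circuit): `X` represses its own promoter
  (`beta_f_X = 10` free, `beta_b_X = 0` bound) while `Y` is constitutive.

Binding at a multi-site promoter is *sequential* with per-step association
rate `kappa_Z * x` and dissociation rate `theta_Z`. A single dimensionless
factor `lambda` multiplies `kappa_Z` and `theta_Z` — and nothing else — so
one parameter set can be moved between the adiabatic (`lambda = 10^3`) and
non-adiabatic (`lambda = 1`) regimes without changing any equilibrium
constant. Time is measured in units of the protein degradation rate
(`delta = 1`), concentrations in molecules per system size `Omega = 10^3`.

The central phenomenon: deterministic mass-action kinetics of these
circuits admit **no limit cycle** (shown below), yet in the non-adiabatic
regime the stochastic system displays robust, unimodal *stochastic cycles*
of alternating high-`x` and high-`y` expression. The package provides four
progressively reduced descriptions of the same model and the statistics
needed to compare them.

## The model hierarchy

### Full chemical master equation (CME)

The exact molecular-level description: discrete copy numbers
`(N_X, N_Y)` and promoter occupancies `(s_X, s_Y)`, with mass-action
propensities scaled by reaction order (zeroth order `Omega * beta`, first
order `rate * N`, second order `rate * N * N' / Omega`). Binding of one `X`
to a promoter site consumes a free molecule; unbinding returns it.
`simulate_cme()` generates statistically exact sample paths with the
Gillespie direct method (compiled inner loop). At `Omega = 10^3` a single
long run needs on the order of `10^7`–`10^8` events, so trajectories are
thinned to grid snapshots while every promoter-state change is stored
un-thinned (period detection and occupancy statistics only need these).

### Piecewise deterministic Markov process (PDMP)

In the thermodynamic limit (`Omega >> 1`) the concentrations
`x = N_X / Omega`, `y = N_Y / Omega` follow the deterministic drift

    dx/dt = beta_X(s_X) - delta_X x - alpha x y
    dy/dt = beta_Y(s_Y) - delta_Y y - alpha x y

between promoter switching events, while switching stays discrete and
stochastic with hazards `kappa_Z x` (binding, `s_Z < nb_Z`) and `theta_Z`
(unbinding, `s_Z > 0`). The `O(1/Omega)` sequestration of TF into the
promoter is dropped from the drift, consistent with the lowest-order
system-size expansion. No timescale assumption is made: the PDMP is valid
in both regimes. `simulate_pdmp()` implements the exact event clock for
time-inhomogeneous hazards: the cumulative hazard
`Lambda(t) = ∫ Σ hazards dt` is integrated alongside the ODE flow and an
event fires when `Lambda` crosses an `Exp(1)` threshold (`-log u`), located
by the integrator's root finder; the channel is chosen proportionally to
the hazards *at the located event time*.

### Linearized PDMP (fast-titration limit)

The only nonlinearity is the titration term `alpha x y`. When titration is
fast compared with everything else, the minority species is consumed
essentially instantly, so the state collapses onto two regimes — `x > 0,
y = 0` or `x = 0, y > 0` — and the positive species `w` obeys the *linear*
flow `dw/dt = b - delta w` with net production
`b = beta_X(s_X) - beta_Y(s_Y)` (x-positive regime; the sign flips in the
y-positive regime). Everything is then analytic:

* the flow `w(t) = b/delta + (w0 - b/delta) e^{-delta t}` (`closed_flow()`),
* the deterministic regime-switch time (first hitting of `w = 0`,
  `hitting_time_zero()`),
* the binding-time survival function
  `S(t) = exp(-kappa ∫ w)` (`survival_binding()`), sampled exactly by
  monotone bracketed inversion (`sample_binding_time()`).

`simulate_linear_pdmp()` competes unbinding (exponential), binding
(survival inversion; identically zero hazard in the y-positive regime where
`x = 0`) and the deterministic titration switch. For the ATC at
`lambda = 1` the typical orbit is the anticlockwise "full cycle"
`(s=0, y>0) → (s=0, x>0) → (s=1, x>0) → (s=1, y>0)`; with multiple binding
sites the same machinery shows the system trapped in a `s = 0 ↔ 1`
"mini-cycle", which is why extra sites neither lengthen the period nor
improve coherence in the idealized circuits.

### Alternative deterministic limit (ADL)

`simulate_adl()` replaces every random waiting time by its first moment
(exponential mean `1/theta`; binding mean `∫ S dt` by quadrature, infinite
when the accumulated hazard stays bounded) and, among competing channels,
fires the one with the minimal mean — a deterministic analogue of the
first-reaction method. The orbit becomes exactly periodic at the first
state revisit (states compared with `w` quantized at `1e-9`); if every
channel's mean time is infinite, the parameter set is flagged
non-oscillatory. The ADL answers "what would the cycle look like with all
switching variance removed" and gives a zero-variance reference period.

### Why the deterministic (adiabatic) limit cannot oscillate

In the fast-switching limit the promoter occupancy reaches the
quasi-stationary distribution (QSD) of a birth-death chain with constant
birth `kappa_Z x` and death `theta_Z`: `pi_s ∝ (kappa_Z x / theta_Z)^s`
(`promoter_qsd()`; invariant under `lambda` since `kappa` and `theta` scale
together). The promoter-averaged production
`beta_eff = beta_f pi_0 + beta_b (1 - pi_0)` closes the planar mass-action
system (`adiabatic_rhs()`). Its Jacobian trace is

    tr J = d beta_eff_X/dx - delta_X - delta_Y - alpha (x + y)

(`jacobian_trace()`, with the analytic QSD derivative). For the ATC
`beta_eff_X` is constant and for the RTC it is decreasing in `x`, so the
trace is negative on the whole positive quadrant and the Bendixson
criterion rules out limit cycles. `no_limit_cycle_check()` certifies this
on a configurable grid (default 200 x 200 over `[0, 3 beta_max/delta]^2`) —
a numerical certificate, not a symbolic proof. `check_adiabatic()` adds an
empirical convergence check from random initial conditions.

## Period detection and coherence

Stochastic cycles have no marker event, so a measurement protocol is part
of the analysis. The default (`period_protocol()`) is hysteresis
thresholding of the TF concentration `x`: an upward crossing of `x_hi`
counts only after a prior excursion below `x_lo`, and the period is the
time between successive qualifying crossings. Thresholds default to 50%
and 5% of the maximal steady level of the observable's own gene
(`beta_max / delta` with `beta_max = max(beta_f, beta_b)` of gene X when
observing `x`), i.e. `x_hi = 1`, `x_lo = 0.1` for the ATC and `x_hi = 5`,
`x_lo = 0.5` for the RTC. The hysteresis band is what rejects
promoter-timescale jitter: a transient dip that does not reach `x_lo`
cannot re-arm the detector, so promoter "mini-cycles" do not register as
full periods. An alternative `"promoter"` protocol measures the time
between successive empty-to-occupied (`s: 0 → 1`) binding events; it *does*
see mini-cycles and is the right instrument for questions about rapid
promoter shuttling (it is also how the two protocols disagree about the
linearized model: the linear PDMP has exactly zero rebinding hazard while
`x = 0`, so it under-represents short promoter cycles relative to the CME,
whereas under the hysteresis protocol its lack of leftover-`y` memory
produces slightly faster regrowth).

Coherence is summarized by the coefficient of variation (CV = sd/mean) of
the detected periods; `glance()` on a period sample reports it with a
bootstrap standard error (10^3 resamples, unbiased variance estimator). A
minimum-period filter (`period_filter()`) is available for analyses that
discard sub-threshold cycles and records how many were removed.

The origin of cycling is laid bare by a two-state promoter with constant
rates `k_plus`, `k_minus`: its period is the sum of two independent
exponentials — hypoexponential, with mean `1/k_plus + 1/k_minus` and
variance `1/k_plus^2 + 1/k_minus^2` (`hypoexp_pdf()`, `hypoexp_moments()`,
`hypoexp_sample()`). The full circuits improve on this baseline because the
full cycle restarts binding from `x0 = 0`: the hazard must ramp up, which
concentrates the binding-time distribution. Note the effect is on the
*relative* width — at `b = 2, delta = 1, kappa = 1` the binding-time CV is
0.63 from `x0 = 0` against 1.0 (exponential) from `x0 = 2` — while the
absolute variance actually decreases with `x0`; coherence of the cycle is
a statement about CVs.

## Extended models

Two published, more mechanistic versions of the ATC are implemented as
*structural* PDMP engines: their numeric rate values are not printed in the
source this package follows and are therefore config-supplied (YAML
templates with placeholders under `inst/extdata/`; loading an unfilled
template fails validation loudly).

* **KB model**: explicit mRNAs, activator homodimerization (`2A ⇌ A2`),
  reversible titration (`A + I ⇌ AI`), and *distributive* multi-site
  binding — hazards carry the combinatorial multiplicities
  `kappa_b (G_max - G) [A2]` and `theta_b G` (`kb_drift()`,
  `kb_hazards()`, `simulate_kb_pdmp()`). The mRNA stage introduces the lag
  that lets the promoter reach full occupancy before titration catches up,
  which is the mechanism behind longer, more coherent cycles.
  `rescale_mrna()` implements the lifetime experiment: multiply mRNA
  degradation *and* translation by a factor `w` so protein output is fixed
  while the lag `1/(w delta_m)` shrinks. `simulate_kb_reduced()` keeps only
  the stochastic unbinding events and fires binding deterministically at
  the first moment of its waiting-time law (quadrature on
  `exp(-∫ kappa_b (G_max - G) [A2])` along the flow).
* **VKBL model**: the activator also activates itself (two binary
  promoters `G_A`, `G_R`), titration forms a complex `C` from which the
  inhibitor is recycled when the bound activator degrades (`vkbl_drift()`,
  `vkbl_hazards()`, `simulate_vkbl_pdmp()`). With self-activation the
  adiabatic system can be excitable; rare long unbinding events are what
  kick it into large excursions, and the ADL of this model (all waiting
  times at their means) shows none.

Design choice: promoter-bound dimers are treated as sequestered from the
free pool at the drift level only through the `O(1/V)` correction, which is
dropped — the same convention as the idealized PDMP. The complex-recycling
structure of the VKBL model follows its published schematic; users
supplying parameters should confirm the heterodimer conventions of the
original sources.

## Numerical choices

* **Event clock** (PDMP engines): `Lambda` is augmented as an ODE state and
  the crossing of `-log u` located by `lsodar` root-finding; integration
  proceeds in chunks of 25 time units so long inter-event gaps do not build
  oversized dense outputs. ODE tolerances `rtol = 1e-8`, `atol = 1e-10`;
  event-time roots to the integrator's root precision.
* **Negativity guard**: concentrations within `-1e-8` of zero after a step
  are clipped to 0 (integrator undershoot); anything more negative raises
  a simulation error rather than being silently repaired.
* **Survival inversion**: on the log scale, bisection via `uniroot` to
  `1e-10` inside a bracket grown geometrically until the cumulative hazard
  exceeds the target; if the total accumulable hazard (closed form) cannot
  reach `-log u`, the binding time is `+Inf` (possible whenever `b <= 0`).
* **Ties**: simultaneous events have probability zero; the deterministic
  resolution order is titration switch > unbinding > binding.
* **Degenerate inputs**: `theta = 0` with positive binding gives a QSD
  point mass at full occupancy (returned explicitly); `nb = 0` genes are
  constitutive; `x0 = 0` flows with `b < 0` have hitting time 0; the ADL
  raises a typed error from absorbing states.
* **Crossing times** are linearly interpolated between stored samples
  (default grid `dt = 0.01`), so detected ADL periods are constant only up
  to interpolation error (~1e-5); the exact zero-variance statement is
  checked on the segment durations themselves.
* **Reproducibility**: every engine takes an integer seed; a seed plus a
  parameter set reproduces the event sequence bit for bit. The CME engine
  draws from R's RNG stream inside the compiled loop, so R-level seeding
  governs it too.

## What the test conditions do and do not show

The quantitative checks in `tests/testthat/test-acceptance.R` run the
study conditions: the preset parameter sets, `lambda = 1`, `Omega = 10^3`,
with problem sizes chosen for a single CPU — about 2 x 10^3 detected cycles
for the CV reproduction and the CME-PDMP distributional comparison
(two-sample KS), 10^4 cycles for the two-state hypoexponential law, 100
random draws for the closed-form-vs-quadrature oracles. The synthetic
stochastic-cycle data are generated by the package's own exact CME engine,
so these tests validate the *reduction chain* (CME → PDMP → linear PDMP →
ADL) and the analysis protocol against the exact molecular model; they do
not validate the biological realism of the idealized circuits themselves
(single promoter copy, lumped transcription-translation, irreversible
titration, no extrinsic noise). KB/VKBL quantitative behaviour depends on
rate sets the user must supply and is checked structurally only.

## Known limitations

* The CME engine is specialized to the two-gene titration family rather
  than a general reaction-network compiler; this keeps the inner loop
  simple and fast.
* The PDMP is a law-of-large-numbers limit: at small `Omega` the neglected
  demographic noise in `(x, y)` matters, and no Langevin correction is
  provided (by design).
* The linearized PDMP assumes fast titration; with `alpha` comparable to
  other rates its period distribution visibly departs from the CME's in
  the short-period tail.
* `no_limit_cycle_check()` certifies a sign condition on a finite grid;
  pathological traces varying below the grid scale would escape it.
* Period detection is protocol-dependent by nature; both protocols are
  exposed and configurable, and reported CVs should always be read
  together with the protocol that produced them.
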