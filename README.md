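# pdmposc

Stochastic gene-expression dynamics in the **non-adiabatic regime** —
where transcription-factor binding and unbinding at the promoter is as
slow as, or slower than, protein production and turnover — simulated and
analysed through a hierarchy of exact and reduced models of
**titration-based genetic oscillators**.

## Who this is for

Modellers of gene circuits (circadian clocks, immune signalling motifs,
synthetic oscillators) who need to go beyond the quasi-steady-state
(adiabatic) approximation: when promoter states are long-lived, averaging
them into an effective transcription rate erases the very dynamics of
interest. The package provides matched implementations of the exact
molecular model and its principled reductions, so the same parameter set
can be followed from discrete molecules down to a deterministic caricature.

## The models

Two minimal circuits couple a TF `X` and an inhibitor `Y` that titrates
`X` into an inactive complex at rate `α`: the **ATC** (X activates gene Y;
production `β_Y^f = 0` free, `β_Y^b = 10` bound) and the **RTC** (X
represses its own gene; `β_X^f = 10`, `β_X^b = 0`). Binding at the `n_b`
promoter sites is sequential (`κ_Z x` per step up, `θ_Z` per step down),
and a single scaling factor `λ` multiplies `κ_Z, θ_Z` to interpolate
between the non-adiabatic (`λ = 1`) and adiabatic (`λ = 10³`) regimes at
fixed equilibrium constants. Four engines share this parameterization:

| engine | description |
|---|---|
| `simulate_cme()` | exact Gillespie sample paths of the chemical master equation (compiled inner loop, `Ω = 10³` scale) |
| `simulate_pdmp()` | piecewise deterministic Markov process: ODE drift `dx/dt = β_X(s_X) − δ_X x − αxy` (and symmetrically for `y`) between stochastic promoter switches with hazards `κ_Z x`, `θ_Z`; exact integrated-hazard event clock |
| `simulate_linear_pdmp()` | fast-titration linearization: two regimes (`x>0, y=0` / `x=0, y>0`), closed-form flows `w(t) = b/δ + (w₀ − b/δ)e^{−δt}`, analytic binding survival `S(t) = exp(−κ∫w)` inverted exactly |
| `simulate_adl()` | alternative deterministic limit: every waiting time replaced by its first moment, minimal-mean channel fires — a zero-variance reference cycle |

Around them: adiabatic-limit theory (`promoter_qsd()`,
`effective_production()`, `jacobian_trace()`, `no_limit_cycle_check()` — a
Bendixson certificate that the deterministic limit cannot oscillate),
stochastic-cycle period detection with a hysteresis or promoter-event
protocol (`detect_periods()`, `period_filter()`), the hypoexponential
two-state period law (`hypoexp_pdf()` and friends), and structural PDMP
engines for two published mechanistic ATC variants with explicit mRNA
(`simulate_kb_pdmp()`, `simulate_kb_reduced()`, `simulate_vkbl_pdmp()`;
rate values are config-supplied via YAML templates in `inst/extdata/`).

Results come back as tibbles (trajectories) or tidy-able objects
(`tidy()` / `glance()` on period samples, `autoplot()` on both), so the
natural workflow is a pipe.

## Worked example

Simulate the idealized ATC in the non-adiabatic regime, detect its
stochastic cycles and summarize their coherence:

```r
library(pdmposc)

p <- atc_params(lam = 1, nb = 1)   # preset ATC rates, lambda = 1
traj <- simulate_cme(p, t_end = 3000, seed = 1)
glance(detect_periods(traj))
#> # A tibble: 1 × 6
#>       n  mean variance    cv  cv_se n_discarded
#>   <int> <dbl>    <dbl> <dbl>  <dbl>       <int>
#> 1   403  7.42     22.5 0.639 0.0431           0
```

403 complete stochastic cycles were detected in 3000 time units; their
mean period is 7.42 (in units of the protein lifetime) and the coefficient
of variation — the inverse measure of oscillation coherence — is
0.639 ± 0.043. For comparison, a bare two-state promoter with the same
switching rates (`k₊ = 1`, `k₋ = 0.5`) would give

```r
hypoexp_moments(1, 0.5)
#> # A tibble: 1 × 3
#>    mean variance    cv
#>   <dbl>    <dbl> <dbl>
#> 1     3        5 0.745
```

so the circuit's full cycle (binding from `x₀ = 0` after every titration
round) is measurably more coherent than its promoter alone. The
deterministic reference cycle and the impossibility of deterministic
oscillation in the adiabatic limit:

```r
attr(simulate_adl(p), "period")
#> [1] 4.746166
no_limit_cycle_check(p)$worst_trace   # Bendixson: trace < 0 everywhere
#> [1] -2
```

A command-line interface over the same functions ships at
`inst/cli.R` (`simulate`, `periods`, `sweep`, `check-adiabatic`,
`theory` subcommands).

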