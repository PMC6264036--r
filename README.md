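# flipdg

Simulation and calibration of **fluorescence loss in photobleaching (FLIP)**
experiments on real or synthetic 2-D cell geometries, built for quantifying
the transport of aggregation-prone proteins — diffusion, nucleo-cytoplasmic
exchange and the binding/release kinetics between the cytoplasm and
micron-sized protein aggregates (inclusion bodies) — directly from image
series.

## Who this is for

Quantitative cell biologists and modelers with FLIP sequences of cells
expressing a tagged protein (e.g. GFP-tagged polyglutamine constructs) who
want physical rate constants rather than empirical decay curves, and
numerical analysts who need a compact, fully testable interior-penalty
discontinuous Galerkin (DG) implementation of a reaction–diffusion model
with internal interface conditions.

## The model

The observable intensity is `c = u + u_b`: a free pool `u` diffusing with
constant `α` (µm²/s) and a hindered pool `u_b` bound reversibly with
space-dependent rate `k_on(x) = γ·u_b⁰(x)` and constant `k_off = γ·u⁰`,
both derived from the pre-bleach frame. While the laser is on, both pools
are bleached at rate `β` (1/s) inside the bleach disc Ω_B:

    u_t    = ∇·(α ∇u) + k_off·u_b − k_on·u − θ β u |_{Ω_B}
    (u_b)_t =            k_on·u − k_off·u_b − θ β u_b |_{Ω_B}

with zero-flux boundary conditions. The nuclear membrane Γ_M is either
semipermeable (flux `p⟦u⟧`, permeability `p` in µm/s) or an active
first-order exchange (import `k_cn`, export `k_nc`); aggregate boundaries
Γ_A carry a mass-conserving first-order exchange (binding `k₁`, release
`k₂`). Pre-bleach intensity ratios between compartments fix `k₂ = k₁/K`
and `k_nc = k_cn/K_M`, and the remaining free parameters are calibrated by
Nelder–Mead minimization of the misfit

    E = (1/n) Σ_i ∫_Ω (c_sim(t_i) − c_goal(t_i))² dx

against goal functions: denoised image frames represented in the same
piecewise-linear discontinuous space as the simulation.

The discretization is P1 SIPG (symmetric interior-penalty DG) with backward
Euler in time and two pre-assembled, pre-factored system matrices (bleach
on / bleach off) reused across all steps.

## Worked example: ground-truth parameter recovery

The package validates its own inverse machinery end to end: simulate the
semipermeable model with known parameters on a synthetic labeled cell
(30 µm cell, off-center nucleus, three aggregates, bleach disc in the
nucleus, ~470 triangles), add zero-mean Gaussian noise with variance equal
to 10% of the maximum intensity through the image pipeline, and calibrate
from deliberately wrong initial guesses:

```r
library(flipdg)

spec <- ground_truth_spec(seed = 1)      # truth: α=17, β=36, γ=0.2, p=0.3, k₁=0.0718
report <- parameter_recovery_experiment(spec)
print(report)
#> parameter-recovery experiment (permeable membrane model)
#>               alpha    beta    gamma      p      k1
#> truth      17.00000 36.0000 0.200000 0.3000 0.07180
#> recovered  17.97000 31.4900 0.199700 0.2950 0.07821
#> rel. error  0.05688  0.1252 0.001694 0.0168 0.08931
#> misfit 51.55 -> 3.77, 554 iterations
```

Diffusion, hindrance, permeability and aggregate-exchange parameters come
back within a few percent of the truth; the bleach rate `β` is recovered
with more scatter because a 2-second bleach at `β = 36 s⁻¹` already empties
the disc — solutions for `β = 16` and `β = 250` differ by less than
`10⁻¹³` in the pure-bleach limit, so the data contain little information
about it. The run takes a few minutes on one CPU.

Individual pieces are available directly: `build_synthetic_cell()` /
`read_gmsh_mesh()` for geometry, `forward_simulate()` for simulations,
`load_flip_stack()` / `goal_series_from_stack()` / `misfit()` for the goal
side, and `flip_objective()` / `calibrate_flip()` for fitting real data. A
command-line front end (`inst/cli/flipdg.R`) wraps the synthetic generator
(`synth`), the recovery experiment (`recover`) and real-data calibration
(`calibrate`).

## Layout

- `R/` — mesh geometry and Gmsh MSH I/O, DG assembly, time stepping, FLIP
  model, goal functions, calibration, synthetic experiment
- `tests/testthat/` — unit, property and acceptance tests (analytic
  oracles, matrix-exponential and stiff-ODE cross-checks, optimizer
  oracles, end-to-end recovery)
- `vignettes/flip-calibration.Rmd` — the model, discretization choices,
  units of interface rates, calibration design and known limitations
- `scripts/acceptance.R`, `inst/cli/flipdg.R`
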