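# foldax

Coupled simulation of cortical folding and axon-bundle pathfinding in a
2-D slice of developing brain tissue.

During the third trimester the cerebral cortex folds into gyri and sulci
while thalamocortical axon bundles are still navigating the white matter
toward it.  Imaging consistently finds far more fibers terminating in
gyri than in sulci.  `foldax` implements a mechanical explanation: the
folding cortex creates a stress landscape in the white matter — radial
tension beneath prospective gyri, tangential tension beneath sulci — and
growing axon bundles (i) accelerate under axial tension ("towed growth")
and (ii) gradually reorient toward the maximum tensile principal stress
(MTPS) direction, which steers them into gyri.  The bundles are not
passive: every element they traverse becomes a stiffer "fiber" element,
so the developing connectivity also reshapes where folds can form.

The package is aimed at computational biomechanics researchers studying
brain development: it provides the forward model, parameter sweeps and
ensembles, and the quantitative readouts used to characterise outcomes.

## Model core

* **Folding** — differential tangential growth of a morphoelastic bilayer:
  multiplicative decomposition `F = Fe·Fg` with tangential cortical growth
  `Fg = √ϑ I + (1−√ϑ) n₀⊗n₀` (det `Fg` = ϑ, `ϑ̇ = G_ctx = 0.02/d`) over an
  isotropically growing ECM (`Fg = ϑ^{1/3} I`, rate `G_ctx/6`);
  compressible neo-Hookean stress
  `T = μ Je^{−5/3} dev(be) + k(Je−1) I`; explicit quasi-static relaxation
  (plane-strain quads, mass scaling, mass-proportional damping, kinetic
  energy held below 5% of internal energy).
* **Pathfinding** — discrete bundle agents with Gaussian angle noise
  (0.025 rad/step), reorientation toward the MTPS at angular speed
  `ω = π/(2t*)·‖n^A × n_max‖` (`t* = 300` steps; skipped under
  compression or equal principal stresses), elongation
  `ΔL = [a(σ−σ₀) + G_axn]Δt` (`a = 0.015 mm Pa⁻¹ d⁻¹`, `σ₀ = 0`,
  `G_axn = 0.6–1.2 mm/d`), irreversible ECM→fiber element conversion, and
  settlement at the cortex–white-matter interface.
* **Readouts** — gyrification index (pial arc length over its convex-hull
  upper chain), gyral/sulcal classification against the mid-surface's
  average level, normalized gyral/sulcal fiber densities, fiber volume
  fractions, local (1 mm disc) and equivalent stiffness ratios, angular
  distributions, and counts of bundles reaching the cortex.

It also reproduces the literature conversion of stretch- and
force-dependent neurite elongation rates to the stress-dependent rate
`a` (`a = G/E` and `a = b·πD²/4`), spanning 0.0004–0.31 mm Pa⁻¹ d⁻¹.

## Worked example

A reduced-scale coupled run (a 12 × 24 mm slab, 20 bundles — the full
study conditions are the defaults of `simulation_config()`):

```r
library(foldax)
cfg <- simulation_config(w = 12, h = 24, t_c = 1.2, elem_size = 0.4,
                         n_fibers = 20, agent_steps = 200, substeps = 50,
                         seed_band = 4, seed = 42)
res <- run_simulation(cfg)
res
#> foldax result (seed 42): T = 1.000, GI = 1.9910
#>   agents settled 9 / stalled 9 / growing 2 of 20
#>   gyral density 100.0%, V_f 0.419, max KE/IE 0.0737 [quasi-static criterion violated]
```

The slab folds deeply (gyrification index 1.99), and every one of the 9
bundles that reached the cortex settled in a gyrus — the folding stress
field steered them there.  Nine bundles wandered into the symmetric side
walls of this narrow slab and stalled; on the full-width default geometry
stalling is rare.  (At this heavily mass-scaled test stepping the
kinetic-energy criterion is flagged; the default production stepping
keeps it below 5%.)  Ensembles and sweeps follow the same pattern:

```r
ens <- run_ensemble(cfg, n_replicates = 10)      # mean/SD of every metric
sw  <- run_sweep(cfg, "G_axn", c(0.6, 0.8, 1.0, 1.2), posthoc = TRUE)
```

Results can be written as VTK/CSV/JSON/YAML via `write_result()`, and the
agent model can be exercised against analytic stress fields without any
finite elements via `make_field()` + `agent_sandbox()`.

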