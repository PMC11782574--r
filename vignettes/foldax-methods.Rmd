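---
title: "Coupled cortical folding and axon pathfinding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled cortical folding and axon pathfinding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldax)
```

## The model

`foldax` simulates a 2-D slice of developing brain tissue as a growing
bilayer: a thin, stiff cortical plate (gray-matter analogue) on a deep
white-matter substrate whose continuum is the extracellular matrix (ECM).
Folding is driven by differential tangential growth (DTG): the cortex grows
tangentially faster than the substrate grows volumetrically, the mismatch
puts the plate under compression, and past a critical strain the plate
buckles into gyri (ridges) and sulci (valleys).  Discrete axon-bundle
agents grow through the substrate while it folds, are steered by the
substrate's stress field, and in turn stiffen the substrate — a two-way
mechanical coupling.

### Morphoelastic kinematics

Each material point carries a multiplicative decomposition of the
deformation gradient, $F = F^e F^g$, separating irreversible growth from
the elastic distortion that generates stress.  The cortex grows in-plane
(tangentially to the pial surface with referential normal $n_0$):

$$F^g_{\mathrm{ctx}} = \sqrt{\vartheta}\, I + (1 - \sqrt{\vartheta})\,
n_0 \otimes n_0, \qquad \det F^g_{\mathrm{ctx}} = \vartheta,$$

while the ECM (and converted fiber elements, to avoid spurious shear
between them) grows isotropically, $F^g_{\mathrm{sub}} =
\vartheta^{1/3} I$.  Both multipliers follow linear kinetics
$\dot\vartheta = G$ with $G^{\mathrm{ctx}} = 0.02\,\mathrm{d}^{-1}$ and a
cortex-to-substrate rate ratio of 6; dimensionless time is
$T = G^{\mathrm{ctx}} t \in [0, 1]$ (50 days).  Linear kinetics double the
cortical area over a run.  An exponential-kinetics switch
(`growth_kinetics = "exponential"`, $\dot\vartheta = G\vartheta$) is
provided because a larger terminal area expansion is also biologically
defensible; the package defaults to the linear law and asserts nothing
about which better matches any particular dataset.

All materials are compressible neo-Hookean,

$$W = \tfrac{\mu}{2}\!\left( J_e^{-2/3}\,\mathrm{tr}(F_e^T F_e) - 3 \right)
 + \tfrac{k}{2}(J_e - 1)^2, \qquad
T = \mu J_e^{-5/3}\,\mathrm{dev}(b_e) + k (J_e - 1) I,$$

with per-material shear moduli: ECM $\mu_s$ (default 100 Pa), cortex
$\mu_c = 2\mu_s$, fiber $\mu_f = 2\mu_s$.  Only the *ratios* shape the
folding pattern; the absolute $\mu_s$ sets the stress scale felt by the
stress-induced axon growth term and 100 Pa makes that term commensurate
with the tip growth rate at the default $a = 0.015$ mm Pa$^{-1}$ d$^{-1}$.
Bulk moduli are $k = 50\mu$ per material — effectively incompressible
without making the explicit solver's stable increment impractically small.

### Axon-bundle agents

Bundles (default 100) seed at $t = 0$, uniformly over the full width and
the bottom 10 mm of the substrate, with growth angles uniform in
$\pi/2 \pm 10\%$ so they head for the cortex.  Per agent step each growing
bundle:

1. receives Gaussian angle noise ($\sigma = 0.025$ rad by default) —
   the stochastic component of tip growth;
2. reads the in-plane Cauchy stress at its tip and, if the largest
   in-plane principal value $\sigma_1$ is tensile and non-degenerate,
   rotates its preferred direction $n^A$ toward the maximum tensile
   principal stress (MTPS) direction by the angular speed
   $\omega = \frac{\pi}{2 t^*} \lVert n^A \times n^T_{\max}\rVert$
   with relaxation parameter $t^* = 300$ agent steps.  The principal
   direction's sign ambiguity is resolved into the bundle's forward
   half-plane, and equal principal values (within a relative tolerance of
   $10^{-6}$, floored at the scale $\mu_s$) suppress reorientation
   entirely — an equibiaxial state has no preferred direction;
3. elongates by the combined tip and towed (stress-induced) law
   $\Delta L = [a(\sigma - \sigma_0) + G^{\mathrm{axn}}]\,\Delta t$ with
   target stress $\sigma_0 = 0$, where $\sigma = n^A \cdot T \cdot n^A$.
   The increment is floored at zero by default
   (`clamp_negative_growth`): compressive stress pauses growth but does
   not retract the tip, since the discrete tip model has no mechanism to
   un-convert elements; the unfloored variant is available behind the
   flag;
4. converts every ECM element its new tip segment traverses into a fiber
   element ($\mu \to \mu_f$ from the next increment; irreversible), and
5. settles permanently when it crosses the cortex–white-matter interface.

These conversions are the only symmetry-breaking imperfection in a default
coupled run, exactly as intended: the growing stiff fibers both trigger
buckling and bias where sulci can form.

### Coupling and time integration

The quasi-static folding problem is solved by explicit dynamic relaxation:
4-node plane-strain quadrilaterals (full 2$\times$2 Gauss quadrature for
the deviatoric response; the volumetric term uses the element-averaged
elastic Jacobian — a mean-dilatation/B-bar treatment that removes the
volumetric locking a fully integrated quad exhibits at $k/\mu = 50$,
while avoiding the hourglass machinery reduced integration would need),
total-Lagrangian assembly, lumped masses, central-difference updates and
mass-proportional damping.  Plane strain is realized by carrying the full
3-D tensors with total $F_{33} = 1$; the growth tensors keep their 3-D
forms, so out-of-plane elastic compression arises naturally.

Two clocks are used: agents update once per *agent step* (default 500 per
run, i.e. the cortical multiplier grows by 0.002 between updates, and
$t^*$ and the noise SD are expressed per agent step), while the solver
takes `substeps` explicit increments (default 100) inside each agent step.
The density is chosen automatically so the dilatational-wave CFL matches
the requested substep ("mass scaling"); the damping default is three times
the critical value of the structure's lowest estimated mode — enough to
absorb the kinetic-energy burst at the buckling bifurcation without
over-damping, which would visibly lag the quasi-static response (an
over-damped run stays compressed, which in turn suppresses the clamped
stress-dependent axon growth).  A run is accepted as quasi-static only if
kinetic energy stays below 5% of internal energy; the result carries a
`quasi_static_ok` flag and is never silently passed.  At the default
stepping the baseline run's maximum ratio is about 4%.

Tips are tracked in material (reference) coordinates, so advection with
the deforming substrate is automatic — a settled tip is a material point
and moves with the tissue.  Growth increments happen in the deformed
frame along $n^A$ and are pulled back by Newton inversion of the bilinear
isoparametric map; converted elements are found by a grid traversal of the
pulled-back segment.

Symmetric boundary conditions ($u_x = 0$) act on the lateral walls, the
base is fixed vertically, and the pial surface is free.  Pial self-contact
is not modelled; runs whose pial line self-intersects are flagged
(`pial_self_intersects`) rather than silently reported.  At the
gyrification levels reached under the study conditions, self-contact does
not occur.

## Readouts

* **Gyrification index** — arc length of the pial polyline divided by the
  length of its convex hull, using only the hull's upper chain between the
  pial endpoints: a straight or convex pial line scores exactly 1 (closing
  the hull underneath would bias the index).  Note the hull of a folded
  line hugs the gyral crowns, not the horizontal extent.
* **Gyral/sulcal classification** — the mid-surface is the pointwise mean
  of pial and interface heights at matched grid columns; a column is
  gyral when the mid-surface there is at or above the mid-surface's
  average height (the "average position" of the cortical surface), else
  sulcal.  Comparing the interface against the pointwise mid-surface
  itself would be degenerate — the interface lies below it everywhere by
  construction — so the average level is the reference.  Ties are gyral,
  making the labels a partition; a flat slab is entirely "gyral" by the
  tie rule.
* **Fiber density** — settled tips are assigned to the nearest interface
  point; each region's raw density is its settled count divided by its
  interface *arc length* (the natural 2-D measure of the region's
  extent), and the two densities are normalized to sum to 100%.
* **Volume fractions and stiffness** — deformed-area fractions of fiber
  vs. ECM elements over the white matter; the equivalent stiffness ratio
  is $V_f (\mu_f/\mu_s) + V_{ECM}$, and the local stiffness ratio
  evaluates the same quantity inside a 1 mm disc around each query point
  (discs clipped at the domain boundary).
* **Angular distribution** — tip angles folded into $[0, \pi]$, binned,
  normalized by the total agent count.

## Study conditions and reduced-scale testing

The production configuration is the study's: a $60 \times 30$ mm slab,
1.5 mm cortex, 0.25 mm elements by default (0.5 mm for the quasi-static
acceptance run; 0.1 mm is available where full fidelity is required),
100 bundles, 10-replicate ensembles.  Replicate seeds derive from the base
seed through a counter-based generator (splitmix64); every agent owns an
independent stream, so runs reproduce bit-for-bit and are independent of
R's global RNG.

The test suite exercises the coupled trends on a deliberately reduced
domain chosen on dimensional grounds, not tuned to outcomes:
$12 \times 24$ mm, 1.2 mm cortex, 0.4 mm elements, **20** bundles seeded
in the bottom 4 mm, 200 agent steps of 50 substeps.  The reduction
preserves the quantities the trends depend on: the fiber *line density*
(100 bundles / 60 mm $\approx$ 20 / 12 mm — keeping the default 100
bundles in a 12 mm window would quintuple the density and saturate the
substrate with conversions), the cortical thickness scale that sets the
fold wavelength, and the ratio of axon travel time to folding onset
(tips must still be in flight when folding starts, or the reorientation
mechanism has nothing to act on).

What coarse meshes cannot preserve is the conversion footprint: a
"bundle" occupies elements, so at 0.4–0.5 mm elements the fiber volume
fraction after a run is several times the value a 0.1 mm mesh would give,
the substrate stiffens more than physically intended, and
stiffness-mediated effects (the fiber-stiffness trends, and the
gyral-vs-sulcal margin in fast-growth scenarios where settlement precedes
folding) are distorted or can even invert.  Passing reduced-scale trend
tests therefore demonstrates the mechanism's direction under these
conditions, not the study's effect sizes; conversely a reduced-scale
failure of a stiffness-mediated trend reflects the coarse-mesh conversion
artifact rather than the model equations.

Two further observations from agent-free runs are documented here because
they shape the tests.  First, mesh-convergence of the gyrification index
holds only when the substep count scales with refinement (fixed CFL);
fixing the substeps while refining quietly increases the scaled inertia.
Second, with the lateral walls fixed, isotropic substrate growth at a
growth-rate ratio of 1 reaches ~26% confined compression by $T = 1$ —
beyond the creasing threshold — so an imperfection-seeded equal-growth run
creases even though DTG buckling is absent; the differential-growth null
case is therefore the imperfection-free run, which stays flat to
$GI < 1.005$.

## Limitations

* 2-D plane strain; no 3-D fold morphologies.
* No self-contact of deep sulci (flagged, not modelled).
* Tangential/association fibers, branching, fasciculation and chemical
  guidance cues are out of scope; only radially seeded bundles are
  modelled.
* The conversion footprint ties the fiber volume fraction to the element
  size (see above); quantitative $V_f$ and stiffness-map values are
  mesh-dependent at coarse resolution.
* The agent noise SD is defined per agent step, so its effective angular
  diffusion depends on the agent-step count; comparisons across different
  `agent_steps` values should rescale the noise accordingly.
* Absolute ECM modulus, tissue density and damping are not independently
  measured quantities here: the density implements mass scaling, the
  damping implements quasi-static relaxation, and only stiffness ratios
  and the stress scale $\mu_s$ carry physical meaning.

## A minimal coupled run

```{r example, eval = FALSE}
cfg <- simulation_config(w = 12, h = 24, t_c = 1.2, elem_size = 0.4,
                         n_fibers = 20, agent_steps = 200, substeps = 50,
                         seed_band = 4, seed = 42)
res <- run_simulation(cfg)
res$metrics
```
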