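---
title: "Model and methods: multi-phase-field simulation of cell extrusion"
author: "extrudesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multi-phase-field simulation of cell extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`extrudesim` simulates a confluent monolayer of N deformable cells on a rigid
substrate in three dimensions. Each cell i is a phase field
$\phi_i(\vec x) \in [0, 1]$ on a shared lattice (periodic in x and y, bounded
in z), with the $\phi_i = 0.5$ level set delineating the cell boundary and a
diffuse interface of width $\lambda$. The substrate is a static phase field
$\phi_w(z)$ occupying the bottom of the box.

The free energy has six contributions per cell:

$$
\mathcal F = \sum_i \frac{\gamma}{\lambda}\int
  4\phi_i^2(1-\phi_i)^2 + \lambda^2 |\nabla \phi_i|^2 \,\mathrm d\vec x
+ \sum_i \mu \Big(1 - \tfrac{1}{V_0}\!\int \phi_i^2\Big)^2
+ \sum_i \sum_{j \ne i} \frac{\kappa_{cc}}{\lambda} \int \phi_i^2 \phi_j^2
+ \sum_i \sum_{j \ne i} \omega_{cc} \lambda^2 \int \nabla\phi_i\!\cdot\!\nabla\phi_j
+ \sum_i \frac{\kappa_{cw}}{\lambda} \int \phi_i^2 \phi_w^2
+ \sum_i \omega_{cw} \lambda^2 \int \nabla\phi_i\!\cdot\!\nabla\phi_w .
$$

The first bracket is the Cahn–Hilliard interface energy (stiffness $\gamma$);
the second a soft volume constraint around $V_0 = \frac{4}{3}\pi R_0^3$
(compressibility $\mu$); $\kappa$ terms penalize overlap (repulsion) and
$\omega$ terms couple interface gradients (adhesion — overlapping diffuse
interfaces have anti-parallel gradients, so the term is negative and deepens
with contact, which is verified empirically on a two-droplet fixture rather
than assumed: with $\omega_{cc} > 0$ a relaxed pair drifts together and keeps
its contact, with $\omega_{cc} = 0$ and repulsion only it separates).

Dynamics couple an advected relaxation of each field,

$$ \partial_t \phi_i + \vec v_i \cdot \nabla \phi_i = -\frac{\delta \mathcal F}{\delta \phi_i}, $$

to an over-damped force balance per cell,

$$ \vec t_i \;=\; \xi \vec v_i - \alpha \vec p_i \;=\; \int \phi_i \,\nabla\!\cdot\!\Pi^{\rm int}\, \mathrm d\vec x, \qquad
   \Pi^{\rm int} = \Big(\sum_j -\tfrac{\delta \mathcal F}{\delta\phi_j}\Big) \mathbb 1, $$

with substrate friction $\xi$, in-plane polarity
$\vec p_i = (\cos\theta_i, \sin\theta_i, 0)$ and self-propulsion strength
$\alpha$. Polarity follows contact inhibition of locomotion:
$\partial_t \theta_i = -J\,|\vec t_i|\,\Delta\theta_i + \sqrt{2 D_r}\,\eta$,
where $\Delta\theta_i$ is the signed deviation of the polarity from the
in-plane traction direction and $\eta$ is unit white noise (Euler–Maruyama,
Itô increment $\sqrt{2 D_r \mathrm{d}t}\,N(0,1)$). The deviation convention
is such that the polarity rotates *toward* the net interaction force (the
stated biological mechanism); an exact anti-parallel tie breaks toward
$+\pi$. All times are reported in units of $\tau_0 = \xi R_0 / \alpha$.

A cell extrudes when its vertical center-of-mass displacement, relative to
the **median** height of the not-yet-extruded cells, first exceeds $R_0/2$.
The median (not the mean) keeps the reference robust to the extruding cell
itself. Extruded cells keep evolving by default (they detach naturally); a
config flag removes them from the dynamics instead.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| $a_0$ | 1 | length | grid spacing (all lengths in grid units) |
| $R_0$ | 8 | $a_0$ | initial cell radius; $V_0 = \frac43 \pi R_0^3$ |
| $\lambda$ | 2 | $a_0$ | interface width (2 is the resolvability floor) |
| $\gamma$ | 0.08 | energy | interface stiffness |
| $\mu$ | 300 | energy | volume-constraint modulus |
| $\kappa_{cc}$ | 0.1 | energy | cell–cell repulsion |
| $\kappa_{cw}$ | 0.05 | energy | cell–wall repulsion |
| $\omega_{cw}$ | 0.0025 | energy | cell–wall adhesion (canonical sweep 0.0015–0.0025) |
| $\Omega$ | 0.4 | — | $\omega_{cc}/\omega_{cw}$ (canonical sweep 0.2–0.6) |
| $\xi$ | 1 | force/velocity | substrate friction |
| $\alpha$ | 0.1 | force | self-propulsion strength |
| $J$ | 0.2 | 1/(force·time) | CIL alignment rate |
| $D_r$ | 0.005 | 1/time | rotational diffusivity |
| $\mathrm dt$ | 0.25 | time | explicit Euler step |

$\omega_{cw}$, $\Omega$, the box (320×320×64), $N = 400$, $R_0 = 8$ and the
29,000-step production length are the published study conditions. The
remaining coefficients are not printed in the source study (which defers them
to prior phase-field work); the set above was fixed once from first
principles on single-cell and two-cell fixtures: $\gamma, \lambda$ resolve a
stable tanh interface with explicit Euler at $\mathrm dt = 0.25$ (diffusion
stability bound $\mathrm dt < a_0^2/(12\,\gamma\lambda) \approx 0.52$); $\mu$
holds a relaxed droplet's volume within 5% of $V_0$; $\kappa_{cw},
\omega_{cw}$ let a droplet wet the substrate with a basal footprint of order
$R_0$ without sinking into it. The activity scale ($\alpha$, $J$, $D_r$) was
chosen so that a desk-scale monolayer (tens of cells, thousands of steps) is
pushed visibly out of its hexagonal ground state and produces extrusion
events within a tractable run length; at much weaker driving the reduced
system shows no extrusions at all within feasible desk-scale runs, which
would leave the extrusion statistics empty. These choices were made once and
define the package's study conditions at reduced scale.

# Numerical scheme

* **Discretization.** 7-point Laplacian and central/one-sided gradients;
  first-order upwind advection per velocity sign (a central option exists).
  Explicit Euler in time for both the fields and the polarity SDE. A CFL
  check (`max |v| dt / a0 < 1`) and a field-magnitude guard (`|phi| < 2`)
  stop the run with a diagnosable error rather than integrating garbage.
* **Exact energy–derivative adjointness.** Gradient-squared energy terms are
  discretized with forward differences (including the $-1$-index face terms
  of each cell's subdomain), whose exact discrete adjoint is the zero-halo
  7-point Laplacian used in the functional derivative. A central-difference
  variation of the total energy therefore matches the analytic derivative to
  round-off, which the test suite pins at relative $10^{-5}$ per term.
* **Boundaries.** Periodic in x/y. In z every cell-field operator uses a
  zero-Dirichlet halo (cells never reach the box ceiling in practice); the
  substrate profile enters through analytically extended difference vectors.
* **Subdomains.** Each field is stored on a moving rectangular box sized from
  its support plus padding, capped at about $1.3 R_0 + 6\lambda$ half-extent
  and always strictly smaller than the periodic axes (so the zero halo is
  exact). The box recenters on the cell's center of mass with a 2-point
  hysteresis. Scatter/gather between subdomain and full lattice is exact
  (round-trip tested). The linear wall-adhesion coupling induces a thin
  wetting film on the whole substrate plane ($\phi \sim 10^{-2}$); the cap
  truncates this film away from the cell body — the one deliberate deviation
  from an unbounded-support field, without which per-cell storage would be
  the whole lattice.
* **Startup.** Cells are seeded as tanh spheres of radius $R_0$ tangent to
  the substrate surface plane ($z_s = 4 a_0$, a few points above the floor)
  on a square lattice with spacing $\ge 2 R_0$, polarity uniform in
  $[-\pi, \pi]$. A short passive relaxation (pure gradient flow, CFL-limited
  steps, no advection) precedes production so the seeded shape — which is far
  from stationarity and would otherwise translate into large spurious startup
  tractions — is forgotten. With advection off and $\alpha = 0$ the scheme is
  a strict discrete gradient flow; the energy decreases monotonically, which
  is tested step by step.

# Analysis stack

* **Basal footprints and orientation.** The basal plane is the first lattice
  plane above the substrate midpoint surface. Cell orientation is the
  principal-axis angle (mod $\pi$) of the footprint's second-moment tensor;
  near-isotropic footprints (anisotropy < 0.05) are excluded from director
  averaging as unreliable.
* **Director and defects.** The nematic tensor $Q = \langle 2 n \otimes n -
  \mathbb 1\rangle$ is Gaussian-averaged (width $\ell_{dir} = R_0$) on a grid
  of spacing $\ell_{dir}/2$; defects are plaquettes whose director winding
  (differences re-wrapped to $(-\pi/2, \pi/2]$) is $\pm\pi$. Because the
  winding sum telescopes, the total charge over the periodic plane is exactly
  zero whenever every plaquette is counted. The $+1/2$ comet axis is the
  direction of $\nabla\!\cdot\!Q$ at the core. Tracking is greedy
  frame-to-frame nearest-neighbor linking, same charge only, gated at $R_0$
  per frame; a track's lifetime is its frame count.
* **Neighbor graph.** Cells are neighbors iff $\int \phi_i^2 \phi_j^2 >$
  threshold, with the default calibrated as $10^{-3}\times$ the overlap of an
  ideally tangent relaxed pair, making the graph insensitive to the threshold
  over about two decades. z = degree; z = 5 / z = 7 are fivefold / sevenfold
  disclinations. Lewis-law diagnostics compare mean basal area per z class
  against $(z-2)/4$ and $(z/6)^2$.
* **Stress.** The traction density $\vec T = (\sum_i \phi_i)\,\nabla \pi$
  (with $\pi$ the interaction scalar) is coarse-grained over cubes of side
  $\ell_{stress} = \max(R_0/4,\, 2a_0)$:
  $\sigma_{ij} = \frac{1}{2 V_{cg}} \sum_m (T_i e_j + T_j e_i)$, $\vec e =
  (\vec x_0 - \vec x_m)/|\vec x_0 - \vec x_m|$, excluding the undefined self
  point. $\sigma_{iso}$ is the 3D trace third by default (a 2D in-plane
  option exists for comparison with planar experiments); negative =
  compression throughout. Defect-frame averaging samples the basal
  $\sigma_{iso}$ on a square window of side $L = 1.5 R_0$ rotated so the
  comet axis points $+x$, accumulated over every frame of every $+1/2$ track
  and normalized by the maximum magnitude; bilinear periodic interpolation at
  resolution $a_0$.
* **Null model and test.** The no-correlation null re-draws extrusion events
  as a homogeneous Poisson process on the basal rectangle (intensity = the
  observed count, times uniform on $[1, n_{sim}]$), five realizations by
  default. The two-sample Kolmogorov–Smirnov test is implemented from the
  ECDF sup-difference with the asymptotic tail series and effective-size
  correction $\lambda_{KS} = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e}) D$; the
  base-R implementation is the independent cross-check in the tests, never
  the implementation. The five null realizations are pooled into one sample
  for the headline test (per-realization tests are reported alongside);
  rejection level 0.05, stated in the report.

# What the synthetic scenarios do and do not show

The built-in scenarios (`passive_hex_relax`, `two_cell_adhesion`,
`small_active_monolayer`, `production_scale`) generate every input from the seed —
there is no external data. The desk-scale `small_active_monolayer` (36 cells,
R0 = 6, 78×78×24 box — seeding spacing just above 2 R0, confluent after
spreading without a jamming cascade — for a few thousand steps; the test
suite uses 1,600-step runs over two seeds and the acceptance script
2,000-step runs over three seeds) reproduces the qualitative
phenomenology: hexagonal ground state when passive, fivefold/sevenfold
disclinations and half-integer defects when active, extrusion events
correlated with both, and compressive-head/tensile-tail defect stress
patterns. It does **not** reproduce the published statistics quantitatively:
those come from 36 cluster-scale runs (400 cells, 29,000 steps); at reduced
size the defect gas is sparse, event counts are tens rather than hundreds,
and distribution tails are noisy. Passing tests at desk scale therefore
validate the machinery and the qualitative science, not the exact published
curves; `production_scale` exposes the full configuration for anyone with the
compute budget.

# Numerical edge cases and conventions

* Degenerate (empty) fields: center-of-mass errors; empty basal footprints
  are masked, never silently zero.
* Windows clipped by the trajectory bounds are averaged over the available
  frames and flagged (`clipped`, `truncated`).
* Missing defect signs inside an event window yield missing values, not
  zeros.
* An all-zero stress field normalizes to zero by convention.
* Histogram densities integrate to one; the first moment is the plain mean,
  independent of binning.
* Seed policy: one master seed drives initialization and the polarity noise;
  sweep runs derive per-run seeds by a fixed linear congruence
  (`seed + 9973 * run_index` mod $2^{31} - 1$), so analysis reshuffles never
  perturb simulation randomness.

# Known limitations

* Single rigid velocity per cell in the advection term (consistent with the
  per-cell force balance); no intracellular flow.
* Explicit Euler: the time step is bounded by the interface stiffness, not by
  accuracy.
* The substrate wetting film induced by the linear adhesion coupling is
  truncated at the subdomain cap (see above).
* No proliferation, no apoptotic signaling, no deformable substrate, no
  active nematic (dipolar) stress — passive interactions plus polar driving
  only.
* The median-reference extrusion criterion, evaluated at step resolution, can
  fire during transient collective height fluctuations in very small systems
  (N of order 10); at the scales used here this was not observed.
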