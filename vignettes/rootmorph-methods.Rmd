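---
title: "Methods: depth-averaged morphodynamics around vertical-root patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-averaged morphodynamics around vertical-root patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootmorph)
```

## The problem

Several wetland and coastal tree species grow vertical root protrusions —
cypress knees, mangrove pencil and cone roots — whose function is debated.
One candidate explanation is geomorphological: during floods, a patch of
emergent vertical roots slows the flow passing through and around it
("bleed flow"), suppresses erosion in its wake, and accumulates a sand bar
downstream. That elevated, flow-sheltered bar is a prime germination site
for water-dispersed seeds. `rootmorph` implements a desk-scale coupled
model of this process: two-dimensional depth-averaged flow around arrays of
circular obstacles, mixed grain-size sediment transport, and bed evolution,
together with the analysis metrics used to quantify the effect (viable
downstream area above an elevation threshold, percent velocity change
across the patch, bar-peak position, optimal root density, and two-patch
cooperativity).

## Flow model

Continuity and momentum are solved in depth-averaged form,

$$\partial_t h + \nabla\cdot(\mathbf{V} h) = 0,$$
$$D_t(uh) - f(vh) = -gh\,\partial_x H + D_{xy}(uh) - \tau_{bx}/\rho,$$

and the analogous $v$ equation, where $h$ is depth, $\mathbf{V} = (u, v)$,
$H = h + z$ the water surface over bed elevation $z$, and $f$ a Coriolis
parameter (retained but zero by default: on a domain of tens of metres the
term is negligible and no latitude is specified for the scenarios).
Bed friction follows Manning:
$\tau_{bx}/\rho = C_f u\sqrt{u^2+v^2}$ with $C_f = g n^2/h^{1/3}$. The
Manning coefficient is a free parameter (default $n = 0.03$, a natural
channel); all sweeps record the value used.

Turbulent exchange uses an algebraic (zero-equation) closure derived from
the standard $k$–$\epsilon$ constants: the turbulent kinetic energy is tied
to the friction velocity, $\kappa_t = 2.07\,u_*^2$ with
$u_* = \sqrt{C_f}\,|\mathbf{V}|$, the dissipation is
$\epsilon = C_e \kappa_t^{3/2}/l$, and the eddy viscosity is

$$\nu = C_\mu \kappa_t^2/\epsilon = (C_\mu/C_e)\sqrt{\kappa_t}\,l,$$

with $C_\mu = 0.09$, $C_e = 1$, and the turbulence length scale $l$ equal
to the local depth — standard depth-averaged practice. We deliberately use
the dimensionally consistent $\nu = C_\mu\kappa_t^2/\epsilon$ rather than
the (dimensionally inconsistent, presumably typeset-garbled) form
$C_\mu\kappa_t/\epsilon$ that sometimes appears in solver documentation;
both constants are configurable. A floor `nu_background` ($10^{-4}$
m$^2$/s) keeps still water regularized.

### Obstacles and boundaries

Roots are circular obstacles represented as masked (blocked) cells on a
graded Cartesian tensor grid; obstacle faces carry zero flux and a no-slip
condition in the momentum diffusion term, so each root sheds a momentum
deficit into the flow. This replaces the unstructured triangular meshes
used by GUI-based river solvers; the 20-degree minimum-angle rule of such
meshes has no analogue here. Cell sizes grade from `near_cell_area` around
the roots (0.0006 m$^2$ for roots thinner than 20 cm, 0.001 m$^2$
otherwise, matching the reference configuration) to `far_cell_area`
(1.3 m$^2$) with an adjacent-cell ratio bounded by 1.3. Grid edges come
from integrating a mesh-density function, which makes the grid
deterministic and exactly symmetric for symmetric scenarios — a property
the test suite uses.

The flood boundary conditions mimic a riparian floodplain at peak flood:
discharge $Q$ (10–40 m$^3$/s) enters the upstream edge, distributed across
wetted cells in proportion to their Manning conveyance $\mathrm{d}y\,
h^{5/3}$ (the reference solver does not document its distribution rule;
conveyance weighting is the standard choice and degenerates to uniform for
uniform depth). The other three edges clamp the water height to 1 m via
ghost cells and are open to both water and sediment. Initial depth is 1 m
over a flat 10 m bed. The inflow ramps up over `q_ramp` seconds (60 s) of
the spin-up to avoid an impulsive bore; the morphology is frozen during
the 500 s spin-up.

### Numerics

The solver is an explicit flux-form finite-volume scheme on the collocated
grid: upwinded advection (first order by default, optional minmod-limited
second order), centered pressure gradient on $H$, and semi-implicit
friction. A Rusanov-type interface dissipation proportional to the local
gravity-wave speed $\sqrt{gh}$ is added to the mass and momentum fluxes.
It vanishes identically at rest (it acts on differences of $H$, not $h$,
so the lake-at-rest state is preserved to machine precision) and is what
stabilizes the collocated centered pressure coupling; without it,
obstacle-array pockets resonate gravity waves to blow-up. The price is the
two-dimensional stability bound
$\Delta t\,[(c+|u|)/\Delta x + (c+|v|)/\Delta y] \le 1$, which the
CFL-adaptive mode (target Courant number 0.7) enforces; fixed time steps in
the 0.01–0.08 s range are available for the "paper" settings bundle.
Positivity of $h$ is guarded by an outflow-flux limiter; cells below the
dry threshold ($10^{-4}$ m) drop out of friction and transport, and
near-dry cells shed momentum through a desingularized velocity recovery.
The water-volume budget closes against the boundary-flux ledger to
machine precision (the tests require $10^{-8}$ relative per step).

## Sediment transport

The sediment is a mixture of $n$ grain classes on log-spaced bins between
0.001 mm and 34 mm with $D_{50} = 3.2$ mm. Because "well-mixed" does not
determine a distribution, fractions follow a lognormal cumulative curve
(geometric spread `sdlog`, default 2.0 natural-log units) truncated to the
range and renormalized, with the median calibrated so the piecewise
log-linear cumulative curve crosses 0.5 exactly at $D_{50}$. Each class's
representative diameter is its bin mass centroid, which makes the mean
diameter $d_m = \sum p_k d_k$ insensitive to the number of classes (the
test suite checks an 8-versus-16-class halving); five classes are the
default for coupled runs.

Per class and cell:

* Shields stress $\tau_* = u_*^2/(s_g g d)$ with $s_g = 1.65$.
* Effective stress $\tau_*' = (n'/n)^{3/2}\tau_*$ by grain-roughness
  partition, $n' = d_m^{1/6}/(7.66\sqrt{g})$ (toggleable to
  $\tau_*' = \tau_*$): form drag on bedforms and vegetation does not move
  grains.
* Critical stress from the Iwagaki piecewise relation evaluated at the
  local mean diameter, modified per class by the sheltering (hiding /
  exposure) ratio: 0.85 for $d_k/d_m \le 0.4$ and the Egiazaroff-type
  $[1 + 0.34\ln(d_k/d_m)]^{-2}$ above, as printed ("paper" mode). The
  printed rendering of this rule is ambiguous, so an "ashida_michiue" mode
  with the $0.85/(d_k/d_m)$ lower branch ships as well; the two agree
  within 1% at the branch point and the mode is recorded in every run
  manifest.
* Bedload by Meyer–Peter–Müller,
  $q_b = 8\sqrt{s_g g d^3}\,(\tau_*' - \tau_{*c})^{3/2}$.
* Direction: near-bed speed $v_b = 8.5 u_*$ along the streamline and a
  secondary-flow transverse component $u_{bn} = -7 v_b h/r$ from the
  streamline curvature $1/r$ (computed by centered differences from the
  dimensionally consistent reading
  $[u(u v_x - v u_x) + v(u v_y - v u_y)]/|\mathbf{V}|^3$), plus a
  bed-slope deviation with coefficient
  $\sqrt{\tau_{*c}/(\mu_s\mu_k\tau_*)}$ ($\mu_s = 1.0$, $\mu_k = 0.45$).
  The square root follows Hasegawa's form; the printed expression is
  ambiguous about it and the toggle `kdev_sqrt` exposes both. The
  $(q_s, q_n)$ pair is rotated into Cartesian components by the flow angle
  $\theta = \mathrm{atan2}(v, u)$ with the standard rotation; the printed rotation
  formulas are not a rotation (at $\theta = 0$ they would map streamwise
  transport onto the transverse axis) and are treated as a typo.
* Suspended load: depth-integrated concentration $C h$ per class is
  advected (upwind, sub-stepped to its own CFL limit inside the
  morphodynamic step) and diffused with $D = \nu$ (turbulent Schmidt
  number 1). Entrainment follows Itakura–Kishi,
  $E_s = K[\alpha_*(\rho/\sigma)(u_*/w_0)(\Omega/\tau_*) - 1]$ floored at
  zero, with $K = 0.008$, $\alpha_* = 0.14$, and the original
  Gaussian-integral $\Omega$ ($B_* = 0.143$, $\eta_0 = 0.5$); a simplified
  pickup law is available as a fallback. Deposition uses the near-bed
  reference concentration from the Lane–Kalinske profile
  $C/C_\alpha = \exp[-(6w_0/\kappa_{vK}u_*)(z - z_\alpha)/h]$ with
  $z_\alpha = 0.05h$: integrating the profile gives
  $C_\alpha = \bar{C}\,\beta/(1 - e^{-0.95\beta})$,
  $\beta = 6w_0/(\kappa_{vK}u_*)$, capped at `profile_factor_cap` (100).
  The deposition term is integrated implicitly — for coarse classes
  $C_\alpha w_0/h$ far exceeds any explicit stability limit — which keeps
  the bed–suspension exchange exactly antisymmetric. Settling velocities
  come from Rubey's formula at 20 °C water viscosity.
* Entrainment of class $k$ is weighted by its surface fraction $p_k$
  (availability), the standard active-layer convention.
* Open boundaries pass sediment in both directions; fluxes *entering* the
  domain are scaled by `supply_ratio` relative to the local equilibrium
  load. The default 1 (equilibrium feed) leaves a uniform far field
  unchanged and lets the wake bar grow from material routed around the
  patch. Ratio 0 is a clear-water flood: physically the regime of
  progressive flood erosion, but its degradation front advances at only
  $\sim q_b/[(1-\lambda)\,\Delta z]$ — well under a metre per
  thousand seconds at the stated discharge — so it cannot traverse a
  desk-scale domain in affordable morphological time.

## Bed evolution

The Exner balance sums bedload divergence and net suspension exchange:

$$\partial_t z = \frac{-\nabla\cdot\sum_k p_k \mathbf{q}_k - \sum_k (E_{s,k} - C_{\alpha,k})w_{0,k}}{1-\lambda},$$

with void ratio $\lambda = 0.30$. Two deliberate corrections to the
printed balance: the $1/(1-\lambda)$ porosity factor is applied (the
reference configuration specifies the 30% void ratio; omitting the factor
mis-books solid volume, and a toggle restores the literal form via
`void_ratio = 0`), and the sign of the exchange term is the
mass-conserving one — net entrainment must lower the bed by exactly the
volume the suspension gains. As printed, the suspended-load and bed
equations would both gain mass on entrainment. With these choices the
global sediment budget (porosity-corrected bed change plus suspended
store, against the boundary-flux ledger) closes to round-off; the tests
require $10^{-6}$ relative.

Surface-layer composition advances by the active (exchange) layer
equation over the 0.5 m layer thickness: class fractions gain their own
deposition and lose the interface share of the total bed change, are
floored at zero, and renormalize to sum to one. A class cannot erode more
than its share of the layer in one step; any such clamp is logged in the
budget ledger. The morphological factor multiplies the bed-update rate and
stays at 1 (real-time coupling). Morphodynamics are sub-cycled every
`morpho_every` flow steps (10 in the coarse bundle, 5 in the paper
bundle); the suspended advection sub-steps internally so the sub-cycled
step never violates its own stability limit.

## Scenario generator

All inputs are synthetic and produced by `scenario_preset()`:

* Hexagonal root arrays grown ring by ring (ties broken by angle from the
  +x axis, so partial rings are deterministic); patch diameter $D$ =
  circumscribed circle of root centers + one root diameter (the source
  material does not define $D$ for partial rings); solid volume fraction
  $\phi = N(d/D)^2$; density $N/(\pi D^2/4)$.
* `tree_with_knees` / `tree_without_knees`: a 40 cm trunk with and
  without a surrounding knee array (61 roots of 20 cm at 0.6 m spacing,
  patch diameter about 5 m = 1 patch length).
* Three density-sweep families (fixed patch area, fixed root count, fixed
  spacing), trunk + 10 cm knee mixtures on the dual lattice for 40/80 cm
  trunks, two 37-root patches at a configurable edge gap, and small tree
  clusters.
* The two-patch preset separates the patches cross-stream with identical
  streamwise extents ("edges aligned"); the source description of the
  offset geometry is ambiguous, and this reading maximizes wake overlap,
  the mechanism behind the cooperative effect.
* Domain and patch position are not stated in the source material; the
  defaults (80 m streamwise × 30 m cross-stream, patch centered 20 m from
  the inflow) keep the 1–8 patch-length analysis window inside the domain
  and are configurable, as are all scenario fields through `overrides`.

## Settings bundles and what a green test establishes

Full reproduction of the reference experiments needs roughly $5\times10^5$
time steps per run across dozens of runs — not desk scale. Two documented
bundles separate the regimes:

* `numerical_settings("paper")`: fixed $\Delta t = 0.04$ s, second-order
  advection, near-root cells at the reference areas, 25000 s floods.
* `numerical_settings("coarse")`: CFL-adaptive steps, first-order
  advection, coarser grids and shorter floods (the test suite uses
  hundreds of seconds on metre-scale patches).

The automated tests establish: exact analytic closures, conservation to
stated tolerances, closed-form recoveries (Manning normal depth,
solid-body curvature, Gaussian-mound level sets), and the qualitative wake
transition with $\phi$ including the monotone growth of the percent
velocity change. Two scaled-down morphodynamic checks run at the largest
duration the test budget affords and are *expected to fail there*, by
design rather than accident: the downstream knee-patch bar emerges in this
model only after roughly 4000–6000 s of real coupled time on a full 5 m
patch (a 6000 s run yields a band +0.03–0.04 m above the far field with
its crest 1.6 patch lengths downstream, and morphological-factor
acceleration distorts the wake deposition rather than compressing it),
and the viable-area discrimination across root densities additionally
requires domain-wide bed change on the scale of the full 25000 s flood.
Both checks remain in the suite at their honest scaled settings; turning
them green requires the paper bundle on a workstation, not different
physics.

## Known limitations

* Depth-averaged 2-D flow over-predicts the onset of coherent wake
  turbulence (inverse energy cascade); the same caveat applies to the
  reference solver.
* First-order upwinding (coarse bundle) adds numerical diffusion that
  damps vortex shedding on coarse grids; the second-order switch reduces
  but does not remove this.
* No bank failure or avalanching, no cohesive sediment, a single exchange
  layer (no deeper stratigraphy), and the secondary-flow closure is the
  algebraic $u_{bn} = -7v_b h/r$ only.
* Stage-clamped lateral boundaries weakly reflect waves; scenarios should
  keep patches several diameters away from them.
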