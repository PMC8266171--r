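---
title: "A coupled phase-field / growth / transport model of atherosclerosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled phase-field / growth / transport model of atherosclerosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atheroFEM)
```

# The model

atheroFEM simulates atherosclerotic plaque development in an artery wall as
the interplay of three continuum fields on a 2D annulus (cross-section,
plane strain) or a 3D tube:

* **Displacement $u$** — quasi-static finite-strain equilibrium
  $\nabla\cdot\sigma = 0$.  The deformation gradient is computed from the
  spatial displacement gradient, $F = (I - \nabla u)^{-1}$, and split
  multiplicatively into an elastic and a growth part, $F = F_e F_g$ with
  $F_g = (1+\alpha) I$.  The Cauchy stress derives from a
  Holzapfel–Gasser–Ogden-type free energy
  $$\Psi = \tfrac{\mu}{2}(I_1 - 3)
         + \tfrac{\eta}{\beta}
           e^{\beta[\rho\langle \bar I_4-1\rangle^2 + (1-\rho)(\bar I_1-3)^2]}
         + \kappa_{vol}(J_e-1)^2 - \mu \log J_e ,$$
  with tension-only collagen fibers (Macaulay bracket
  $\langle\cdot\rangle$) wound helically at a constant elevation angle
  $\theta_{el}$ about the vessel axis.
* **Nutrient concentration $c$** — steady diffusion–reaction
  $\nabla\cdot(D\nabla c) - R_c = 0$, with diffusivity interpolating
  linearly between healthy and inflamed tissue,
  $D = \phi D_{min} + (1-\phi) D_{max}$.  Transport is quasi-steady because
  diffusion is much faster than the inflammation.
* **Inflammation phase field $\phi \in [0,1]$** — Allen–Cahn dynamics
  $\dot\phi = -M f'(\phi) + \epsilon^2\nabla^2\phi + S(\phi, c)$ with the
  double well $f(\phi) = 16 M \phi^2(1-\phi)^2$ and the nutrient-scarcity
  source
  $$S = R_s\, H(c - c_{cri})\,
        \frac{\nabla\phi\cdot\nabla c}{\max(|\nabla c|, \delta_g)} ,$$
  where $H$ steps *down* at the critical value ($H = 1$ for
  $c \le c_{cri}$): the lesion boundary is advected at speed $R_s$ along
  the nutrient gradient, but only where nutrient is scarce.

The closure is the growth law
$\dot\alpha/(1+\alpha) = k_g H(\alpha - \alpha_{cri})\,\phi$: overgrowth is
proportional to local inflammation and ceases once $\alpha$ crosses
$\alpha_{cri}$ (same inverted-Heaviside convention).

The outer wall layers are nourished by a **vasa-vasorum network** generated
as stochastic tree fractals anchored on the outer surface and penetrating to
mid-wall; every element cut by a tree segment carries the maximum-nutrient
Dirichlet condition.  The disease trigger is the occlusion of the tree
nearest the prescribed arc coordinate $S$: its nourishment is removed and a
small inflamed seed is placed at mid-wall there.

# Discretization and solver

Bilinear quadrilaterals (2D, 4 dofs/node) and trilinear hexahedra (3D,
5 dofs/node) on a structured polar grid; $2^d$ Gauss points per element;
$\alpha$ lives at Gauss points as an internal variable.  All three fields
are assembled **monolithically** on the deformed configuration and solved
per pseudo-time step by Newton–Raphson with a direct sparse LU
factorization; the transient phase-field term uses backward Euler.  The
element residual is implemented once, templated over the scalar type, and
the consistent tangent is obtained by complex-step differentiation of that
residual — exact to machine precision, including the follower-pressure and
finite-strain geometric terms.  Convergence is declared on the Euclidean
norm of the free-dof residual of the $K_c/K_\phi$-scaled system
(absolute tolerance, default `1e-6`); a diverged step is retried at half
the step size.

Three quantities are deliberately *lagged* at the previous converged step,
so they contribute no tangent blocks and keep the Newton residual smooth:
the scarcity gate $H(c - c_{cri})$, the advection direction
$\nabla c / \max(|\nabla c|,\delta_g)$ ($\delta_g = 10^{-8}$), and
$\alpha$, which is advanced *after* convergence by the exact sub-step
formula $\alpha_{n+1} = (1+\alpha_n)e^{k_g\phi\Delta t} - 1$ while the gate
is open.  The lumen pressure is a follower load on the deformed inner
surface (a dead load would be unphysical at the ~25% strains the soft wall
reaches); the initial growth-free pressurization is ramped in four
increments purely to give Newton a good path.

Boundary conditions: follower pressure $p_{max}$ and $c = c_{max}$ on the
inner surface; $c = c_{max}$ on nodes of vasa-vasorum-cut elements (minus
the occluded tree); natural zero flux for $\phi$ everywhere; rigid-body
modes are removed by minimal point constraints on three reference-ring
nodes (tangential components only, so radial breathing and — in 3D —
axial motion stay free).

# Parameters

All defaults (`default_config()`) are in micrometres, kilopascals and a
dimensionless pseudo-time unit: lumen diameter 50, wall thickness 15,
length 100, occlusion arc 30; $\mu = 10$ kPa, $\nu = 0.49$,
$\eta = 100$ kPa, $\beta = 1$, $\rho = 0.5$, $\theta_{el} = 60^\circ$;
$k_g = 0.25$, $\alpha_{cri} = 10^{-3}$; $D_{max} = 1$, $D_{min} = 0.1$,
$R_c = 10^{-3}$, $c_{max} = c_{cri} = 1$; $\epsilon = 1$, $M = 10$,
$R_s = 0.1$, $K_p = 10^4$; $p_{max} = 3.3$ kPa (25 mmHg);
$K_c = K_\phi = 1$.  The vasa-vasorum fractal uses trunk length 3, unit
branching ratios, $2\pi/3$ opening angles (2D), azimuths
$\{0, 2\pi/3, 4\pi/3\}$ with elevations $\pi/3$ (3D).

Choices the model statement leaves open, decided once here:

* **Volumetric coefficient.** The commonly printed coefficient
  $\nu/(\mu(1-2\nu))$ has units 1/kPa, inconsistent with the other energy
  terms.  The default is the standard Lamé combination
  $\kappa_{vol} = \mu\nu/(1-2\nu)$; the literal form is available via
  `material$vol_coeff_literal = TRUE`.
* **Matrix-term invariant.** With an isochoric $\bar I_1$ in the matrix
  term, the $-\mu\log J_e$ term leaves a spurious pressure $-\mu$ at
  $F_e = I$.  The default evaluates the matrix term with the full $I_1$ so
  the unloaded state is exactly stress-free (a property the model asserts
  and the tests enforce); the all-isochoric variant is
  `material$isochoric_matrix = TRUE`, and the fiber term keeps isochoric
  invariants in either case.
* **2D growth** is in-plane, $F_g = (1+\alpha)I_2$ with unit out-of-plane
  stretch: the cross-section model cannot observe axial growth.
* **Branching multiplicity**: 2 children per node in 2D (symmetric
  $\pm\gamma_k/2$ about the parent, reading the single tabulated angle as
  the full opening angle), 3 in 3D (one per listed azimuth).  Stochasticity
  multiplies lengths and angles by $(1 + 0.1\,\mathcal N(0,1))$; 8 trees
  per cross-section, anchors equally spaced.  Trees are clipped at
  mid-wall rather than rejected; segment–element tagging is endpoint- and
  boundary-inclusive (ties tag all touching elements, conservative
  nourishment).
* **Seed**: $\phi = 1$ on nodes within radius $2h$ of the mid-wall point at
  the occlusion arc (shape and size are not prescribed by the model
  statement).
* **Pseudo-time**: $\Delta t = 0.05$, $t_{end} = 20$ by default, with the
  advective Courant cap $R_s \Delta t / h \le 0.5$ respected by the 1D
  fixtures.  No SUPG-type stabilization is added; the advection velocity
  $R_s$ is small.
* **Exponent clipping** at 50 in the fiber energy prevents overflow for
  pathologically large stretches; beyond the clip the fiber stress is
  frozen.

# Stenosis metric

`stenosis_series()` reports
$100\,(1 - A(t)/A_{ref})$ where $A$ is the shoelace area of the deformed
inner-boundary polygon (mid-plane ring in 3D) and $A_{ref}$ is the area of
the **growth-free pressurized reference state** solved once before the time
loop.  Measuring against the healthy pressurized vessel — rather than the
unloaded mesh — isolates disease-induced narrowing from the elastic
pressure dilation, which at these parameters (soft $\mu = 10$ kPa wall
under 3.3 kPa) reaches tens of percent and would otherwise swamp the
growth signal.  Stenosis is 0 at $t = 0$ by construction, stays 0 under
pure pressurization, and is negative if the lumen dilates further.

# What the synthetic cases do and do not show

The shipped canonical cases (`canned_case()`) re-create the three
cross-section scenarios — isotropic wall without vasa vasorum,
circumferentially fiber-reinforced wall ($\theta_{el} = 0$), and
fiber-reinforced wall with an 8-tree network and one occluded tree — plus a
coarse 3D tube, at desk-scale resolutions ($h = 2.5\,\mu m$ in 2D,
$5\,\mu m$ in 3D, horizons of a few pseudo-time units; the defaults of the
full model are $h = 0.5$, $t_{end} = 20$).  Two consequences of the
*default parameter values themselves* — not of the coarsening — are worth
stating plainly:

* The equilibrium interface width of the phase field is
  $\approx \epsilon/(\sqrt{32}M) \approx 0.018\,\mu m$, far below any
  practical mesh size for a 50-μm vessel.  On such meshes the discrete
  front is pinned by the well term: after the seed's one-off discrete
  relaxation, the $\phi = 0.5$ contour creeps radially (toward scarcity)
  at sub-element amplitude while its circumferential position freezes —
  the radial-dominance *mechanism* is visible, but front propagation at
  speed $R_s$ is only realized on meshes that resolve the interface, as in
  the 1D strip fixture (`interface_speed_case()`, $h = 0.01\,\mu m$),
  where the measured speed matches $R_s$ within a few percent and scales
  linearly in it.
* With $k_g = 0.25$ and $\alpha_{cri} = 10^{-3}$, growth saturates within
  the first default time step at
  $\alpha \le \alpha_{cri} + (1+\alpha_{cri})(e^{k_g\Delta t}-1)
  \approx 0.0127$ — about a 1% linear expansion of the seeded region.  The
  resulting lumen-area changes are of order 0.05% and, under lumen
  pressure, their net sign is a slight *dilation* that is larger for the
  softer fiber-free wall.  The end-time stenosis comparison between the
  three cases therefore does not reproduce the qualitative ordering
  reported for visibly bulging lesions; the corresponding check in the
  test suite is left failing rather than met by altering the default
  constants.
  The lesion stress signature — compressive interior, tensile healthy rim —
  does reproduce robustly.

None of the synthetic geometry emulates patient anatomy: the wall is a
single homogenized layer, residual stresses and the opening angle are
neglected, blood flow is replaced by boundary data, and the vasa-vasorum
trees are parametric fractals, not image-derived vessels.  Passing tests
certify the numerics (oracle equivalence, conservation, convergence orders,
invariances) and the stated mechanisms on these idealized conditions, not
clinical predictive power.

# Numerical edge cases

* Element inversion during a Newton update signals step halving (up to 8
  halvings, then abort with the residual history).
* An under-constrained system (missed rigid-body modes) surfaces as a
  singular-tangent error, not a silent garbage solution.
* $\phi$ is clamped to $[0,1]$ only *inside* constitutive evaluations
  (diffusivity, growth); the field itself is penalty-bounded
  ($K_p = 10^4$).  On meshes that do not resolve the interface the nodal
  extrema overshoot the wells by a few percent — see the discussion above.
* $c < 0$ (possible in starved regions, since the sink is constant) is
  clamped to zero inside the scarcity gate and triggers a starvation
  warning; the linear transport solve itself is left intact.
* The azimuth (fiber direction, anchor placement) is undefined on the
  vessel axis and rejected there; the branch cut lies on the positive
  x-axis, and the occlusion arc coordinate is measured counter-clockwise
  from it along the mid-wall circle.

# A small worked example

A coarse fiber-free cross-section, short horizon (seconds to run):

```{r example, eval = FALSE}
cfg <- canned_case("no_fiber_no_vv", t_end = 0.5)
res <- simulate_artery(cfg)
print(res)
tail(res$series, 3)
```

The problem sizes used throughout the test suite (2D meshes of ~500–2000
elements, a 3D tube of ~2500 hexahedra, 1D strips of 150–300 elements) were
chosen as the coarsest discretizations on which each verified property is
clearly measurable.
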