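# atheroFEM

Finite-element simulation of atherosclerosis as an inflammation-driven
overgrowth of the artery wall triggered by failure of its own
micro-circulation.  The package is aimed at computational biomechanics
researchers who want a small, fully scripted, testable implementation of a
coupled three-field arterial wall model — not at clinical use.

## The model in one paragraph

On a 2D annulus (artery cross-section, plane strain) or a 3D tube, three
nodal fields are solved monolithically per pseudo-time step:

* quasi-static finite-strain mechanics, `div(sigma) = 0`, with
  `F = (I - grad u)^-1 = F_e F_g`, isotropic volumetric growth
  `F_g = (1 + alpha) I`, and a Holzapfel–Gasser–Ogden-type anisotropic
  energy `Psi = mu/2 (I1 - 3) + eta/beta exp(beta [rho <I4b - 1>^2 +
  (1 - rho)(I1b - 3)^2]) + kappa_vol (J_e - 1)^2 - mu log J_e` with
  tension-only helical collagen fibers;
* steady nutrient diffusion–reaction, `div(D grad c) = R_c`, with
  `D = phi D_min + (1 - phi) D_max`, fed by the lumen (`c = c_max` on the
  inner surface) and by a stochastic fractal **vasa-vasorum** network whose
  cut elements also carry `c = c_max`;
* an Allen–Cahn phase field `phi` (0 healthy, 1 inflamed),
  `phi_t = -M f'(phi) + eps^2 lap(phi) + S`, with double well
  `f = 16 M phi^2 (1 - phi)^2` and the scarcity-gated advective source
  `S = R_s H(c - c_cri) (grad phi . grad c)/max(|grad c|, delta_g)`
  (`H = 1` at or below the critical concentration).

Growth follows the inflammation: `alpha_dot/(1 + alpha) =
k_g H(alpha - alpha_cri) phi`, frozen once `alpha` crosses its cap.  The
disease trigger is the occlusion of the vasa-vasorum tree nearest a
prescribed arc position, plus a small inflamed seed there.

Elements are bilinear quads / trilinear hexes with 4 / 5 dofs per node and
`alpha` stored per Gauss point; the consistent tangent of the monolithic
Newton solver comes from complex-step differentiation of the templated C++
element residual, and the lumen pressure is a follower load on the deformed
inner surface.

## A worked example

A coarse fiber-free cross-section with the default material constants
(lumen diameter 50 um, wall 15 um, shear modulus 10 kPa, lumen pressure
3.3 kPa = 25 mmHg), short horizon:

```r
library(atheroFEM)
cfg <- canned_case("no_fiber_no_vv", t_end = 0.5)
res <- simulate_artery(cfg)
print(res)
#> sim_result: 2D artery, 492 elements, 11 recorded steps
#>   pseudo-time 0 .. 0.5; reference lumen area 4561.8 um^2
#>   final stenosis -0.05132%, max phi 1.03, min c 0.893
tail(res$series, 3)
#>    time lumen_area_um2 stenosis_pct  min_c max_phi max_p1_kPa
#> 9  0.40           4564     -0.05075 0.8925   1.028      14.75
#> 10 0.45           4564     -0.05106 0.8925   1.028      14.75
#> 11 0.50           4564     -0.05132 0.8925   1.028      14.76
```

Reading the numbers: the healthy pressurized reference lumen area is
4561.8 um^2 (the soft wall dilates substantially from the unloaded
`pi * 25^2 = 1963` um^2 under 3.3 kPa — stenosis is measured against the
pressurized state, so it starts at 0).  The inflamed seed drives the growth
variable to its cap within the first step; the resulting ~1% expansion of
the small mid-wall lesion changes the lumen by only ~0.05% (here a slight
dilation, hence the negative sign).  `min_c` is the steady nutrient minimum
at the outer wall, `max_phi` the phase-field maximum (slightly above the
well because the model's equilibrium interface width, ~0.02 um, is far
below mesh resolution), and `max_p1` the largest principal wall stress in kPa —
tensile in the healthy rim around the compressed lesion core.

`plot_stenosis()`, `write_series_csv()` and `write_vtu_state()` export the
comparison plot, the scalar series and ParaView snapshots;
`inst/cli/atherofem.R` wraps the same functions as a shell tool
(`run`, `mesh`, `vv`, `post` subcommands).  See the vignette
(`vignettes/atherosclerosis-model.Rmd`) for the full model description,
parameter table and numerical choices.

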