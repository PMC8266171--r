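#' Macaulay bracket (tension-only ramp)
#'
#' Returns `x` where `x >= 0` and `0` elsewhere.  Used to switch the collagen
#' fiber energy off under compression and in the phase-field boundedness
#' penalty.
#'
#' @param x numeric vector.
#' @return `pmax(x, 0)` with the convention `macaulay(0) == 0`.
#' @export
macaulay <- function(x) pmax(x, 0)

#' Inverted Heaviside gate
#'
#' Steps *down* at the critical value: returns 1 where `x <= x_cri` and 0
#' above.  This at-or-below-threshold convention gates both the inflammation
#' source (active under nutrient scarcity) and the growth law (active until
#' the growth variable reaches its cap).
#'
#' @param x numeric vector.
#' @param x_cri critical value (boundary inclusive).
#' @return 0/1 vector.
#' @export
heaviside <- function(x, x_cri) as.numeric(x <= x_cri)

#' Helical collagen fiber direction
#'
#' Unit tangent of a helix wound along the vessel axis:
#' `n = c(-cos(theta_el) sin(theta_az), cos(theta_el) cos(theta_az),
#' sin(theta_el))`.
#'
#' @param theta_az azimuth angle of the material point about the axis.
#' @param theta_el constant helix elevation angle (a material parameter;
#'   0 gives in-plane circumferential fibers, pi/2 purely axial ones).
#' @return unit 3-vector.
#' @export
fiber_direction <- function(theta_az, theta_el) {
  c(-cos(theta_el) * sin(theta_az),
    cos(theta_el) * cos(theta_az),
    sin(theta_el))
}

#' Deformation gradient from the spatial displacement gradient
#'
#' In the spatial (deformed-configuration) formulation the deformation
#' gradient is `F = solve(I - grad_u)` with `grad_u` the displacement
#' gradient with respect to current coordinates.
#'
#' @param grad_u d x d spatial displacement gradient.
#' @return d x d deformation gradient.
#' @export
deformation_gradient <- function(grad_u) {
  d <- nrow(grad_u)
  A <- diag(d) - grad_u
  if (abs(det(A)) < 1e-14)
    stop("singular (I - grad_u): element inversion")
  solve(A)
}

#' Elastic invariants of the isochoric right Cauchy-Green tensor
#'
#' @param F_e elastic deformation gradient (3 x 3, or 2 x 2 which is embedded
#'   with unit out-of-plane stretch).
#' @param n_fiber reference fiber unit vector (length 3).
#' @return list with `I1e = tr(Ce_bar)`, `I4e = n . Ce_bar . n` and
#'   `J_e = det(F_e)`, where `Ce_bar = J_e^{-2/3} t(F_e) F_e`.
#' @export
elastic_invariants <- function(F_e, n_fiber) {
  F_e <- embed3(F_e)
  J <- det(F_e)
  if (J <= 0) stop("non-positive det(F_e)")
  Cb <- J^(-2 / 3) * crossprod(F_e)
  list(I1e = sum(diag(Cb)),
       I4e = drop(n_fiber %*% Cb %*% n_fiber),
       J_e = J)
}

embed3 <- function(F) {
  if (nrow(F) == 3) return(F)
  out <- diag(3)
  out[1:2, 1:2] <- F
  out
}

#' Anisotropic hyperelastic free energy of the artery wall
#'
#' Holzapfel-Gasser-Ogden-type energy density (kPa): a neo-Hookean matrix
#' term, an exponential tension-only collagen fiber term with dispersion
#' weight `rho`, and a compressible volumetric term.  By default the matrix
#' term uses the full first invariant and the volumetric coefficient is the
#' Lame combination `mu*nu/(1-2*nu)`, which together make the unloaded state
#' exactly stress-free; both conventions are switchable via the `material`
#' flags `isochoric_matrix` and `vol_coeff_literal` (see the vignette).
#'
#' @param F_e elastic deformation gradient (2 x 2 or 3 x 3).
#' @param n_fiber fiber unit vector (length 3).
#' @param material material section of the configuration.
#' @return energy density in kPa.
#' @export
free_energy <- function(F_e, n_fiber, material) {
  psi_hgo_cpp(embed3(F_e), n_fiber, material)
}

#' Cauchy stress of the artery wall material
#'
#' `sigma = (1/J_e) dPsi/dF_e t(F_e)` with the analytic closed-form
#' derivative of [free_energy()]; symmetric, and exactly zero at `F_e = I`
#' under the default conventions.
#'
#' @inheritParams free_energy
#' @return 3 x 3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(F_e, n_fiber, material) {
  stress_hgo_cpp(embed3(F_e), n_fiber, material)
}

#' Isotropic growth tensor
#'
#' `F_g = (1 + alpha) I`: inflammation-driven volumetric overgrowth
#' characterized by the scalar internal variable `alpha` per Gauss point.
#'
#' @param alpha growth magnitude, `alpha > -1`.
#' @param dim spatial dimension of the tensor (the 2D model grows in-plane
#'   with unit out-of-plane stretch).
#' @return dim x dim growth tensor.
#' @export
growth_tensor <- function(alpha, dim = 3L) {
  if (alpha <= -1) stop("alpha must exceed -1")
  (1 + alpha) * diag(dim)
}

#' Advance the growth internal variable over one time step
#'
#' Integrates `d(alpha)/dt / (1 + alpha) = k_g H(alpha - alpha_cri) phi`
#' exactly over `dt` with the Heaviside gate lagged at the old value (the
#' inverted convention of [heaviside()]: growth is active while
#' `alpha <= alpha_cri` and ceases once the cap is crossed):
#' `alpha_new = (1 + alpha) * exp(k_g * phi * dt) - 1` while active.
#'
#' @param alpha current growth variable (vector ok), `>= 0`.
#' @param phi inflammation phase field at the same points; clamped to [0,1].
#' @param dt time step.
#' @param growth growth section of the configuration (`k_g`, `alpha_cri`).
#' @return updated alpha.
#' @export
update_alpha <- function(alpha, phi, dt, growth) {
  phi <- pmin(pmax(phi, 0), 1)
  active <- alpha <= growth$alpha_cri
  out <- alpha
  out[active] <- (1 + alpha[active]) * exp(growth$k_g * phi[active] * dt) - 1
  out
}
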