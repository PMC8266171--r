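#' Double-well potential of the inflammation phase field
#'
#' `f(phi) = 16*M*phi^2*(1-phi)^2`: wells at the healthy (`phi = 0`) and
#' inflamed (`phi = 1`) states and a barrier of height `f(1/2) = M` between
#' them.
#'
#' @param phi phase field value(s).
#' @param M barrier scale.
#' @return potential value(s).
#' @export
double_well <- function(phi, M) 16 * M * phi^2 * (1 - phi)^2

#' Derivative of the double-well potential
#'
#' `f'(phi) = 32*M*phi*(1-phi)*(1-2*phi)`; positive on (0, 1/2), negative on
#' (1/2, 1), zero at both wells and at the barrier top.
#'
#' @inheritParams double_well
#' @return derivative value(s).
#' @export
double_well_prime <- function(phi, M) 32 * M * phi * (1 - phi) * (1 - 2 * phi)

#' Nutrient-scarcity source term of the phase-field equation
#'
#' The driver of lesion progression: an advection-like term that moves the
#' inflammation interface along the nutrient gradient direction,
#' `S = R_s * H(c - c_cri) * (grad_phi . grad_c) / max(|grad_c|, delta_g)`,
#' active only where the nutrient has dropped to its critical value
#' (inverted Heaviside, boundary inclusive).  `c` is clamped at zero before
#' the gate so starved (negative-concentration) regions count as scarce.
#'
#' @param grad_phi phase-field gradient at the evaluation point (length dim).
#' @param grad_c nutrient gradient at the same point.
#' @param c nutrient concentration at the same point.
#' @param phasefield phase-field section of the configuration (`R_s`,
#'   `delta_g`).
#' @param c_cri critical nutrient concentration.
#' @return scalar source value (1/time).
#' @export
source_term <- function(grad_phi, grad_c, c, phasefield, c_cri) {
  H <- heaviside(max(c, 0), c_cri)
  gnorm <- max(sqrt(sum(grad_c^2)), phasefield$delta_g)
  phasefield$R_s * H * sum(grad_phi * grad_c) / gnorm
}

#' Derivative of the phase-field boundedness penalty
#'
#' Penalty `P(phi) = <phi-1>^2 + <-phi>^2` keeps `phi` in [0,1]; its
#' derivative `P'(phi) = 2<phi-1> - 2<-phi>` vanishes inside the bounds and
#' pulls back linearly outside.  Multiplied by the penalty factor `K_p` in
#' the weak form.
#'
#' @param phi phase field value(s).
#' @return derivative value(s).
#' @export
penalty_prime <- function(phi) 2 * macaulay(phi - 1) - 2 * macaulay(-phi)
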