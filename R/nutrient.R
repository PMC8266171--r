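#' Inflammation-dependent nutrient diffusivity
#'
#' Linear interpolation between the healthy and inflamed tissue
#' diffusivities: `D = phi*D_min + (1-phi)*D_max`, with `phi` clamped to
#' [0,1] first.
#'
#' @param phi inflammation phase field value(s).
#' @param nutrient nutrient section of the configuration (`D_max`, `D_min`).
#' @return diffusivity in um^2/time.
#' @export
diffusivity <- function(phi, nutrient) {
  phi <- pmin(pmax(phi, 0), 1)
  phi * nutrient$D_min + (1 - phi) * nutrient$D_max
}

#' Solve the steady nutrient transport problem on a fixed geometry
#'
#' Linear FEM solve of the steady diffusion-reaction equation
#' `div(D grad c) - R_c = 0` with Dirichlet data `c = c_max` on the given
#' node set and zero flux elsewhere, at frozen displacement and phase field.
#' This is the nutrient block of the monolithic system in isolation; being
#' linear it converges in a single Newton iteration.
#'
#' @param mesh a `fem_mesh`.
#' @param config full configuration list.
#' @param dirichlet_nodes node indices receiving `c = c_max` (defaults to the
#'   inner surface).
#' @param u optional nodal displacement (n x dim); solves on the deformed
#'   configuration.
#' @param phi optional nodal phase field entering the diffusivity.
#' @return numeric vector of nodal concentrations.
#' @export
solve_nutrient <- function(mesh, config, dirichlet_nodes = NULL,
                           u = NULL, phi = NULL) {
  n <- nrow(mesh$nodes)
  if (is.null(dirichlet_nodes)) {
    dirichlet_nodes <- sort(unique(as.vector(mesh$facets$inner_surface$nodes)))
  }
  state <- new_field_state(mesh, config)
  if (!is.null(u)) state$u <- u
  if (!is.null(phi)) state$phi <- phi
  state$c <- rep(0, n)
  bc <- list(dirichlet = data.frame(
    node = dirichlet_nodes, field = "c",
    value = config$nutrient$c_max))
  st <- newton_solve(state, mesh, config, bc,
                     active_fields = "c", p_now = 0, state_prev = state)
  st$state$c
}
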