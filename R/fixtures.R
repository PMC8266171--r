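#' Analytic radial solution of the annulus reaction-diffusion problem
#'
#' Closed form of `D (c'' + c'/r) = R_c` for radii between `r_in` and
#' `r_out` with
#' `c(r_in) = c_max` and zero flux at `r_out`:
#' `c(r) = c_max + (R_c/D) * ((r^2 - r_in^2)/4 - (r_out^2/2) log(r/r_in))`.
#'
#' @param r radius (vector ok).
#' @param r_in,r_out annulus radii.
#' @param D diffusivity; `R_c` consumption; `c_max` inner Dirichlet value.
#' @param R_c,c_max see above.
#' @return concentration at `r`.
#' @export
annulus_diffusion_exact <- function(r, r_in, r_out, D, R_c, c_max) {
  c_max + (R_c / D) * ((r^2 - r_in^2) / 4 - (r_out^2 / 2) * log(r / r_in))
}

#' Analytic 1D slab solution of the reaction-diffusion problem
#'
#' `D c'' = R_c` on `[0, L]` with `c(0) = c_max` and zero flux at `L`:
#' `c(x) = c_max - (R_c/(2 D)) (2 L x - x^2)`.
#'
#' @param x position; `L` slab length; other parameters as in
#'   [annulus_diffusion_exact()].
#' @param L,D,R_c,c_max see above.
#' @return concentration at `x`.
#' @export
slab_diffusion_exact <- function(x, L, D, R_c, c_max) {
  c_max - (R_c / (2 * D)) * (2 * L * x - x^2)
}

#' Lame thick-walled cylinder solution (plane strain, internal pressure)
#'
#' Linear-elastic radial displacement of a cylinder `a <= r <= b` under
#' internal pressure `p`:
#' `u(r) = (1+nu) p a^2 / (E (b^2 - a^2)) * ((1-2 nu) r + b^2 / r)` with
#' `E = 2 mu (1 + nu)`.
#'
#' @param r radius; `a`,`b` inner/outer radii; `p` pressure (kPa);
#'   `mu` shear modulus (kPa); `nu` Poisson ratio.
#' @param a,b,p,mu,nu see above.
#' @return radial displacement (um).
#' @export
lame_cylinder_exact <- function(r, a, b, p, mu, nu) {
  E <- 2 * mu * (1 + nu)
  (1 + nu) * p * a^2 / (E * (b^2 - a^2)) * ((1 - 2 * nu) * r + b^2 / r)
}

#' Annulus reaction-diffusion oracle fixture
#'
#' Mesh, configuration and exact solution for verifying the nutrient block
#' against [annulus_diffusion_exact()].
#'
#' @param h mesh size (um).
#' @return list with `mesh`, `config`, and `exact(r)` closure.
#' @export
manufactured_diffusion_case <- function(h = 2.5) {
  config <- default_config(2)
  config$geometry$h <- h
  config$solver$p_max <- 0
  config$solver$seed_phase <- FALSE
  mesh <- make_annulus_mesh(config$geometry)
  n <- config$nutrient
  exact <- function(r) annulus_diffusion_exact(r, mesh$r_in, mesh$r_out,
                                               n$D_max, n$R_c, n$c_max)
  list(mesh = mesh, config = config, exact = exact)
}

#' 1D interface-advection fixture
#'
#' A long thin strip of quads with the phase field as the only active
#' unknown: the nutrient is frozen to a prescribed linear profile below the
#' critical concentration so the scarcity gate is open everywhere and the
#' source term advects the interface at speed `R_s` along the strip.  The
#' strip is fine enough (`h`) to resolve the equilibrium interface width
#' `~ eps/(sqrt(32) M)` so the discrete front actually translates instead of
#' pinning to the grid.
#'
#' @param R_s inflammation rate to test.
#' @param length strip length (um).
#' @param h element size along the strip (um).
#' @param t_end simulated pseudo-time.
#' @param dt time step (kept within the advective Courant limit
#'   `R_s dt / h <= 0.5`).
#' @return list with `mesh`, `config`, initial nodal `phi` and `c`, and
#'   `front(phi_nodal)` returning the interpolated front position.
#' @export
interface_speed_case <- function(R_s = 0.1, length = 1.5, h = 0.01,
                                 t_end = 4, dt = NULL) {
  if (is.null(dt)) dt <- 0.4 * h / max(R_s, 1e-12)
  mesh <- strip_mesh(length, h)
  nx <- mesh$n_c
  nodes <- mesh$nodes
  config <- default_config(2)
  config$geometry$h <- h
  config$phasefield$R_s <- R_s
  config$solver <- utils::modifyList(config$solver, list(
    dt = dt, t_end = t_end, p_max = 0, active_fields = "phi",
    seed_phase = FALSE))
  # nutrient: linear decrease along x, everywhere below critical
  c0 <- 0.9 * config$nutrient$c_cri - 0.05 * nodes[, 1]
  # phase: front at x0 = length/3 with the equilibrium tanh-like width
  kw <- sqrt(32) * config$phasefield$M / config$phasefield$eps
  phi0 <- 1 / (1 + exp(kw * (nodes[, 1] - length / 3)))
  front <- function(phi_nodal) {
    row <- 1:(nx + 1L)
    crossings(nodes[row, 1], phi_nodal[row])[1]
  }
  list(mesh = mesh, config = config, phi0 = phi0, c0 = c0, front = front)
}

#' Measure the 1D inflammation front speed
#'
#' Runs the [interface_speed_case()] strip with the phase field as the only
#' unknown and fits the front position against time by least squares.
#'
#' @param case fixture from [interface_speed_case()].
#' @return list with `speed` (um/time), `positions`, `times`.
#' @export
measure_front_speed <- function(case) {
  mesh <- case$mesh
  config <- case$config
  state <- new_field_state(mesh, config)
  state$c <- case$c0
  state$phi <- case$phi0
  bc <- list(dirichlet = data.frame(node = integer(0), field = character(0),
                                    comp = integer(0), value = numeric(0)),
             pressure = NULL)
  s <- config$solver
  nsteps <- ceiling(s$t_end / s$dt)
  times <- numeric(nsteps + 1L)
  pos <- numeric(nsteps + 1L)
  pos[1] <- case$front(state$phi)
  for (k in seq_len(nsteps)) {
    state$lag <- compute_lag(state, mesh, config)
    ns <- newton_solve(state, mesh, config, bc, active_fields = "phi",
                       p_now = 0, state_prev = state, dt = s$dt)
    if (!ns$converged) stop("front-speed run failed to converge")
    state <- ns$state
    state$lag <- NULL
    times[k + 1L] <- k * s$dt
    pos[k + 1L] <- case$front(state$phi)
  }
  # discard the initial transient (first quarter)
  keep <- times >= s$t_end / 4
  fit <- stats::lm(pos[keep] ~ times[keep])
  list(speed = abs(unname(stats::coef(fit)[2])), positions = pos,
       times = times)
}

#' Ready-to-run configurations of the canonical simulation cases
#'
#' The three 2D scenarios (matrix-only wall without nourishing microvessels;
#' circumferentially fiber-reinforced wall; fiber-reinforced wall with a
#' vasa-vasorum network and one occluded tree) plus a coarse 3D tube.  The
#' shipped resolutions and horizons are desk-scale; pass `h`/`t_end`
#' overrides for finer studies.
#'
#' @param name one of `"no_fiber_no_vv"`, `"fiber_no_vv"`, `"fiber_vv"`,
#'   `"tube3d_coarse"`.
#' @param h mesh size override (um).
#' @param t_end pseudo-time horizon override.
#' @param seed RNG seed for the vasa-vasorum network.
#' @return a full configuration list.
#' @export
canned_case <- function(name = c("no_fiber_no_vv", "fiber_no_vv", "fiber_vv",
                                 "tube3d_coarse"),
                        h = NULL, t_end = NULL, seed = 1L) {
  name <- match.arg(name)
  dim <- if (name == "tube3d_coarse") 3L else 2L
  config <- default_config(dim)
  config$geometry$h <- if (!is.null(h)) h else if (dim == 2L) 2.5 else 5
  config$solver$t_end <- if (!is.null(t_end)) t_end else 2
  config$solver$seed <- as.integer(seed)
  switch(name,
    no_fiber_no_vv = {
      config$material$eta <- 0
    },
    fiber_no_vv = {
      config$material$theta_el <- 0 # in-plane circumferential fibers
    },
    fiber_vv = {
      config$material$theta_el <- 0
      config$vasa_vasorum$enabled <- TRUE
    },
    tube3d_coarse = {
      config$vasa_vasorum$enabled <- TRUE
      config$solver$t_end <- if (!is.null(t_end)) t_end else 0.5
    })
  config
}

# one-element-wide strip of quads along x (internal 1D reduction helper)
strip_mesh <- function(length, h, width = h) {
  nx <- as.integer(round(length / h))
  xs <- seq(0, length, length.out = nx + 1L)
  nodes <- cbind(x = rep(xs, 2), y = rep(c(0, width), each = nx + 1L))
  elems <- cbind(1:nx, 2:(nx + 1L), (nx + 1L) + 2:(nx + 1L),
                 (nx + 1L) + 1:nx)
  structure(list(
    nodes = nodes, elems = elems, dim = 2L,
    facets = list(), n_r = 1L, n_c = nx, n_z = 0L,
    r_in = NA, r_out = NA, h = h, inner_ring = NULL, outer_ring = NULL
  ), class = "fem_mesh")
}
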