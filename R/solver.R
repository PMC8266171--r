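#' @importFrom Matrix sparseMatrix solve
NULL

n_gp <- function(mesh) if (mesh$dim == 2L) 4L else 8L

#' Create an initial field state
#'
#' Nodal displacement zero, nutrient at `c_max`, phase field zero, growth
#' variable zero at every Gauss point.
#'
#' @param mesh a `fem_mesh`.
#' @param config full configuration list.
#' @return a `field_state` list with elements `u`, `c`, `phi`, `alpha`,
#'   `time`.
#' @export
new_field_state <- function(mesh, config) {
  n <- nrow(mesh$nodes)
  structure(list(
    u     = matrix(0, n, mesh$dim),
    c     = rep(config$nutrient$c_max, n),
    phi   = rep(0, n),
    alpha = matrix(0, nrow(mesh$elems), n_gp(mesh)),
    time  = 0
  ), class = "field_state")
}

pack_dofs <- function(state, dim) {
  ndpn <- dim + 2L
  n <- nrow(state$u)
  dofs <- numeric(n * ndpn)
  for (i in seq_len(dim)) dofs[seq(i, by = ndpn, length.out = n)] <- state$u[, i]
  dofs[seq(dim + 1L, by = ndpn, length.out = n)] <- state$c
  dofs[seq(dim + 2L, by = ndpn, length.out = n)] <- state$phi
  dofs
}

unpack_dofs <- function(dofs, state, dim) {
  ndpn <- dim + 2L
  n <- nrow(state$u)
  for (i in seq_len(dim)) state$u[, i] <- dofs[seq(i, by = ndpn, length.out = n)]
  state$c <- dofs[seq(dim + 1L, by = ndpn, length.out = n)]
  state$phi <- dofs[seq(dim + 2L, by = ndpn, length.out = n)]
  state
}

dirichlet_indices <- function(dirichlet, dim) {
  ndpn <- dim + 2L
  comp <- integer(nrow(dirichlet))
  comp[dirichlet$field == "u"] <- dirichlet$comp[dirichlet$field == "u"]
  comp[dirichlet$field == "c"] <- dim + 1L
  comp[dirichlet$field == "phi"] <- dim + 2L
  (dirichlet$node - 1L) * ndpn + comp
}

#' Resolve boundary conditions for the artery problem
#'
#' Inner surface: follower pressure (applied on the deformed surface) and
#' maximum-nutrient Dirichlet data; vasa-vasorum-cut element nodes: the same
#' nutrient Dirichlet data (minus the occluded tree); phase field: natural
#' zero flux everywhere; displacement: minimal point constraints removing
#' rigid-body modes only, leaving radial motion and (in 3D) axial freedom
#' unconstrained.
#'
#' @param mesh a `fem_mesh`.
#' @param config full configuration list.
#' @param vv_nodes optional node indices of vasa-vasorum-nourished elements.
#' @return list with `dirichlet` (data frame `node`, `field`, `comp`,
#'   `value`) and `pressure` (inner-surface facet table).
#' @export
boundary_conditions <- function(mesh, config, vv_nodes = NULL) {
  c_max <- config$nutrient$c_max
  inner_nodes <- sort(unique(as.vector(mesh$facets$inner_surface$nodes)))
  dir <- data.frame(node = inner_nodes, field = "c", comp = 0L, value = c_max)
  if (length(vv_nodes)) {
    vvn <- setdiff(vv_nodes, inner_nodes)
    if (length(vvn))
      dir <- rbind(dir, data.frame(node = vvn, field = "c", comp = 0L,
                                   value = c_max))
  }
  # minimal rigid-body constraints on the reference ring nearest theta = 0,
  # pi/2, pi (outer ring; mid-plane ring in 3D): radial motion stays free
  ring <- mesh$outer_ring
  th <- azimuth_of_point(mesh$nodes[ring, , drop = FALSE])
  pick <- function(target) ring[which.min(abs(th - target))]
  nA <- pick(0); nB <- pick(pi); nC <- pick(pi / 2)
  ucon <- data.frame(node = c(nA, nB, nC), field = "u",
                     comp = c(2L, 2L, 1L), value = 0)
  if (mesh$dim == 3L) {
    ucon <- rbind(ucon, data.frame(node = c(nA, nB, nC), field = "u",
                                   comp = 3L, value = 0))
  }
  dir <- rbind(dir, ucon)
  list(dirichlet = dir, pressure = mesh$facets$inner_surface)
}

# Lagged per-Gauss-point quantities for the phase-field source, frozen from
# the previous converged state: the scarcity gate H(c - c_cri) (with c
# clamped at zero) and the floored nutrient gradient direction.
compute_lag <- function(state, mesh, config) {
  dofs <- pack_dofs(state, mesh$dim)
  gp <- fem_gp_fields(mesh$nodes, mesh$elems - 1L, mesh$dim, dofs)
  H <- matrix(heaviside(pmax(gp$c_gp, 0), config$nutrient$c_cri),
              nrow(gp$c_gp), ncol(gp$c_gp))
  d <- mesh$dim
  ngp <- ncol(gp$c_gp)
  gnorm <- matrix(0, nrow(H), ngp)
  for (i in seq_len(d)) gnorm <- gnorm + gp$gradc[, (0:(ngp - 1)) * d + i]^2
  gnorm <- sqrt(gnorm)
  denom <- pmax(gnorm, config$phasefield$delta_g)
  ghat <- gp$gradc
  for (i in seq_len(d)) {
    cols <- (0:(ngp - 1)) * d + i
    ghat[, cols] <- gp$gradc[, cols] / denom
  }
  list(H = H, ghat = ghat, phi_gp = gp$phi_gp, c_gp = gp$c_gp)
}

assemble_full <- function(dofs, mesh, config, bc, state_n, dt, p_now,
                          want_tangent) {
  par <- config
  par$solver$dt <- dt
  out <- fem_assemble(mesh$nodes, mesh$elems - 1L, mesh$dim, dofs,
                      state_n$phi, state_n$alpha, state_n$lag$H,
                      state_n$lag$ghat, par, want_tangent)
  if (!out$ok) return(list(ok = FALSE))
  res <- out$res
  ti <- out$i; tj <- out$j; tx <- out$x
  if (p_now != 0) {
    pr <- fem_assemble_pressure(mesh$nodes, mesh$dim, dofs,
                                bc$pressure$nodes - 1L, bc$pressure$orient,
                                p_now, want_tangent)
    res <- res + pr$res
    if (want_tangent) {
      ti <- c(ti, pr$i); tj <- c(tj, pr$j); tx <- c(tx, pr$x)
    }
  }
  list(ok = TRUE, res = res, i = ti, j = tj, x = tx)
}

#' Monolithic Newton solve of the coupled three-field system
#'
#' Newton-Raphson iteration on the block residual `[u | c | phi]` with the
#' consistent tangent of all implemented terms (the lagged scarcity gate,
#' nutrient-gradient direction and growth variable contribute none by
#' construction).  Convergence is declared when the Euclidean norm of the
#' residual restricted to free dofs falls below `newton_tol` (absolute, on
#' the `K_c`/`K_phi`-scaled system).
#'
#' @param state initial guess `field_state` (its `alpha` is held frozen).
#' @param mesh a `fem_mesh`.
#' @param config full configuration list.
#' @param bc boundary-condition list from [boundary_conditions()].
#' @param active_fields subset of `c("u","c","phi")` actually solved for;
#'   the rest are frozen at their current nodal values.
#' @param p_now current lumen pressure (kPa).
#' @param state_prev converged state of the previous time step (supplies the
#'   lagged quantities and the backward-Euler history).
#' @param dt pseudo-time step; `0` drops the transient phase-field term.
#' @return list with `state`, `converged`, `iterations`, `res_norms`.
#' @export
newton_solve <- function(state, mesh, config, bc,
                         active_fields = c("u", "c", "phi"),
                         p_now = 0, state_prev = state, dt = 0) {
  dim <- mesh$dim
  ndpn <- dim + 2L
  n <- nrow(mesh$nodes)
  ndof <- n * ndpn
  s <- config$solver

  state_n <- state_prev
  if (is.null(state_n$lag)) state_n$lag <- compute_lag(state_n, mesh, config)
  state$alpha <- state_prev$alpha

  dofs <- pack_dofs(state, dim)
  di <- dirichlet_indices(bc$dirichlet, dim)
  dofs[di] <- bc$dirichlet$value

  fixed <- rep(FALSE, ndof)
  fixed[di] <- TRUE
  field_of_dof <- rep(c(rep("u", dim), "c", "phi"), n)
  fixed[!(field_of_dof %in% active_fields)] <- TRUE
  free <- which(!fixed)

  res_norms <- numeric(0)
  for (it in seq_len(s$newton_max_iter + 1L)) {
    sys <- assemble_full(dofs, mesh, config, bc, state_n, dt, p_now,
                         want_tangent = TRUE)
    if (!sys$ok)
      return(list(state = unpack_dofs(dofs, state, dim), converged = FALSE,
                  iterations = it - 1L, res_norms = res_norms,
                  inverted = TRUE))
    rnorm <- sqrt(sum(sys$res[free]^2))
    res_norms <- c(res_norms, rnorm)
    if (!is.finite(rnorm))
      return(list(state = unpack_dofs(dofs, state, dim), converged = FALSE,
                  iterations = it - 1L, res_norms = res_norms))
    if (rnorm < s$newton_tol) {
      st <- unpack_dofs(dofs, state, dim)
      return(list(state = st, converged = TRUE, iterations = it - 1L,
                  res_norms = res_norms))
    }
    if (it > s$newton_max_iter)
      return(list(state = unpack_dofs(dofs, state, dim), converged = FALSE,
                  iterations = it - 1L, res_norms = res_norms))
    A <- sparseMatrix(i = sys$i + 1L, j = sys$j + 1L, x = sys$x,
                      dims = c(ndof, ndof))
    Aff <- A[free, free, drop = FALSE]
    delta <- tryCatch(
      as.numeric(Matrix::solve(Aff, -sys$res[free])),
      error = function(e)
        stop("singular tangent: system under-constrained ",
             "(unremoved rigid-body modes?): ", conditionMessage(e)))
    dofs[free] <- dofs[free] + delta
  }
}

#' Run the coupled atherosclerosis simulation
#'
#' Full pipeline: mesh generation, vasa-vasorum network generation and
#' element tagging, phase-field seeding at the occlusion site, a growth-free
#' pressurized reference solve (the stenosis baseline), then backward-Euler
#' pseudo-time stepping with a monolithic Newton solve of `[u, c, phi]` per
#' step and a staggered Gauss-point update of the growth variable `alpha`
#' after convergence.  On Newton divergence the step is halved, up to
#' `step_halving_max` times.
#'
#' @param config full configuration list (see [default_config()]); validated
#'   on entry.
#' @param mesh optional pre-built `fem_mesh` (built from `config$geometry`
#'   when omitted).
#' @param quiet suppress progress output.
#' @return a `sim_result`: mesh, configuration, vasa-vasorum trees, recorded
#'   times and `field_state`s, the scalar time series (time, lumen area,
#'   stenosis degree, field extrema, maximum principal stress) and run log.
#' @export
simulate_artery <- function(config, mesh = NULL, quiet = TRUE) {
  validate_config(config)
  g <- config$geometry
  if (is.null(mesh))
    mesh <- if (g$dim == 2L) make_annulus_mesh(g) else make_tube_mesh(g)
  dim <- mesh$dim
  s <- config$solver
  r_mid <- (mesh$r_in + mesh$r_out) / 2

  trees <- NULL
  vv_nodes <- integer(0)
  if (isTRUE(config$vasa_vasorum$enabled)) {
    trees <- generate_vv_network(config, mesh)
    occ <- attr(trees, "occluded")
    keep <- setdiff(seq_along(trees), occ)
    cut <- if (length(keep)) tag_cut_elements(mesh, trees[keep]) else integer(0)
    vv_nodes <- sort(unique(as.vector(mesh$elems[cut, ])))
  }
  bc <- boundary_conditions(mesh, config, vv_nodes)

  state <- new_field_state(mesh, config)
  if (isTRUE(s$seed_phase)) {
    r_seed <- if (is.null(s$seed_radius)) 2 * mesh$h else s$seed_radius
    th_occ <- g$occlusion_arc / r_mid
    ctr <- r_mid * c(cos(th_occ), sin(th_occ))
    if (dim == 3L) ctr <- c(ctr, mesh$length / 2)
    dist <- sqrt(rowSums((mesh$nodes -
                            matrix(ctr, nrow(mesh$nodes), dim,
                                   byrow = TRUE))^2))
    state$phi[dist <= r_seed] <- 1
  }

  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  # nutrient pre-solve so the reference state has a consistent c field
  if ("c" %in% s$active_fields) {
    ns <- newton_solve(state, mesh, config, bc, active_fields = "c",
                       p_now = 0, state_prev = state, dt = 0)
    state <- ns$state
    note("nutrient pre-solve: %d iteration(s)", ns$iterations)
  }

  # growth-free pressurized reference (stenosis baseline), pressure ramped
  if ("u" %in% s$active_fields && s$p_max != 0) {
    n_ramp <- 4L
    for (k in seq_len(n_ramp)) {
      ns <- newton_solve(state, mesh, config, bc, active_fields = "u",
                         p_now = s$p_max * k / n_ramp, state_prev = state,
                         dt = 0)
      if (!ns$converged)
        stop("reference pressurization failed to converge at p = ",
             s$p_max * k / n_ramp, " kPa")
      state <- ns$state
    }
    note("pressurized reference solved (p = %.3g kPa)", s$p_max)
  }

  A_ref <- lumen_area(mesh, state$u)
  times <- state$time <- 0
  states <- list(state)
  newton_iters <- integer(0)
  starved_warned <- FALSE

  t_now <- 0
  step <- 0L
  while (t_now < s$t_end - 1e-12) {
    dt_try <- min(s$dt, s$t_end - t_now)
    halved <- 0L
    state$lag <- compute_lag(state, mesh, config)
    repeat {
      ns <- newton_solve(state, mesh, config, bc,
                         active_fields = s$active_fields,
                         p_now = s$p_max, state_prev = state, dt = dt_try)
      if (ns$converged) break
      halved <- halved + 1L
      if (halved > s$step_halving_max)
        stop("Newton diverged at t = ", t_now, " despite ", halved - 1L,
             " step halvings; last residual norms: ",
             paste(signif(ns$res_norms, 3), collapse = " "))
      dt_try <- dt_try / 2
      note("step halving at t = %.4g (dt -> %.4g)", t_now, dt_try)
    }
    new_state <- ns$state
    # staggered growth update at Gauss points with the converged phase field
    gp_phi <- compute_lag(new_state, mesh, config)$phi_gp
    new_state$alpha <- matrix(
      update_alpha(as.vector(state$alpha), as.vector(gp_phi), dt_try,
                   config$growth),
      nrow(state$alpha), ncol(state$alpha))
    if (!starved_warned && min(new_state$c) < -1e-8) {
      note("starvation: nutrient dropped below zero (min c = %.3g)",
           min(new_state$c))
      warning("nutrient concentration dropped below zero in starved regions")
      starved_warned <- TRUE
    }
    t_now <- t_now + dt_try
    step <- step + 1L
    new_state$time <- t_now
    new_state$lag <- NULL
    state <- new_state
    newton_iters <- c(newton_iters, ns$iterations)
    if (step %% s$save_every == 0L || t_now >= s$t_end - 1e-12) {
      times <- c(times, t_now)
      states[[length(states) + 1L]] <- state
    }
  }

  res <- structure(list(
    mesh = mesh, config = config, trees = trees, vv_nodes = vv_nodes,
    times = times, states = states, lumen_area_ref = A_ref,
    newton_iterations = newton_iters, log = log_lines
  ), class = "sim_result")
  res$series <- stenosis_series(res)
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %dD artery, %d elements, %d recorded steps\n",
              x$mesh$dim, nrow(x$mesh$elems), length(x$times)))
  cat(sprintf("  pseudo-time 0 .. %.4g; reference lumen area %.5g um^2\n",
              max(x$times), x$lumen_area_ref))
  if (!is.null(x$series)) {
    last <- x$series[nrow(x$series), ]
    cat(sprintf("  final stenosis %.4g%%, max phi %.3g, min c %.3g\n",
                last$stenosis_pct, last$max_phi, last$min_c))
  }
  invisible(x)
}
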