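#' Default simulation configuration
#'
#' Returns the full nested configuration with every parameter at its default
#' value: artery geometry, wall material, growth law, nutrient transport,
#' inflammation phase field, vasa-vasorum fractal and solver controls.
#' All values are in micrometres, kilopascals and the dimensionless
#' pseudo-time unit of the growth process.
#'
#' @param dim spatial dimension, 2 (cross-section, plane strain) or 3 (tube).
#' @return a named nested list with sections `geometry`, `material`, `growth`,
#'   `nutrient`, `phasefield`, `vasa_vasorum` and `solver`.
#' @export
default_config <- function(dim = 2) {
  stopifnot(dim %in% c(2L, 3L))
  list(
    geometry = list(
      dim            = as.integer(dim),
      inner_diameter = 50.0,   # lumen diameter D [um]
      wall_thickness = 15.0,   # t [um]
      length         = 100.0,  # axial length L [um], 3D only
      occlusion_arc  = 30.0,   # arc coordinate S of the initial occlusion [um]
      h              = 0.5     # target mesh size [um]
    ),
    material = list(
      mu       = 10.0,   # shear modulus [kPa]
      nu       = 0.49,   # Poisson ratio
      eta      = 100.0,  # fiber stiffness scale [kPa]
      beta     = 1.0,    # fiber exponent
      rho      = 0.5,    # fiber dispersion weight in [0,1]
      theta_el = pi / 3, # fiber helix elevation angle, 60 degrees [rad]
      # Conventions for the two ambiguities in the printed free energy; see
      # the methods vignette.  Defaults restore a stress-free reference state.
      vol_coeff_literal = FALSE, # TRUE: literal nu/(mu(1-2nu)) volumetric coeff
      isochoric_matrix  = FALSE, # TRUE: matrix term uses isochoric I1
      exp_clip = 50.0            # cap on the fiber exponential argument
    ),
    growth = list(
      k_g       = 0.25, # overgrowth rate constant [1/time]
      alpha_cri = 1e-3  # critical growth magnitude (cap)
    ),
    nutrient = list(
      D_max = 1.0,  # diffusivity, healthy tissue [um^2/time]
      D_min = 0.1,  # diffusivity, inflamed tissue [um^2/time]
      R_c   = 1e-3, # uniform consumption rate [ug um^-3 / time]
      c_max = 1.0,  # blood-contact concentration [ug um^-3]
      c_cri = 1.0   # critical concentration gating the inflammation source
    ),
    phasefield = list(
      eps     = 1.0,  # interface coefficient (eps^2 multiplies laplacian)
      M       = 10.0, # double-well barrier scale
      R_s     = 0.1,  # inflammation front advection rate [um/time]
      K_p     = 1e4,  # boundedness penalty factor
      delta_g = 1e-8  # floor on |grad c| in the source term
    ),
    vasa_vasorum = list(
      enabled   = FALSE,
      L0        = 3.0,               # trunk length [um]
      lambda    = c(1.0, 1.0, 1.0),  # length ratios, levels 2..4
      gamma_2d  = c(2, 2, 2) * pi / 3, # full opening angles, levels 2..4 (2D)
      gamma_az  = c(0, 2, 4) * pi / 3, # child azimuths in parent frame (3D)
      gamma_el  = c(1, 1, 1) * pi / 3, # child elevations (3D)
      n_levels  = 4L,                # trunk + branching levels 2..4
      n_trees   = 8L,                # anchors equally spaced on outer circle
      jitter    = 0.1,               # relative sd of randomized lengths/angles
      occlude   = TRUE               # occlude the tree nearest occlusion_arc
    ),
    solver = list(
      K_c       = 1.0,   # nutrient-block scaling
      K_phi     = 1.0,   # phase-field-block scaling
      dt        = 0.05,  # pseudo-time step
      t_end     = 20.0,  # total pseudo-time
      newton_tol      = 1e-6,
      newton_max_iter = 25L,
      step_halving_max = 8L,
      p_max     = 3.3,   # lumen pressure [kPa] (25 mmHg)
      seed      = 1L,    # RNG seed for the vasa-vasorum fractal
      seed_phase = TRUE, # place the phase-field seed at the occlusion site
      seed_radius = NULL, # phase seed radius [um]; default 2*h
      active_fields = c("u", "c", "phi"),
      save_every = 1L    # record every k-th step
    )
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]; any key
#' not present in the file keeps its default.
#'
#' @param path path to a YAML file with (a subset of) the sections of
#'   [default_config()].
#' @return a full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  dim <- if (!is.null(user$geometry$dim)) user$geometry$dim else 2L
  merge_config(default_config(dim), user)
}

#' Merge configuration overrides over a base configuration
#'
#' @param base full configuration list.
#' @param overrides nested list of keys to replace.
#' @return merged configuration.
#' @export
merge_config <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Validate a configuration
#'
#' Checks positivity and admissibility constraints on every parameter group
#' and the mesh-resolution requirement h < wall_thickness/3 (at least three
#' element layers through the wall).
#'
#' @param config configuration list as from [default_config()].
#' @return the configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  g <- config$geometry
  stopifnot(g$dim %in% c(2L, 3L))
  if (any(c(g$inner_diameter, g$wall_thickness, g$h) <= 0))
    stop("geometry: inner_diameter, wall_thickness and h must be positive")
  if (g$dim == 3L && g$length <= 0) stop("geometry: length must be positive")
  if (g$h > g$wall_thickness / 3)
    stop("geometry: h too coarse ",
         "(at least 3 element layers through the wall)")
  m <- config$material
  if (m$mu <= 0) stop("material: mu must be positive")
  if (m$nu <= 0 || m$nu >= 0.5) stop("material: nu must lie in (0, 0.5)")
  if (m$eta < 0 || m$beta <= 0) stop("material: eta >= 0 and beta > 0 required")
  if (m$rho < 0 || m$rho > 1) stop("material: rho must lie in [0, 1]")
  gr <- config$growth
  if (gr$k_g < 0 || gr$alpha_cri <= 0)
    stop("growth: k_g >= 0 and alpha_cri > 0 required")
  n <- config$nutrient
  if (!(n$D_max >= n$D_min && n$D_min > 0))
    stop("nutrient: D_max >= D_min > 0 required")
  if (n$R_c < 0 || n$c_max <= 0) stop("nutrient: R_c >= 0 and c_max > 0 required")
  p <- config$phasefield
  if (p$eps <= 0 || p$M <= 0 || p$R_s < 0 || p$K_p < 0 || p$delta_g <= 0)
    stop("phasefield: eps, M, delta_g > 0 and R_s, K_p >= 0 required")
  v <- config$vasa_vasorum
  if (v$L0 <= 0 || any(v$lambda <= 0))
    stop("vasa_vasorum: L0 and all lambda must be positive")
  if (length(v$gamma_az) != length(v$gamma_el))
    stop("vasa_vasorum: gamma_az and gamma_el must have equal length")
  s <- config$solver
  if (s$dt <= 0 || s$newton_tol <= 0 || s$K_c <= 0 || s$K_phi <= 0)
    stop("solver: dt, newton_tol, K_c, K_phi must be positive")
  invisible(config)
}

#' Convert a pressure from mmHg to kPa
#'
#' @param mmHg pressure in millimetres of mercury.
#' @return pressure in kilopascals (1 mmHg = 0.133322 kPa).
#' @export
mmhg_to_kpa <- function(mmHg) mmHg * 0.133322
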