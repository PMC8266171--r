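#' Deformed lumen cross-sectional area
#'
#' Shoelace (signed polygon) area of the deformed inner boundary ring.  In
#' 3D the ring at the mid-plane cross-section is used (where the lesion is
#' seeded and the narrowing is worst).  The ring is stored counter-clockwise
#' so the signed area is positive for a valid (simple) boundary; a
#' self-intersecting boundary means the lesion has closed the lumen and is
#' reported as zero area with a warning.
#'
#' @param mesh a `fem_mesh`.
#' @param u nodal displacement matrix (n x dim), or `NULL` for the
#'   undeformed area.
#' @return lumen area in um^2.
#' @export
lumen_area <- function(mesh, u = NULL) {
  ring <- mesh$inner_ring
  pts <- mesh$nodes[ring, 1:2, drop = FALSE]
  if (!is.null(u)) pts <- pts + u[ring, 1:2, drop = FALSE]
  a <- shoelace_area(pts)
  if (a <= 0) {
    warning("deformed inner boundary is degenerate/self-intersecting; ",
            "reporting full occlusion")
    return(0)
  }
  a
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Per-element principal Cauchy stresses
#'
#' Volume-averaged Cauchy stress per element (from the element's Gauss
#' points) and its ordered eigenvalues.  In 2D the stress is the full 3 x 3
#' plane-strain tensor, so the out-of-plane component participates.
#'
#' @param result a `sim_result`.
#' @param step index into `result$states` (default: last).
#' @return matrix with one row per element: columns `p1 >= p2 >= p3`
#'   (principal stresses, kPa).
#' @export
principal_stresses <- function(result, step = length(result$states)) {
  st <- result$states[[step]]
  mesh <- result$mesh
  sig <- fem_gp_stress(mesh$nodes, mesh$elems - 1L, mesh$dim,
                       pack_dofs(st, mesh$dim), st$alpha,
                       result$config$material)
  t(apply(sig, 1, function(s) {
    S <- matrix(s, 3, 3)
    sort(eigen((S + t(S)) / 2, symmetric = TRUE,
               only.values = TRUE)$values, decreasing = TRUE)
  }))
}

#' Scalar time series of a simulation: stenosis degree and field extrema
#'
#' Stenosis degree is the percentage reduction of lumen area relative to the
#' growth-free pressurized reference configuration:
#' `stenosis_pct = 100 * (1 - lumen_area / lumen_area_ref)`, zero at t = 0
#' and negative if the lumen dilates.
#'
#' @param result a `sim_result`.
#' @return data frame with columns `time`, `lumen_area_um2`, `stenosis_pct`,
#'   `min_c`, `max_phi`, `max_p1_kPa`.
#' @export
stenosis_series <- function(result) {
  rows <- lapply(seq_along(result$states), function(k) {
    st <- result$states[[k]]
    area <- lumen_area(result$mesh, st$u)
    p1 <- max(principal_stresses(result, k)[, 1])
    data.frame(time = result$times[k],
               lumen_area_um2 = area,
               stenosis_pct = 100 * (1 - area / result$lumen_area_ref),
               min_c = min(st$c), max_phi = max(st$phi),
               max_p1_kPa = p1)
  })
  do.call(rbind, rows)
}

#' Plot stenosis degree against pseudo-time for one or several runs
#'
#' @param ... one or more `sim_result` objects (named arguments become curve
#'   labels) or a single named list of them.
#' @param file optional output path (png or svg by extension); default plots
#'   to the active device.
#' @return the combined series data frame, invisibly.
#' @export
plot_stenosis <- function(..., file = NULL) {
  runs <- list(...)
  if (length(runs) == 1L && !inherits(runs[[1]], "sim_result"))
    runs <- runs[[1]]
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  if (!is.null(file)) {
    if (grepl("[.]svg$", file)) grDevices::svg(file)
    else grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  series <- lapply(runs, function(r)
    if (inherits(r, "sim_result")) r$series else r)
  ylim <- range(unlist(lapply(series, function(s) s$stenosis_pct)))
  xlim <- range(unlist(lapply(series, function(s) s$time)))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "pseudo-time", ylab = "stenosis degree [%]",
                 main = "Lumen cross-section reduction")
  for (k in seq_along(series))
    graphics::lines(series[[k]]$time, series[[k]]$stenosis_pct,
                    col = k, lwd = 2)
  graphics::legend("topleft", legend = names(runs), col = seq_along(runs),
                   lwd = 2, bty = "n")
  out <- do.call(rbind, lapply(names(series), function(nm)
    cbind(case = nm, series[[nm]])))
  invisible(out)
}

#' Write the scalar series of a run to CSV
#'
#' @param result a `sim_result`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_series_csv <- function(result, file) {
  utils::write.csv(result$series, file, row.names = FALSE)
  invisible(file)
}

#' Radial and circumferential positions of the inflammation front
#'
#' Locates the `phi = 0.5` crossings of the lesion in physical (deformed)
#' coordinates: radially along the mesh sector column through the seed
#' centre, circumferentially along the node ring nearest the seed radius.
#' Used to quantify whether the front advances dominantly in the radial
#' direction.
#'
#' @param result a `sim_result` from a seeded 2D run.
#' @param step state index.
#' @return list with `radial` (sorted radii of phi = 0.5 crossings along the
#'   seed ray, um) and `circumferential` (sorted arc coordinates of the
#'   crossings along the seed ring, um).
#' @export
front_position <- function(result, step = length(result$states)) {
  mesh <- result$mesh
  stopifnot(mesh$dim == 2L)
  st <- result$states[[step]]
  cfg <- result$config
  r_mid <- (mesh$r_in + mesh$r_out) / 2
  th_occ <- cfg$geometry$occlusion_arc / r_mid
  n_c <- mesh$n_c; n_r <- mesh$n_r
  j_seed <- which.min(abs(2 * pi * (0:(n_c - 1)) / n_c - th_occ)) - 1L
  i_seed <- which.min(abs(seq(mesh$r_in, mesh$r_out,
                              length.out = n_r + 1) - r_mid)) - 1L
  pos <- mesh$nodes + st$u
  # radial ray: nodes of sector column j_seed, rings 0..n_r
  ray <- vapply(0:n_r, function(i) as.integer(node_id_2d(i, j_seed, n_c)),
                integer(1))
  r_ray <- sqrt(pos[ray, 1]^2 + pos[ray, 2]^2)
  radial <- crossings(r_ray, st$phi[ray])
  # circumferential ring: nodes of ring i_seed in theta order centred on seed
  ringj <- ((j_seed + 0:(n_c - 1) - n_c %/% 2) %% n_c)
  ring <- vapply(ringj, function(j) as.integer(node_id_2d(i_seed, j, n_c)),
                 integer(1))
  th <- azimuth_of_point(pos[ring, , drop = FALSE])
  th <- th + 2 * pi * cumsum(c(0, diff(th) < -pi)) # unwrap
  arc <- r_mid * th
  circumferential <- crossings(arc, st$phi[ring])
  list(radial = radial, circumferential = circumferential)
}

# linear-interpolated positions where a sampled field crosses 0.5
crossings <- function(x, v, level = 0.5) {
  s <- v - level
  idx <- which(s[-1] * s[-length(s)] < 0)
  out <- vapply(idx, function(k) {
    x[k] + (x[k + 1] - x[k]) * s[k] / (s[k] - s[k + 1])
  }, numeric(1))
  sort(c(out, x[s == 0]))
}

#' Net radial/circumferential front displacement over a run
#'
#' Compares [front_position()] crossings between an early reference step and
#' the final step, matching each crossing to its nearest counterpart.
#'
#' @param result a seeded 2D `sim_result`.
#' @param ref_step index of the reference step (default 1, i.e. t = 0).
#' @return list `radial`, `circumferential`: maximum absolute displacement
#'   of the matched crossings (um).
#' @export
front_displacement <- function(result, ref_step = 1L) {
  f0 <- front_position(result, ref_step)
  f1 <- front_position(result, length(result$states))
  move <- function(a, b) {
    if (!length(a) || !length(b)) return(0)
    max(vapply(b, function(x) min(abs(x - a)), numeric(1)))
  }
  list(radial = move(f0$radial, f1$radial),
       circumferential = move(f0$circumferential, f1$circumferential))
}

#' Export a recorded state as a VTU snapshot
#'
#' Writes displacement, nutrient and phase field as point data and the
#' Gauss-point-averaged growth variable and maximum principal stress as cell
#' data, on the deformed configuration.
#'
#' @param result a `sim_result`.
#' @param file output path.
#' @param step state index (default: last).
#' @return the file path, invisibly.
#' @export
write_vtu_state <- function(result, file, step = length(result$states)) {
  st <- result$states[[step]]
  p1 <- principal_stresses(result, step)[, 1]
  write_vtu(result$mesh, file,
            point_data = list(u = st$u, c = st$c, phi = st$phi),
            cell_data = list(alpha = rowMeans(st$alpha), max_p1 = p1),
            u = st$u)
}
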