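#' @useDynLib atheroFEM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm setNames
NULL

# -- structured index helpers (0-based ring/sector/layer, 1-based node ids) --
node_id_2d <- function(i, j, n_c) i * n_c + (j %% n_c) + 1L
node_id_3d <- function(i, j, l, n_r, n_c) {
  l * (n_r + 1L) * n_c + i * n_c + (j %% n_c) + 1L
}

#' Build a structured annulus mesh of an artery cross-section
#'
#' Meshes the wall annulus between radii `inner_diameter/2` and
#' `inner_diameter/2 + wall_thickness` with a polar grid of bilinear
#' quadrilaterals (rings x sectors).  The number of radial layers is
#' `ceiling(wall_thickness/h)` and the number of sectors is chosen so the
#' circumferential edge length at mid-wall is close to `h`.
#'
#' @param geometry geometry section of the configuration (see
#'   [default_config()]): `inner_diameter`, `wall_thickness`, `h`.
#' @return an object of class `fem_mesh` with fields `nodes` (n x dim
#'   coordinates, um), `elems` (m x 4 node indices, counter-clockwise),
#'   `dim`, `facets` (tagged boundary facets with parent element and
#'   outward-orientation sign) and structured-grid attributes.
#' @export
make_annulus_mesh <- function(geometry) {
  g <- geometry
  if (any(c(g$inner_diameter, g$wall_thickness, g$h) <= 0))
    stop("all geometry dimensions must be positive")
  if (g$h > g$wall_thickness / 3)
    stop("h too coarse: need at least 3 element layers through the wall")
  r_in  <- g$inner_diameter / 2
  r_out <- r_in + g$wall_thickness
  r_mid <- (r_in + r_out) / 2
  n_r <- as.integer(ceiling(g$wall_thickness / g$h))
  n_c <- max(8L, as.integer(round(2 * pi * r_mid / g$h)))
  radii  <- seq(r_in, r_out, length.out = n_r + 1L)
  thetas <- 2 * pi * (0:(n_c - 1L)) / n_c

  nodes <- cbind(
    x = rep(radii, each = n_c) * cos(rep(thetas, n_r + 1L)),
    y = rep(radii, each = n_c) * sin(rep(thetas, n_r + 1L))
  )
  ij <- expand.grid(j = 0:(n_c - 1L), i = 0:(n_r - 1L))
  # counter-clockwise: inner corner, radially out, then back at next sector
  elems <- cbind(
    node_id_2d(ij$i,      ij$j,      n_c),
    node_id_2d(ij$i + 1L, ij$j,      n_c),
    node_id_2d(ij$i + 1L, ij$j + 1L, n_c),
    node_id_2d(ij$i,      ij$j + 1L, n_c)
  )
  j <- 0:(n_c - 1L)
  inner <- list(nodes = cbind(node_id_2d(0L, j, n_c),
                              node_id_2d(0L, j + 1L, n_c)),
                elem  = 1L + j)
  outer <- list(nodes = cbind(node_id_2d(n_r, j, n_c),
                              node_id_2d(n_r, j + 1L, n_c)),
                elem  = (n_r - 1L) * n_c + 1L + j)
  mesh <- structure(list(
    nodes = nodes, elems = elems, dim = 2L,
    facets = list(inner_surface = inner, outer_surface = outer),
    n_r = n_r, n_c = n_c, n_z = 0L,
    r_in = r_in, r_out = r_out, h = g$h,
    inner_ring = node_id_2d(0L, j, n_c),
    outer_ring = node_id_2d(n_r, j, n_c)
  ), class = "fem_mesh")
  mesh$facets <- lapply(mesh$facets, add_facet_orientation, mesh = mesh)
  mesh
}

#' Build a structured tube mesh of an artery segment
#'
#' Extrudes the annulus cross-section of [make_annulus_mesh()] along the
#' z-axis into 8-node trilinear hexahedra.  The number of axial layers is
#' `round(length/h)`.
#'
#' @param geometry geometry section of the configuration; uses `length` in
#'   addition to the annulus parameters.
#' @return a `fem_mesh` with `dim = 3` and facet tags `inner_surface`,
#'   `outer_surface`, `axial_end_minus` (z = 0), `axial_end_plus` (z = L).
#' @export
make_tube_mesh <- function(geometry) {
  if (is.null(geometry$length) || geometry$length <= 0)
    stop("length must be positive for a 3D tube")
  ann <- make_annulus_mesh(geometry)
  n_r <- ann$n_r; n_c <- ann$n_c
  n_z <- max(1L, as.integer(round(geometry$length / geometry$h)))
  zs <- seq(0, geometry$length, length.out = n_z + 1L)
  n2 <- nrow(ann$nodes)
  nodes <- cbind(
    x = rep(ann$nodes[, 1], n_z + 1L),
    y = rep(ann$nodes[, 2], n_z + 1L),
    z = rep(zs, each = n2)
  )
  ijl <- expand.grid(j = 0:(n_c - 1L), i = 0:(n_r - 1L), l = 0:(n_z - 1L))
  bot <- function(i, j, l) node_id_3d(i, j, l, n_r, n_c)
  elems <- cbind(
    bot(ijl$i,      ijl$j,      ijl$l),      bot(ijl$i + 1L, ijl$j,      ijl$l),
    bot(ijl$i + 1L, ijl$j + 1L, ijl$l),      bot(ijl$i,      ijl$j + 1L, ijl$l),
    bot(ijl$i,      ijl$j,      ijl$l + 1L), bot(ijl$i + 1L, ijl$j,      ijl$l + 1L),
    bot(ijl$i + 1L, ijl$j + 1L, ijl$l + 1L), bot(ijl$i,      ijl$j + 1L, ijl$l + 1L)
  )
  elem_id <- function(i, j, l) l * n_r * n_c + i * n_c + (j %% n_c) + 1L
  jl <- expand.grid(j = 0:(n_c - 1L), l = 0:(n_z - 1L))
  lateral <- function(i_ring, i_elem) list(
    nodes = cbind(bot(i_ring, jl$j, jl$l),      bot(i_ring, jl$j + 1L, jl$l),
                  bot(i_ring, jl$j + 1L, jl$l + 1L), bot(i_ring, jl$j, jl$l + 1L)),
    elem  = elem_id(i_elem, jl$j, jl$l)
  )
  ij <- expand.grid(j = 0:(n_c - 1L), i = 0:(n_r - 1L))
  cap <- function(l_node, l_elem) list(
    nodes = cbind(bot(ij$i, ij$j, l_node),      bot(ij$i, ij$j + 1L, l_node),
                  bot(ij$i + 1L, ij$j + 1L, l_node), bot(ij$i + 1L, ij$j, l_node)),
    elem  = elem_id(ij$i, ij$j, l_elem)
  )
  mesh <- structure(list(
    nodes = nodes, elems = elems, dim = 3L,
    facets = list(
      inner_surface   = lateral(0L, 0L),
      outer_surface   = lateral(n_r, n_r - 1L),
      axial_end_minus = cap(0L, 0L),
      axial_end_plus  = cap(n_z, n_z - 1L)
    ),
    n_r = n_r, n_c = n_c, n_z = n_z,
    r_in = ann$r_in, r_out = ann$r_out, h = geometry$h,
    length = geometry$length,
    inner_ring = node_id_3d(0L, 0:(n_c - 1L), as.integer(round(n_z / 2)),
                            n_r, n_c),
    outer_ring = node_id_3d(n_r, 0:(n_c - 1L), as.integer(round(n_z / 2)),
                            n_r, n_c)
  ), class = "fem_mesh")
  mesh$facets <- lapply(mesh$facets, add_facet_orientation, mesh = mesh)
  mesh
}

# Orientation sign per facet so that sign * (conventional normal) points out
# of the domain.  2D convention: edge a->b has normal (t_y, -t_x); 3D quad
# a,b,c,d has normal cross(b-a, d-a).
add_facet_orientation <- function(facet, mesh) {
  fn <- facet$nodes
  orient <- numeric(nrow(fn))
  for (k in seq_len(nrow(fn))) {
    pts <- mesh$nodes[fn[k, ], , drop = FALSE]
    ec  <- colMeans(mesh$nodes[mesh$elems[facet$elem[k], ], , drop = FALSE])
    fc  <- colMeans(pts)
    if (mesh$dim == 2L) {
      t_ <- pts[2, ] - pts[1, ]
      nrm <- c(t_[2], -t_[1])
    } else {
      nrm <- cross3(pts[2, ] - pts[1, ], pts[4, ] - pts[1, ])
    }
    orient[k] <- if (sum(nrm * (fc - ec)) >= 0) 1 else -1
  }
  facet$orient <- orient
  facet
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Azimuth angle of a point about the vessel axis
#'
#' Standard `atan2` convention mapped to `[0, 2*pi)`: the branch cut lies on
#' the positive x-axis and the angle increases counter-clockwise; the z
#' coordinate (if any) is ignored.
#'
#' @param x numeric vector of length 2 or 3, or a matrix with one point per
#'   row; must not lie on the axis.
#' @param tol points with in-plane radius below `tol` are rejected.
#' @return azimuth angle(s) in `[0, 2*pi)`.
#' @export
azimuth_of_point <- function(x, tol = 1e-12) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  r <- sqrt(x[, 1]^2 + x[, 2]^2)
  if (any(r < tol)) stop("azimuth undefined on the vessel axis")
  th <- atan2(x[, 2], x[, 1])
  ifelse(th < 0, th + 2 * pi, th)
}

#' Element volumes (areas in 2D) by Gauss quadrature
#'
#' @param mesh a `fem_mesh`.
#' @param u optional nodal displacement matrix (n x dim); volumes are then
#'   measured on the deformed configuration.
#' @return numeric vector of element volumes; all positive for a valid mesh.
#' @export
element_volumes <- function(mesh, u = NULL) {
  coords <- mesh$nodes
  if (!is.null(u)) coords <- coords + u
  fem_element_volumes(coords, mesh$elems - 1L, mesh$dim)
}

#' Minimum Jacobian determinant over all Gauss points of all elements
#'
#' A positive value certifies that no element is inverted or degenerate.
#'
#' @inheritParams element_volumes
#' @return smallest det(J) across the 2^dim Gauss points of every element.
#' @export
min_jacobian <- function(mesh, u = NULL) {
  coords <- mesh$nodes
  if (!is.null(u)) coords <- coords + u
  fem_min_jacobian(coords, mesh$elems - 1L, mesh$dim)
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %dD, %d nodes, %d elements (%s)\n",
              x$dim, nrow(x$nodes), nrow(x$elems),
              if (x$dim == 2L) "bilinear quads" else "trilinear hexes"))
  cat(sprintf("  annulus radii [%.3g, %.3g] um, target h = %.3g um\n",
              x$r_in, x$r_out, x$h))
  cat(sprintf("  grid: %d radial x %d circumferential%s\n", x$n_r, x$n_c,
              if (x$dim == 3L) sprintf(" x %d axial", x$n_z) else ""))
  cat("  facet tags:", paste(names(x$facets), collapse = ", "), "\n")
  invisible(x)
}

#' Export a mesh and nodal/element fields as an ASCII VTU file
#'
#' Writes a VTK unstructured-grid XML file readable by ParaView, with point
#' data (e.g. displacement, nutrient, phase field) and cell data (e.g. growth
#' variable, tags) attached.
#'
#' @param mesh a `fem_mesh`.
#' @param file output path (conventionally `.vtu`).
#' @param point_data named list of numeric vectors (length n) or matrices
#'   (n x k) of per-node fields.
#' @param cell_data named list of per-element fields.
#' @param u optional nodal displacement; when given, deformed coordinates are
#'   written.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list(),
                      u = NULL) {
  coords <- mesh$nodes
  if (!is.null(u)) coords <- coords + u
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  n <- nrow(coords); m <- nrow(mesh$elems)
  vtk_type <- if (mesh$dim == 2L) 9L else 12L  # quad / hexahedron
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(format(v, digits = 9, trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(coords, 1, num), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, function(r) paste(r, collapse = " ")), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * ncol(mesh$elems), collapse = " "), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(vtk_type, m), collapse = " "), con)
  w('</DataArray></Cells>')
  write_data_arrays <- function(fields, what) {
    w('<%s>', what)
    for (nm in names(fields)) {
      v <- fields[[nm]]
      k <- if (is.matrix(v)) ncol(v) else 1L
      w('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, k)
      if (is.matrix(v)) writeLines(apply(v, 1, num), con)
      else writeLines(num(v), con)
      w('</DataArray>')
    }
    w('</%s>', what)
  }
  write_data_arrays(point_data, "PointData")
  write_data_arrays(cell_data, "CellData")
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}
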