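#' Generate a 2D vasa-vasorum tree fractal
#'
#' Grows a binary tree of straight segments from an anchor on the outer wall
#' surface toward the lumen.  The trunk has length `L0`; at each branch node
#' two children spread symmetrically by plus/minus half the opening angle
#' `gamma_2d[k-1]` about the parent direction with length `lambda[k-1]` times
#' the parent length, for levels `k = 2 .. n_levels`.  Lengths and angles are
#' multiplied by `(1 + jitter * N(0,1))`.  Segments are clipped to the radial
#' band between mid-wall and the outer surface (the vasa vasorum penetrates
#' only up to the middle of the wall).
#'
#' Uses the R RNG stream: call `set.seed()` (or use
#' [generate_vv_network()], which seeds) for reproducibility.
#'
#' @param params `vasa_vasorum` section of the configuration.
#' @param anchor numeric length-2/3 point on the outer surface.
#' @param inward_direction unit vector pointing into the wall.
#' @param r_clip radial band `c(r_mid_wall, r_out)` segments are clipped to;
#'   `NULL` disables clipping.
#' @return a `fractal_tree`: data frame `segments` with columns
#'   `x0,y0[,z0],x1,y1[,z1],level` plus the anchor point.
#' @export
generate_tree_2d <- function(params, anchor, inward_direction,
                             r_clip = NULL) {
  build_tree(params, anchor, inward_direction, dim = 2L, r_clip = r_clip)
}

#' Generate a 3D vasa-vasorum tree fractal
#'
#' As [generate_tree_2d()], but each branch node spawns one child per pair
#' `(gamma_az[i], gamma_el[i])`: the child direction makes the angle
#' `pi/2 - gamma_el[i]` with the parent axis, at azimuth `gamma_az[i]` about
#' it (defaults: three children at elevations pi/3).
#'
#' @inheritParams generate_tree_2d
#' @return a `fractal_tree`.
#' @export
generate_tree_3d <- function(params, anchor, inward_direction,
                             r_clip = NULL) {
  build_tree(params, anchor, inward_direction, dim = 3L, r_clip = r_clip)
}

build_tree <- function(params, anchor, inward_direction, dim, r_clip) {
  p <- params
  jit <- function(x) x * (1 + p$jitter * rnorm(length(x)))
  d0 <- inward_direction / sqrt(sum(inward_direction^2))
  segs <- list()
  recurse <- function(start, dir, len, level) {
    end <- start + len * dir
    segs[[length(segs) + 1L]] <<- c(start, end, level)
    if (level >= p$n_levels) return(invisible())
    k <- level + 1L                 # children live on level k, ratios index k-1
    lam <- p$lambda[k - 1L]
    if (dim == 2L) {
      half <- jit(rep(p$gamma_2d[k - 1L] / 2, 2)) * c(1, -1)
      for (a in half) {
        ca <- cos(a); sa <- sin(a)
        child <- c(ca * dir[1] - sa * dir[2], sa * dir[1] + ca * dir[2])
        recurse(end, child, jit(lam) * len, k)
      }
    } else {
      frame <- ortho_frame(dir)
      for (i in seq_along(p$gamma_az)) {
        az <- jit(p$gamma_az[i]); el <- jit(p$gamma_el[i])
        child <- cos(el) * (cos(az) * frame$e1 + sin(az) * frame$e2) +
          sin(el) * dir
        child <- child / sqrt(sum(child^2))
        recurse(end, child, jit(lam) * len, k)
      }
    }
  }
  recurse(anchor, d0, jit(p$L0), 1L)
  segs <- do.call(rbind, segs)
  cn <- if (dim == 2L) c("x0", "y0", "x1", "y1", "level") else
    c("x0", "y0", "z0", "x1", "y1", "z1", "level")
  segs <- as.data.frame(segs)
  names(segs) <- cn
  tree <- structure(list(segments = segs, anchor = anchor, dim = dim),
                    class = "fractal_tree")
  if (!is.null(r_clip)) tree <- clip_tree(tree, r_clip[1], r_clip[2])
  tree
}

# deterministic orthonormal frame perpendicular to a unit vector
ortho_frame <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, d); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

# Clip every segment to the radial band r in [r_lo, r_hi] about the z-axis
# (in-plane radius).  Segments entirely outside are dropped; crossing
# segments are truncated at the band boundary by bisection on the radius.
clip_tree <- function(tree, r_lo, r_hi) {
  segs <- tree$segments
  d <- tree$dim
  a <- as.matrix(segs[, 1:d, drop = FALSE])
  b <- as.matrix(segs[, (d + 1):(2 * d), drop = FALSE])
  rad <- function(x) sqrt(x[, 1]^2 + x[, 2]^2)
  inside <- function(x) rad(x) >= r_lo - 1e-12 & rad(x) <= r_hi + 1e-12
  keep <- logical(nrow(segs))
  for (k in seq_len(nrow(segs))) {
    ia <- inside(a[k, , drop = FALSE]); ib <- inside(b[k, , drop = FALSE])
    if (ia && ib) { keep[k] <- TRUE; next }
    if (!ia && !ib) next
    # one endpoint outside: bisect the crossing parameter
    lo <- 0; hi <- 1
    pt <- function(t) a[k, ] + t * (b[k, ] - a[k, ])
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (inside(matrix(pt(mid), 1)) == ia) lo <- mid else hi <- mid
    }
    t_cross <- (lo + hi) / 2
    if (ia) b[k, ] <- pt(t_cross) else a[k, ] <- pt(t_cross)
    keep[k] <- sqrt(sum((b[k, ] - a[k, ])^2)) > 1e-9
  }
  segs[, 1:d] <- a
  segs[, (d + 1):(2 * d)] <- b
  tree$segments <- segs[keep, , drop = FALSE]
  rownames(tree$segments) <- NULL
  tree
}

#' @export
print.fractal_tree <- function(x, ...) {
  cat(sprintf("fractal_tree: %dD, %d segments, levels 1..%d\n",
              x$dim, nrow(x$segments), max(x$segments$level)))
  invisible(x)
}

#' Generate the full vasa-vasorum network around an artery
#'
#' Seeds the RNG, places `n_trees` anchors equally spaced on the outer
#' surface (at the mid-plane for a 3D tube) and grows one tree per anchor
#' pointing radially inward.  Trees are clipped to penetrate at most to
#' mid-wall.
#'
#' @param config full configuration list.
#' @param mesh the artery `fem_mesh` the network belongs to.
#' @return list of `fractal_tree` objects with attributes `anchor_angle`
#'   (azimuth of each anchor) and `occluded` (index of the tree whose anchor
#'   is nearest to the occlusion arc coordinate, or `NA` when
#'   `vasa_vasorum$occlude` is off).
#' @export
generate_vv_network <- function(config, mesh) {
  v <- config$vasa_vasorum
  set.seed(config$solver$seed)
  r_out <- mesh$r_out
  r_mid <- (mesh$r_in + mesh$r_out) / 2
  angles <- 2 * pi * (seq_len(v$n_trees) - 1L) / v$n_trees
  trees <- vector("list", v$n_trees)
  for (i in seq_len(v$n_trees)) {
    a2 <- r_out * c(cos(angles[i]), sin(angles[i]))
    d2 <- -c(cos(angles[i]), sin(angles[i]))
    if (mesh$dim == 2L) {
      trees[[i]] <- generate_tree_2d(v, a2, d2, r_clip = c(r_mid, r_out))
    } else {
      zmid <- mesh$length / 2
      trees[[i]] <- generate_tree_3d(v, c(a2, zmid), c(d2, 0),
                                     r_clip = c(r_mid, r_out))
    }
  }
  occluded <- NA_integer_
  if (isTRUE(v$occlude)) {
    theta_occ <- config$geometry$occlusion_arc / r_mid
    dtheta <- abs(((angles - theta_occ) + pi) %% (2 * pi) - pi)
    occluded <- which.min(dtheta)
  }
  attr(trees, "anchor_angle") <- angles
  attr(trees, "occluded") <- occluded
  trees
}

#' Tag mesh elements cut by vasa-vasorum tree segments
#'
#' An element is tagged when the closed element (a convex quad/hex of the
#' structured mesh) intersects any tree segment, endpoints and boundaries
#' inclusive: a segment running along a shared facet tags both neighbours.
#' Nodes of tagged elements later receive the maximum-nutrient Dirichlet
#' condition.
#'
#' @param mesh a `fem_mesh`.
#' @param trees a single `fractal_tree` or a list of them.
#' @param tol geometric inclusiveness tolerance.
#' @return integer vector of tagged element indices (sorted, unique).
#' @export
tag_cut_elements <- function(mesh, trees, tol = 1e-9) {
  if (inherits(trees, "fractal_tree")) trees <- list(trees)
  segs <- do.call(rbind, lapply(trees, function(t) t$segments))
  if (is.null(segs) || nrow(segs) == 0L) return(integer(0))
  d <- mesh$dim
  a <- as.matrix(segs[, 1:d, drop = FALSE])
  b <- as.matrix(segs[, (d + 1):(2 * d), drop = FALSE])
  hits <- fem_segment_cut_elements(mesh$nodes, mesh$elems - 1L, d, a, b, tol)
  sort(unique(hits)) + 1L
}
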