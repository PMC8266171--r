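# Independent oracles for the DERIVED checks: implemented from scratch with
# plain R quadrature / finite differences / enumeration, never through the
# package's C++ paths.

# central finite difference of a scalar function of a matrix argument
fd_matrix_grad <- function(f, X, h = 1e-6) {
  G <- X * 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    G[i, j] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# random proper rotation
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# polygon area by fan triangulation from the centroid (oracle for shoelace)
fan_area <- function(pts) {
  ctr <- colMeans(pts)
  n <- nrow(pts)
  a <- 0
  for (k in seq_len(n)) {
    p1 <- pts[k, ] - ctr
    p2 <- pts[(k %% n) + 1, ] - ctr
    a <- a + 0.5 * (p1[1] * p2[2] - p1[2] * p2[1])
  }
  a
}

# brute-force segment/convex-polygon intersection for 2D quads:
# true if any endpoint inside, or the segment crosses any edge (inclusive).
seg_quad_intersects <- function(a, b, quad, tol = 1e-9) {
  inside <- function(p) {
    for (k in 1:4) {
      p1 <- quad[k, ]; p2 <- quad[(k %% 4) + 1, ]
      e <- p2 - p1
      if ((-e[2]) * (p[1] - p1[1]) + e[1] * (p[2] - p1[2]) < -tol)
        return(FALSE) # inward normal test for CCW quads
    }
    TRUE
  }
  if (inside(a) || inside(b)) return(TRUE)
  seg_cross <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
      (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    eps <- tol * max(1, abs(c(p1, p2, p3, p4)))
    if (abs(d1) < eps && abs(d2) < eps && abs(d3) < eps && abs(d4) < eps) {
      # collinear: reduce to 1D overlap along the dominant direction
      ax <- if (abs(p2[1] - p1[1]) >= abs(p2[2] - p1[2])) 1 else 2
      return(max(p1[ax], p2[ax]) >= min(p3[ax], p4[ax]) - eps &&
               max(p3[ax], p4[ax]) >= min(p1[ax], p2[ax]) - eps)
    }
    (d1 * d2 <= eps) && (d3 * d4 <= eps)
  }
  for (k in 1:4) {
    p1 <- quad[k, ]; p2 <- quad[(k %% 4) + 1, ]
    if (seg_cross(a, b, p1, p2)) return(TRUE)
  }
  FALSE
}

# hand-assembled single-element residual on a quad (independent quadrature):
# nutrient + phase-field rows only, with all coupling data supplied.
hand_element_residual_scalar <- function(X, u, cvec, phivec, phiprev, cfg,
                                         dt, Hlag, ghat) {
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  shp <- function(xi, eta) {
    xa <- c(-1, 1, 1, -1); ya <- c(-1, -1, 1, 1)
    N <- 0.25 * (1 + xa * xi) * (1 + ya * eta)
    dN <- cbind(0.25 * xa * (1 + ya * eta), 0.25 * ya * (1 + xa * xi))
    list(N = N, dN = dN)
  }
  rc <- numeric(4); rphi <- numeric(4)
  xe <- X + u
  nu <- cfg$nutrient; ph <- cfg$phasefield; so <- cfg$solver
  for (g in 1:4) {
    s <- shp(pts[g, 1], pts[g, 2])
    J <- t(xe) %*% s$dN
    dNx <- s$dN %*% solve(J)
    w <- det(J)
    c_gp <- sum(s$N * cvec); phi_gp <- sum(s$N * phivec)
    phiprev_gp <- sum(s$N * phiprev)
    gradc <- drop(t(dNx) %*% cvec); gradphi <- drop(t(dNx) %*% phivec)
    D <- diffusivity(phi_gp, nu)
    rc <- rc + so$K_c * (D * (dNx %*% gradc) + nu$R_c * s$N) * w
    S <- ph$R_s * Hlag[g] * sum(gradphi * ghat[g, ])
    fp <- double_well_prime(phi_gp, ph$M)
    Pp <- penalty_prime(phi_gp)
    rphi <- rphi + so$K_phi * (ph$eps^2 * (dNx %*% gradphi) +
      (ph$M * fp + ph$K_p * Pp - S + (phi_gp - phiprev_gp) / dt) * s$N) * w
  }
  list(c = drop(rc), phi = drop(rphi))
}

# eigenvalues of a symmetric 3x3 via characteristic polynomial roots
charpoly_eigen <- function(S) {
  cp <- c(-det(S),
          (sum(diag(S))^2 - sum(diag(S %*% S))) / 2,
          -sum(diag(S)), 1)
  sort(Re(polyroot(cp)), decreasing = TRUE)
}
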