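small_geom <- list(inner_diameter = 50, wall_thickness = 15, h = 5,
                   length = 100)

test_that("work-free problem stays at the trivial equilibrium", {
  cfg <- default_config(2)
  cfg$geometry$h <- 5
  cfg$nutrient$R_c <- 0 # no consumption: uniform c is the exact solution
  cfg$solver <- utils::modifyList(cfg$solver, list(
    p_max = 0, seed_phase = FALSE, t_end = 0.15, dt = 0.05))
  res <- simulate_artery(cfg)
  last <- res$states[[length(res$states)]]
  expect_lt(max(abs(last$u)), 1e-9)
  expect_lt(max(abs(last$phi)), 1e-9)
  expect_equal(last$c, rep(1, length(last$c)), tolerance = 1e-9)
  expect_lt(max(abs(last$alpha)), 1e-12)
  expect_equal(res$series$stenosis_pct, rep(0, nrow(res$series)),
               tolerance = 1e-9)
})

test_that("single-element patch test matches hand-assembled Gauss sums", {
  cfg <- default_config(2)
  X <- rbind(c(0, 0), c(1.1, 0.1), c(1.2, 1.3), c(-0.1, 0.9))
  mesh <- structure(list(nodes = X, elems = matrix(1:4, 1), dim = 2L,
                         facets = list(), h = 1), class = "fem_mesh")
  set.seed(21)
  u <- matrix(rnorm(8, sd = 0.02), 4, 2)
  cvec <- 0.8 + 0.1 * X[, 1] - 0.05 * X[, 2]
  phiv <- 0.3 + 0.2 * X[, 1]
  phiprev <- phiv - 0.01
  alpha <- matrix(0.005, 1, 4)
  Hlag <- matrix(1, 1, 4)
  ghat <- matrix(rep(c(0.6, 0.8), each = 4), 1, 8) # per-gp (x then y blocks)
  ghat <- matrix(c(rbind(rep(0.6, 4), rep(0.8, 4))), 1, 8) # interleaved
  st <- list(u = u, c = cvec, phi = phiv)
  dofs <- numeric(16)
  for (i in 1:2) dofs[seq(i, by = 4, length.out = 4)] <- u[, i]
  dofs[seq(3, by = 4, length.out = 4)] <- cvec
  dofs[seq(4, by = 4, length.out = 4)] <- phiv
  par <- cfg; par$solver$dt <- 0.05
  out <- atheroFEM:::fem_assemble(X, matrix(0:3, 1), 2L, dofs, phiprev,
                                  alpha, Hlag, ghat, par, FALSE)
  gh_mat <- matrix(ghat, 4, 2, byrow = TRUE)
  oracle <- hand_element_residual_scalar(X, u, cvec, phiv, phiprev, cfg,
                                         0.05, Hlag[1, ], gh_mat)
  expect_equal(out$res[seq(3, by = 4, length.out = 4)], oracle$c,
               tolerance = 1e-10)
  expect_equal(out$res[seq(4, by = 4, length.out = 4)], oracle$phi,
               tolerance = 1e-10)
})

test_that("assembled tangent matches finite differences of the residual", {
  cfg <- default_config(2)
  cfg$geometry$h <- 5
  mesh <- make_annulus_mesh(cfg$geometry)
  set.seed(22)
  st <- new_field_state(mesh, cfg)
  n <- nrow(mesh$nodes)
  st$u <- matrix(rnorm(2 * n, sd = 0.02), n, 2)
  st$c <- 0.8 + 0.1 * runif(n)
  st$phi <- runif(n, 0.1, 0.9)
  st$alpha <- matrix(0.003, nrow(mesh$elems), 4)
  st$lag <- atheroFEM:::compute_lag(st, mesh, cfg)
  dofs <- atheroFEM:::pack_dofs(st, 2L)
  par <- cfg; par$solver$dt <- 0.05
  asm <- function(d, tang) atheroFEM:::fem_assemble(
    mesh$nodes, mesh$elems - 1L, 2L, d, st$phi, st$alpha, st$lag$H,
    st$lag$ghat, par, tang)
  out <- asm(dofs, TRUE)
  A <- Matrix::sparseMatrix(i = out$i + 1L, j = out$j + 1L, x = out$x,
                            dims = rep(length(dofs), 2))
  dvec <- rnorm(length(dofs)); dvec <- dvec / sqrt(sum(dvec^2))
  h <- 1e-6
  rp <- asm(dofs + h * dvec, FALSE)$res
  rm_ <- asm(dofs - h * dvec, FALSE)$res
  fd <- (rp - rm_) / (2 * h)
  Ad <- as.numeric(A %*% dvec)
  expect_lt(max(abs(Ad - fd)) / max(abs(fd)), 1e-6)
})

test_that("pressurized annulus matches the Lame solution at small pressure", {
  cfg <- default_config(2)
  cfg$geometry$h <- 1.25
  cfg$material$eta <- 0
  p <- 0.05 # kPa: small enough for the linear regime
  mesh <- make_annulus_mesh(cfg$geometry)
  bc <- boundary_conditions(mesh, cfg)
  st <- new_field_state(mesh, cfg)
  ns <- newton_solve(st, mesh, cfg, bc, active_fields = "u", p_now = p,
                     state_prev = st, dt = 0)
  expect_true(ns$converged)
  ring <- mesh$inner_ring
  ur <- rowSums(ns$state$u[ring, ] * mesh$nodes[ring, ]) /
    sqrt(rowSums(mesh$nodes[ring, ]^2))
  ex <- lame_cylinder_exact(25, 25, 40, p, cfg$material$mu, cfg$material$nu)
  expect_equal(mean(ur), ex, tolerance = 0.05 * ex)
  # quadratic convergence of the Newton iteration (contraction accelerates)
  rn <- ns$res_norms
  k <- length(rn)
  expect_lt(rn[k], cfg$solver$newton_tol)
  expect_lt(rn[k] / rn[k - 1], rn[k - 1] / rn[k - 2])
})

test_that("linear diffusion sub-problem converges in one iteration", {
  fx <- manufactured_diffusion_case(5)
  mesh <- fx$mesh; cfg <- fx$config
  inner <- sort(unique(as.vector(mesh$facets$inner_surface$nodes)))
  bc <- list(dirichlet = data.frame(node = inner, field = "c", comp = 0L,
                                    value = 1))
  st <- new_field_state(mesh, cfg)
  st$c <- rep(0, nrow(mesh$nodes))
  ns <- newton_solve(st, mesh, cfg, bc, active_fields = "c", p_now = 0,
                     state_prev = st, dt = 0)
  expect_true(ns$converged)
  expect_equal(ns$iterations, 1L)
  # converged nutrient is radially monotone decreasing (maximum principle)
  r <- round(sqrt(rowSums(mesh$nodes^2)), 6)
  rings <- tapply(ns$state$c, r, mean)
  expect_true(all(diff(rings[order(as.numeric(names(rings)))]) < 0))
})

test_that("occluding a tree removes exactly its unshared nutrient constraints", {
  cfg <- canned_case("fiber_vv", t_end = 0.1)
  mesh <- make_annulus_mesh(cfg$geometry)
  trees <- generate_vv_network(cfg, mesh)
  occ <- attr(trees, "occluded")
  expect_false(is.na(occ))
  all_cut <- tag_cut_elements(mesh, trees)
  keep_cut <- tag_cut_elements(mesh, trees[setdiff(seq_along(trees), occ)])
  occ_cut <- tag_cut_elements(mesh, trees[occ])
  # brute-force set difference oracle
  expect_setequal(keep_cut, setdiff(all_cut, setdiff(occ_cut, keep_cut)))
  nodes_all <- unique(as.vector(mesh$elems[all_cut, ]))
  nodes_keep <- unique(as.vector(mesh$elems[keep_cut, ]))
  removed <- setdiff(nodes_all, nodes_keep)
  expect_gt(length(removed), 0)
  # and the simulation's Dirichlet set indeed excludes them
  res <- simulate_artery(cfg)
  expect_length(intersect(res$vv_nodes, removed), 0)
})

test_that("no growth means the pressurized solution is a steady state", {
  cfg <- canned_case("no_fiber_no_vv", h = 5, t_end = 0.15)
  cfg$growth$k_g <- 0
  res <- simulate_artery(cfg)
  # drift bounded by the Newton tolerance (sub-tolerance residual redistributes
  # a little between steps)
  u0 <- res$states[[1]]$u
  uT <- res$states[[length(res$states)]]$u
  expect_lt(max(abs(uT - u0)), 1e-5)
  expect_lt(max(abs(res$series$stenosis_pct)), 1e-5)
})

test_that("uniformly inflamed unloaded patch grows by det F_g = (1+alpha)^2", {
  cfg <- default_config(2)
  cfg$geometry$h <- 5
  cfg$solver$p_max <- 0
  mesh <- make_annulus_mesh(cfg$geometry)
  bc <- boundary_conditions(mesh, cfg)
  bc$dirichlet <- bc$dirichlet[bc$dirichlet$field == "u", ]
  st <- new_field_state(mesh, cfg)
  st$phi <- rep(1, nrow(mesh$nodes))
  v0 <- element_volumes(mesh)
  for (k in 1:3) {
    st$lag <- atheroFEM:::compute_lag(st, mesh, cfg)
    ns <- newton_solve(st, mesh, cfg, bc, active_fields = "u", p_now = 0,
                       state_prev = st, dt = 0.05)
    expect_true(ns$converged)
    new_st <- ns$state
    gp_phi <- atheroFEM:::compute_lag(new_st, mesh, cfg)$phi_gp
    new_st$alpha <- matrix(update_alpha(as.vector(st$alpha),
                                        as.vector(gp_phi), 0.05, cfg$growth),
                           nrow(st$alpha), ncol(st$alpha))
    st <- new_st; st$lag <- NULL
  }
  # after saturation the deformed volumes equal det F_g times the original
  a <- unique(round(as.vector(st$alpha), 12))
  expect_length(a, 1)
  vT <- element_volumes(mesh, st$u)
  expect_equal(vT / v0, rep((1 + a)^2, length(v0)), tolerance = 1e-8)
})

test_that("simulation output is deterministic for a fixed seed", {
  cfg <- canned_case("fiber_vv", t_end = 0.1)
  r1 <- simulate_artery(cfg)
  r2 <- simulate_artery(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$states[[length(r1$states)]],
                   r2$states[[length(r2$states)]])
  expect_identical(lapply(r1$trees, function(t) t$segments),
                   lapply(r2$trees, function(t) t$segments))
})

test_that("coarse 3D tube runs end to end with all couplings active", {
  cfg <- canned_case("tube3d_coarse", t_end = 0.1)
  res <- simulate_artery(cfg)
  expect_equal(res$mesh$dim, 3L)
  last <- res$states[[length(res$states)]]
  expect_gt(max(last$alpha), 0)          # growth engaged at the seed
  expect_gt(max(last$phi), 0.5)          # seed present
  expect_equal(max(last$c), 1)           # lumen + vasa vasorum sources
  expect_gt(lumen_area(res$mesh, last$u), 0)
  expect_true(all(is.finite(res$series$stenosis_pct)))
})
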