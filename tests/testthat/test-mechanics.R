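mat_default <- default_config(2)$material

test_that("macaulay bracket and inverted Heaviside follow their conventions", {
  expect_equal(macaulay(c(3, -2, 0)), c(3, 0, 0))
  expect_equal(heaviside(0.5, 1.0), 1)
  expect_equal(heaviside(1.5, 1.0), 0)
  expect_equal(heaviside(1.0, 1.0), 1) # boundary inclusive
})

test_that("fiber direction is the unit helix tangent", {
  expect_equal(fiber_direction(0, pi / 3), c(0, 0.5, sqrt(3) / 2))
  expect_equal(fiber_direction(1.234, pi / 2), c(0, 0, 1), tolerance = 1e-12)
  set.seed(5)
  for (k in 1:20) {
    n <- fiber_direction(runif(1, 0, 2 * pi), runif(1, -pi / 2, pi / 2))
    expect_equal(sum(n^2), 1, tolerance = 1e-14)
  }
})

test_that("deformation gradient inverts (I - grad_u) and round-trips", {
  expect_equal(deformation_gradient(matrix(0, 3, 3)), diag(3))
  expect_equal(deformation_gradient(diag(c(0.5, 0, 0))), diag(c(2, 1, 1)))
  set.seed(6)
  for (k in 1:10) {
    F0 <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(F0) < 0.3) next
    gu <- diag(3) - solve(F0)
    expect_equal(deformation_gradient(gu), F0, tolerance = 1e-12)
  }
  expect_error(deformation_gradient(diag(c(1, 0, 0))), "inversion")
})

test_that("elastic invariants: identity, pure dilation, uniaxial fiber stretch", {
  iv <- elastic_invariants(diag(3), c(1, 0, 0))
  expect_equal(unlist(iv), c(I1e = 3, I4e = 1, J_e = 1))
  iv2 <- elastic_invariants(2 * diag(3), c(1, 0, 0))
  expect_equal(unlist(iv2), c(I1e = 3, I4e = 1, J_e = 8))
  lam <- 1.44
  Fe <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  iv3 <- elastic_invariants(Fe, c(1, 0, 0))
  expect_equal(iv3$I4e, lam^2, tolerance = 1e-12)
  expect_equal(iv3$J_e, 1, tolerance = 1e-12)
  expect_error(elastic_invariants(-diag(3), c(1, 0, 0)), "det")
})

test_that("free energy is zero and stress-free at the unloaded reference", {
  n <- fiber_direction(0.3, pi / 3)
  # fiber term contributes the constant offset eta/beta at identity
  expect_equal(free_energy(diag(3), n, mat_default),
               mat_default$eta / mat_default$beta)
  m0 <- utils::modifyList(mat_default, list(eta = 0))
  expect_equal(free_energy(diag(3), n, m0), 0)
  expect_equal(max(abs(cauchy_stress(diag(3), n, mat_default))), 0,
               tolerance = 1e-10)
  # literal printed conventions leave the documented spurious pressure -mu
  mlit <- utils::modifyList(mat_default, list(isochoric_matrix = TRUE))
  sig_lit <- cauchy_stress(diag(3), n, mlit)
  expect_equal(sig_lit, diag(-mat_default$mu, 3), tolerance = 1e-10)
})

test_that("analytic Cauchy stress matches finite differences of the energy", {
  set.seed(11)
  worst <- 0
  n_done <- 0
  while (n_done < 100) {
    Fe <- diag(3) + matrix(rnorm(9, sd = 0.12), 3, 3)
    if (det(Fe) < 0.4) next
    nf <- rnorm(3); nf <- nf / sqrt(sum(nf^2))
    P_fd <- fd_matrix_grad(function(X) free_energy(X, nf, mat_default), Fe)
    sig_fd <- P_fd %*% t(Fe) / det(Fe)
    sig <- cauchy_stress(Fe, nf, mat_default)
    worst <- max(worst, max(abs(sig - sig_fd)) / max(abs(sig)))
    # symmetry of the analytic stress
    expect_lt(max(abs(sig - t(sig))) / max(abs(sig)), 1e-10)
    n_done <- n_done + 1
  }
  expect_lt(worst, 1e-6)
})

test_that("energy is objective under 100 random rotations", {
  set.seed(12)
  nf <- fiber_direction(1.1, pi / 3)
  for (k in 1:100) {
    Fe <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    if (det(Fe) < 0.4) next
    Q <- random_rotation()
    p1 <- free_energy(Fe, nf, mat_default)
    p2 <- free_energy(Q %*% Fe, nf, mat_default)
    expect_equal(p2, p1, tolerance = 1e-10)
  }
})

test_that("fiber stretch term is inactive in compression (Macaulay gating)", {
  m <- mat_default
  for (lam in c(0.7, 0.85, 0.999)) {
    Fe <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))) # I4e = lam^2 < 1, J = 1
    # the exponent drops the rho-term entirely: closed form without it
    I1 <- sum(Fe^2)
    psi_expect <- m$mu / 2 * (I1 - 3) +
      (m$eta / m$beta) * exp(m$beta * (1 - m$rho) * (I1 - 3)^2)
    expect_equal(free_energy(Fe, c(1, 0, 0), m), psi_expect,
                 tolerance = 1e-12)
    # with the fiber-stretch term gated off, the stress cannot depend on the
    # fiber direction (only I4e involves n)
    s_x <- cauchy_stress(Fe, c(1, 0, 0), m)                   # I4e < 1
    n_oblique <- c(sqrt(0.6), sqrt(0.2), sqrt(0.2))           # I4e < 1 too
    expect_lt(drop(n_oblique %*% crossprod(Fe) %*% n_oblique), 1)
    s_d <- cauchy_stress(Fe, n_oblique, m)
    expect_equal(s_x, s_d, tolerance = 1e-12)
  }
  # and in tension the fiber direction and dispersion weight do matter
  Fe <- diag(c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2)))
  s0 <- cauchy_stress(Fe, c(1, 0, 0), utils::modifyList(m, list(rho = 0.2)))
  s1 <- cauchy_stress(Fe, c(1, 0, 0), utils::modifyList(m, list(rho = 1)))
  expect_gt(max(abs(s0 - s1)), 1e-6)
  s_y <- cauchy_stress(Fe, c(0, 1, 0), m)
  s_x <- cauchy_stress(Fe, c(1, 0, 0), m)
  expect_gt(max(abs(s_y - s_x)), 0) # direction-independence broken in tension
})

test_that("isotropic limit matches linear elasticity at small strain", {
  m0 <- utils::modifyList(mat_default, list(eta = 0))
  mu <- m0$mu; nu <- m0$nu
  kvol <- mu * nu / (1 - 2 * nu)
  eps <- 1e-4
  # uniaxial strain (constrained lateral): sigma_11 = (lambda + 2 mu) eps
  Fe <- diag(c(1 + eps, 1, 1))
  sig <- cauchy_stress(Fe, c(1, 0, 0), m0)
  lambda_lame <- 2 * kvol # volumetric convention: kvol (J-1)^2 => lambda = 2 kvol
  expect_equal(sig[1, 1], (lambda_lame + 2 * mu) * eps,
               tolerance = 0.02 * (lambda_lame + 2 * mu) * eps)
  expect_equal(sig[2, 2], lambda_lame * eps,
               tolerance = 0.02 * (lambda_lame + 2 * mu) * eps)
  # pure shear: sigma_12 = mu * gamma
  gam <- 1e-4
  Fs <- diag(3); Fs[1, 2] <- gam
  sig_s <- cauchy_stress(Fs, c(0, 0, 1), m0)
  expect_equal(sig_s[1, 2], mu * gam, tolerance = 0.02 * mu * gam)
})

test_that("growth tensor and its velocity gradient follow the scalar law", {
  expect_equal(growth_tensor(0), diag(3))
  expect_equal(det(growth_tensor(1e-3, dim = 3)), (1.001)^3, tolerance = 1e-12)
  expect_error(growth_tensor(-1), "-1")
  # L_g = Fg_dot Fg^{-1} = (alpha_dot/(1+alpha)) I by finite differences
  alpha_t <- function(t) 0.2 * t + 0.05 * t^2
  t0 <- 0.7; h <- 1e-6
  Fg_dot <- (growth_tensor(alpha_t(t0 + h)) - growth_tensor(alpha_t(t0 - h))) / (2 * h)
  Lg <- Fg_dot %*% solve(growth_tensor(alpha_t(t0)))
  adot <- (alpha_t(t0 + h) - alpha_t(t0 - h)) / (2 * h)
  expect_equal(Lg, (adot / (1 + alpha_t(t0))) * diag(3), tolerance = 1e-6)
})

test_that("alpha update: exact sub-step form, gating and the cap", {
  gr <- list(k_g = 0.25, alpha_cri = 1e-3)
  expect_equal(update_alpha(0.5e-3, 0, 0.05, gr), 0.5e-3)  # no inflammation
  expect_equal(update_alpha(2e-3, 1, 0.05, gr), 2e-3)      # beyond the cap
  # trajectory matches the closed form e^{k_g t} - 1 until the cap,
  # cross-checked against fine-step numerical integration of the ODE
  dt <- 1e-3
  a <- 0; a_fine <- 0
  for (k in 1:3) { # 3 steps stay below the cap (crossed at ~4 steps)
    a <- update_alpha(a, 1, dt, gr)
    for (j in 1:100) { # explicit Euler on alpha_dot = k_g (1+alpha) H phi
      if (a_fine <= gr$alpha_cri)
        a_fine <- a_fine + (dt / 100) * gr$k_g * (1 + a_fine)
    }
  }
  expect_equal(a, exp(0.25 * 3 * dt) - 1, tolerance = 1e-12)
  expect_equal(a, a_fine, tolerance = 1e-5)
  # cap overshoot bounded by one increment for any phi history
  set.seed(13)
  a <- 0; dt <- 0.05
  for (k in 1:200) a <- update_alpha(a, runif(1), dt, gr)
  expect_lte(a, gr$alpha_cri + (1 + gr$alpha_cri) * (exp(gr$k_g * dt) - 1))
})
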