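# Viscoelastic momentum balance, cell forces, exposure and energy.

test_that("temporary forces: per-cell balance and phenotype magnitude ratio", {
  m <- small_mesh()
  mp <- mechanics_params()
  expect_equal(temporary_force_load(new_cells(), m, mp), matrix(0, nrow(m$nodes), 2))
  one <- new_cells("fibroblast", 3.7, -1.2, 0L, 0L, phase = 0.3, clock_on = FALSE)
  L <- temporary_force_load(one, m, mp)
  expect_equal(colSums(L), c(0, 0), tolerance = 1e-12)    # 3 equal arcs cancel
  myo <- new_cells("myofibroblast", 3.7, -1.2, 0L, 0L, phase = 0.3, clock_on = FALSE)
  Lm <- temporary_force_load(myo, m, mp)
  expect_equal(Lm, L * 4, tolerance = 1e-12)              # 33.28 / 8.32 = 4
})

test_that("exposure time integrates the TGF/collagen/myofibroblast product", {
  m <- small_mesh()
  tau0 <- numeric(nrow(m$tri))
  n <- nrow(m$nodes)
  # no myofibroblasts or no TGF: unchanged
  expect_equal(update_exposure(tau0, m, rep(1, n), rep(0, n), NULL, 0.1), tau0)
  expect_equal(update_exposure(tau0, m, rep(0, n), rep(0, n), rbind(c(0, 0)), 0.1), tau0)
  # c = 0.02, rho_c = 0, one myofibroblast, dt = 0.1 -> d tau = 0.002
  tau1 <- update_exposure(tau0, m, rep(0.02, n), rep(0, n), rbind(c(1.2, 0.8)), 0.1)
  touched <- which(tau1 > 0)
  expect_gt(length(touched), 0)
  expect_equal(unique(round(tau1[touched], 12)), 0.002)
  # monotone: never decreases
  tau2 <- update_exposure(tau1, m, rep(0.02, n), rep(0, n), rbind(c(1.2, 0.8)), 0.1)
  expect_true(all(tau2 >= tau1))
})

test_that("plastic magnitude saturates at Q_max", {
  expect_equal(plastic_magnitude(0), 0)
  expect_equal(plastic_magnitude(1e3), 33, tolerance = 1e-8)
  expect_equal(plastic_magnitude(1), 33 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(33 * (1 - exp(-1)), 20.86, tolerance = 1e-2)
  expect_error(plastic_magnitude(-1), "negative")
  tt <- seq(0, 5, 0.5)
  expect_true(all(diff(plastic_magnitude(tt)) > 0))
})

test_that("plastic edge forces cancel within a uniformly exposed element", {
  m <- small_mesh()
  mp <- mechanics_params()
  tau <- numeric(nrow(m$tri))
  expect_equal(plastic_force_load(m, tau, mp), matrix(0, nrow(m$nodes), 2))
  tau[5] <- 2
  L <- plastic_force_load(m, tau, mp)
  # the three inward edge forces of a single element sum to zero
  expect_equal(colSums(L), c(0, 0), tolerance = 1e-12)
  expect_gt(max(abs(L)), 0)
  # doubling edge lengths doubles each point force: compare two meshes
  m2 <- build_rect_mesh(120, 80, 40, 30, 10)  # same layout, scaled 2x
  tau2 <- numeric(nrow(m2$tri)); tau2[5] <- 2
  L2 <- plastic_force_load(m2, tau2, mp)
  expect_equal(max(abs(L2)), 2 * max(abs(L)), tolerance = 1e-9)
})

test_that("momentum solve: zero load, Robin limit and antisymmetry", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  mp <- mechanics_params()
  u0 <- matrix(0, n, 2)
  expect_equal(solve_momentum(m, u0, u0, 0.1, mp), u0)
  # kappa_f -> large freezes the outer boundary
  mp_stiff <- mechanics_params(kappa_f = 1e6, eta = 0)
  load <- dirac_point_load(m, rbind(c(5, 3)), 40, direction = rbind(c(0, 1)))
  u <- solve_momentum(m, load, u0, 0.1, mp_stiff)
  bn <- unique(as.vector(m$boundary_edges[m$boundary_tag == "outer", ]))
  expect_lt(max(abs(u[bn, ])), 1e-4)
  # equal-and-opposite pair on the x-axis: u_x antisymmetric under x -> -x
  mp_e <- mechanics_params(eta = 0)
  load2 <- dirac_point_load(m, rbind(c(10, 0), c(-10, 0)), c(20, 20),
                            direction = rbind(c(1, 0), c(-1, 0)))
  u2 <- solve_momentum(m, load2, u0, 0.1, mp_e)
  key <- paste(round(-m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mirror <- match(key, paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9)))
  expect_equal(u2[, 1], -u2[mirror, 1], tolerance = 1e-8)
})

test_that("with eta = 0 the response is step-independent; eta > 0 relaxes to it", {
  m <- tiny_mesh()
  n <- nrow(m$nodes)
  load <- dirac_point_load(m, rbind(c(1, 1)), 5, direction = rbind(c(1, 0)))
  u0 <- matrix(0, n, 2)
  mp0 <- mechanics_params(eta = 0)
  ua <- solve_momentum(m, load, u0, 0.1, mp0)
  ub <- solve_momentum(m, load, ua, 0.1, mp0)
  expect_equal(ua, ub, tolerance = 1e-12)
  # Kelvin-Voigt creep toward the elastic solution under a step load
  mp1 <- mechanics_params(eta = 1)
  u <- u0
  dev <- numeric(40)
  for (i in 1:40) {
    u <- solve_momentum(m, load, u, 0.1, mp1)
    dev[i] <- max(abs(u - ua))
  }
  expect_true(all(diff(dev) < 1e-12))   # monotone approach
  expect_lt(dev[40], 0.05 * max(abs(ua)))
})

test_that("substrate velocity is the displacement difference quotient", {
  u1 <- matrix(0, 4, 2)
  u2 <- u1; u2[, 1] <- 0.1
  expect_equal(substrate_velocity(u2, u1, 0.1), u2 / 0.1 * 1)
  expect_equal(substrate_velocity(u1, u1, 0.1), u1)
  expect_equal(substrate_velocity(u1 + 2 * (u2 - u1), u1, 0.1),
               2 * substrate_velocity(u2, u1, 0.1))
  expect_error(substrate_velocity(u1, u1, 0), "positive")
})

test_that("elastic energy matches the uniform-dilation closed form", {
  m <- tiny_mesh()
  mp <- mechanics_params(eta = 0)
  n <- nrow(m$nodes)
  expect_equal(elastic_strain_energy(m, matrix(0, n, 2), mp), 0)
  # u = eps * x: strain = eps I, energy density = 2 (mu + lam) eps^2
  eps <- 0.01
  u <- eps * m$nodes
  mu <- mp$E / (2 * (1 + mp$nu))
  lam <- mp$E * mp$nu / ((1 + mp$nu) * (1 - 2 * mp$nu))
  A <- sum(signed_areas(m$nodes, m$tri))
  expect_equal(elastic_strain_energy(m, u, mp), 2 * (mu + lam) * eps^2 * A,
               tolerance = 1e-10)
  # random displacements: energy is never negative
  set.seed(5)
  for (i in 1:5) {
    ur <- matrix(rnorm(2 * n, sd = 0.1), n, 2)
    expect_gte(elastic_strain_energy(m, ur, mp), 0)
  }
})

test_that("mechanics parameter validation", {
  expect_error(mechanics_params(nu = 0.5), "Poisson")
  expect_error(mechanics_params(E = -1), "negative")
})
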