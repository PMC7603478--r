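# Hertz repulsion, exponential event clocks, division geometry,
# macrophage influx and the displacement SDE.

test_that("Hertz contact energy matches the closed form", {
  # no overlap
  expect_equal(hertz_energy(5.0), 0)
  expect_equal(hertz_energy(7.3), 0)
  # h = R and h = 2R with E_c = 5, R = 2.5
  expect_equal(hertz_energy(2.5), (1 / 30) * (5 / pi), tolerance = 1e-12)
  expect_equal(hertz_energy(2.5), 0.05305, tolerance = 1e-4)
  expect_equal(hertz_energy(0), (1 / 30) * (5 / pi) * 2^2.5, tolerance = 1e-12)
  expect_equal(hertz_energy(0), 0.30010, tolerance = 1e-4)
})

test_that("net repulsion points away from contact pressure", {
  lone <- new_cells("fibroblast", 0, 0, 0L, 0L, 0, FALSE)
  r <- net_repulsion(lone)
  expect_equal(r$M_hat, 0)
  expect_equal(r$z_hat, matrix(0, 1, 2))
  # one neighbour at distance R along +x: z = (-1, 0), M_hat = -M(R)
  two <- new_cells(rep("fibroblast", 2), c(0, 2.5), c(0, 0), 0L, 0L, 0, FALSE)
  r <- net_repulsion(two)
  expect_equal(r$z_hat[1, ], c(-1, 0), tolerance = 1e-12)
  expect_equal(r$M_hat[1], -hertz_energy(2.5), tolerance = 1e-12)
  expect_lte(r$M_hat[1], 0)
  # two symmetric neighbours ahead at +-45 degrees: y components cancel
  d <- 2.5 / sqrt(2)
  three <- new_cells(rep("fibroblast", 3), c(0, d, d), c(0, d, -d), 0L, 0L, 0, FALSE)
  r <- net_repulsion(three)
  expect_equal(r$z_hat[1, ], c(-1, 0), tolerance = 1e-12)
})

test_that("event probability is the exponential-clock formula", {
  expect_equal(event_probability(0, 0.1), 0)
  expect_equal(event_probability(10, 0.1), 1 - exp(-1))
  expect_equal(event_probability(10, 0.1), 0.63212, tolerance = 1e-5)
  expect_equal(event_probability(1e9, 0.1), 1)
  expect_error(event_probability(-1, 0.1), "negative")
})

test_that("event rates reproduce the piecewise formulas and boundaries", {
  p <- cell_params()
  expect_equal(event_rate("division", 0, 0, p), 2)
  expect_equal(event_rate("division", 0, 0.05, p), 0)    # threshold is strict <
  expect_equal(event_rate("division", 0.1, 0, p), 20 * 0.01 + 2)
  expect_equal(event_rate("apoptosis", 0, 0.07, p), 10)  # boundary inclusive
  expect_equal(event_rate("apoptosis", 0, 0.0699, p), 0)
  expect_equal(event_rate("differentiation", 0.1, 0, p), 10.6)
  expect_equal(event_rate("differentiation", 0.01, 0, p), 0)  # strict >
  expect_equal(event_rate("differentiation", 0.0100001, 0, p),
               60 * 0.0100001^2 + 10)
  expect_error(event_rate("mitosis", 0, 0, p), "unknown")
})

test_that("division geometry: separation 2R, preserved midpoint, uniform angle", {
  p <- cell_params()
  set.seed(10)
  phis <- numeric(2000)
  for (i in seq_len(2000)) {
    cells <- new_cells("fibroblast", 1.3, -2.1, 100L, 50L, 0, FALSE)
    out <- divide_cell(cells, 1, p)
    expect_equal(n_cells(out), 2L)
    dx <- out$x[1] - out$x[2]; dy <- out$y[1] - out$y[2]
    expect_equal(sqrt(dx^2 + dy^2), 5, tolerance = 1e-12)          # 2R
    expect_equal(c(mean(out$x), mean(out$y)), c(1.3, -2.1), tolerance = 1e-12)
    expect_gt(out$mature_at[2], out$mature_at[1])                  # daughter slower
    expect_equal(out$age, c(0L, 0L))
    phis[i] <- atan2(dy, dx) %% (2 * pi)
  }
  expect_gt(stats::ks.test(phis, "punif", 0, 2 * pi)$p.value, 0.01)
  mac <- new_cells("macrophage", 0, 0, 0L, 0L, 0, FALSE)
  expect_error(divide_cell(mac, 1, p), "fibroblasts")
})

test_that("macrophage influx matches the per-site Bernoulli model", {
  sites <- cbind(seq(-20, 20, by = 2), 15)
  expect_equal(n_cells(spawn_macrophages(sites, 0, 0.1)), 0L)
  set.seed(4)
  lambda <- 0.5; dt <- 0.1
  nrep <- 1000
  counts <- vapply(seq_len(nrep), function(i) {
    born <- spawn_macrophages(sites, lambda, dt)
    expect_true(all(born$y == 15))       # on the interface
    n_cells(born)
  }, numeric(1))
  p <- 1 - exp(-lambda * dt)
  expected <- nrow(sites) * p
  se <- sqrt(nrow(sites) * p * (1 - p) / nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("pure random walk has the prescribed mean-square displacement", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  p <- cell_params(v = 0, sigma_rw = 0.5, E_c = 0)  # drifts off, visible walk
  k <- 1000
  cells <- new_cells(rep("fibroblast", k), runif(k, -30, 30), runif(k, -20, 20),
                     0L, 0L, 0, FALSE)
  x0 <- cells$x; y0 <- cells$y
  zero <- numeric(n); Om <- matrix(0, n, 3)
  v0 <- matrix(0, n, 2)
  set.seed(8)
  nst <- 40; dt <- 0.1
  for (i in seq_len(nst)) {
    cells <- displace_cells(cells, m, zero, zero, Om, zero, zero, v0, dt,
                            p, random_walk = TRUE)$cells
  }
  # per-axis variance sigma_rw^2 * t (repulsion may perturb a few pairs)
  t <- nst * dt
  v_emp <- (var(cells$x - x0) + var(cells$y - y0)) / 2
  se <- p$sigma_rw^2 * t * sqrt(2 / (k - 1))
  expect_lt(abs(v_emp - p$sigma_rw^2 * t), 4 * se + 0.02 * p$sigma_rw^2 * t)
})

test_that("chemotaxis drift speed never exceeds mu_c and stalls at saturation", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  p <- cell_params()
  # steep TGF gradient field
  ct <- pmax(0, 1 - abs(m$nodes[, 1]) / 10)
  zero <- numeric(n); Om <- matrix(0, n, 3)
  cells <- new_cells(rep("fibroblast", 5), seq(2, 26, length.out = 5),
                     rep(0.5, 5), 0L, 0L, 0, FALSE)
  out <- displace_cells(cells, m, zero, ct, Om, zero, zero,
                        matrix(0, n, 2), 0.1, p, random_walk = FALSE)
  speed <- sqrt(rowSums(out$active^2)) / 0.1
  expect_true(all(speed <= p$v + 1e-9))
  # all terms zero: position unchanged
  out0 <- displace_cells(cells, m, zero, zero, Om, zero, zero,
                         matrix(0, n, 2), 0.1, p, random_walk = FALSE)
  expect_equal(out0$cells$x, cells$x)
  expect_equal(out0$cells$y, cells$y)
})

test_that("motility and chemotaxis constants evaluate as specified", {
  p <- cell_params()
  expect_equal(p$alpha_i, 1 * 2.5^3 / (0.2 * 10))      # 7.8125
  expect_equal(p$alpha_i, 7.8125)
  # wound interior at t = 0: rho_f = 1/alpha_rho, rho_c = 0 -> mu_c = 1.25
  expect_equal(2.5 * (1 - 1e4 * (1e-4 + 0) / 2), 1.25)
})

test_that("cell population bookkeeping is consistent", {
  a <- new_cells("fibroblast", 1, 2, 0L, 0L, 0, FALSE)
  b <- new_cells("macrophage", 3, 4, 0L, 0L, 1, FALSE)
  ab <- cells_bind(a, b)
  expect_equal(n_cells(ab), 2L)
  expect_equal(cells_subset(ab, c(FALSE, TRUE))$phenotype, "macrophage")
  expect_error(new_cells("neuron", 0, 0, 0L, 0L, 0, FALSE))
})
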