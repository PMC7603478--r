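# Mesh construction, P1 assembly, Dirac and line loads, mesh motion.

test_that("structured mesh resolves domain and wound geometry exactly", {
  m <- small_mesh()
  expect_equal(shoelace_area(wound_polygon(m)), 1200)   # 40 x 30 rectangle
  expect_true(all(signed_areas(m$nodes, m$tri) > 0))
  expect_gt(sum(m$boundary_tag == "wound_interface"), 0)
  expect_gt(sum(m$boundary_tag == "outer"), 0)
  # wound interface edges lie exactly on the wound rectangle
  we <- m$boundary_edges[m$boundary_tag == "wound_interface", , drop = FALSE]
  pts <- m$nodes[unique(as.vector(we)), , drop = FALSE]
  on_rect <- (abs(abs(pts[, 1]) - 20) < 1e-9 & abs(pts[, 2]) <= 15 + 1e-9) |
    (abs(abs(pts[, 2]) - 15) < 1e-9 & abs(pts[, 1]) <= 20 + 1e-9)
  expect_true(all(on_rect))
  # wound polygon is a simple closed rectangle walk
  expect_true(length(m$wound_node_ids) >= 8)
})

test_that("degenerate geometry is rejected and tiny meshes stay oriented", {
  expect_error(build_rect_mesh(10, 10, 10, 5, 1), "invalid geometry")
  expect_error(build_rect_mesh(10, 10, 5, 5, -1), "invalid geometry")
  m <- build_rect_mesh(1, 1, 0.5, 0.5, 0.5)
  expect_true(all(signed_areas(m$nodes, m$tri) > 0))
})

test_that("halving the target edge refines the triangle count about 4x", {
  m1 <- build_rect_mesh(60, 40, 20, 15, 5)
  m2 <- build_rect_mesh(60, 40, 20, 15, 2.5)
  ratio <- nrow(m2$tri) / nrow(m1$tri)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.6)
})

test_that("static-mesh transport with D = 0 and no source is the identity", {
  m <- tiny_mesh()
  c0 <- runif(nrow(m$nodes))
  c1 <- transport_step(c0, m, m, D = 0, kappa = 0, dt = 0.1)
  expect_equal(as.numeric(c1), c0, tolerance = 1e-12)
})

test_that("mass is conserved over 100 steps with kappa = 0", {
  m <- tiny_mesh()
  M <- mass_matrix(m)
  c0 <- runif(nrow(m$nodes))
  mass0 <- sum(M %*% c0)
  cc <- c0
  for (i in 1:100) cc <- transport_step(cc, m, m, D = 3, kappa = 0, dt = 0.05)
  expect_lt(abs(sum(M %*% cc) - mass0) / mass0, 1e-10)
})

test_that("with kappa > 0 and no source the mass strictly decreases", {
  m <- tiny_mesh()
  M <- mass_matrix(m)
  cc <- rep(1, nrow(m$nodes))
  prev <- sum(M %*% cc)
  for (i in 1:20) {
    cc <- transport_step(cc, m, m, D = 3, kappa = 0.5, dt = 0.05)
    cur <- sum(M %*% cc)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("diffusion step converges at order >= 1.8 (manufactured solution)", {
  # c(x, t) = 2 + exp(-t) cos(x) solves c_t - Delta c = 0 on (-pi, pi)
  # with zero Neumann flux at x = +-pi (kept positive since the solver
  # enforces non-negative concentrations); dt ~ h^2 keeps the time error
  # subordinate to the spatial one
  errs <- vapply(c(0.3, 0.15), function(h) {
    m <- build_rect_mesh(pi, 1, pi / 2, 0.5, h)
    cc <- 2 + cos(m$nodes[, 1])
    Tend <- 0.2
    dt <- h^2 / 8
    nst <- round(Tend / dt)
    for (i in seq_len(nst)) cc <- transport_step(cc, m, m, D = 1, kappa = 0, dt = dt)
    ex <- 2 + exp(-nst * dt) * cos(m$nodes[, 1])
    M <- mass_matrix(m)
    sqrt(as.numeric((cc - ex) %*% (M %*% (cc - ex))))
  }, numeric(1))
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 1.8)
})

test_that("Dirac point loads conserve magnitude and respect barycentrics", {
  m <- small_mesh()
  # at a node: all weight on it
  L <- dirac_point_load(m, m$nodes[17, , drop = FALSE], 1)
  expect_equal(L[17], 1, tolerance = 1e-12)
  expect_equal(sum(L), 1, tolerance = 1e-12)
  # at a centroid: equal thirds
  cent <- (m$nodes[m$tri[3, 1], ] + m$nodes[m$tri[3, 2], ] + m$nodes[m$tri[3, 3], ]) / 3
  L <- dirac_point_load(m, rbind(cent), 1)
  expect_equal(sort(L[L > 1e-15]), rep(1 / 3, 3), tolerance = 1e-12)
  # arbitrary interior points: partition of unity
  set.seed(3)
  pts <- cbind(runif(50, -55, 55), runif(50, -35, 35))
  L <- dirac_point_load(m, pts, rep(2.5 / 50, 50))
  expect_equal(sum(L), 2.5, tolerance = 1e-12)
})

test_that("points outside the domain are snapped with a weight simplex", {
  m <- tiny_mesh()
  L <- dirac_point_load(m, rbind(c(100, 100)), 1)
  expect_equal(sum(L), 1, tolerance = 1e-9)
  expect_true(all(L >= -1e-15))
})

test_that("wound line source integrates to the rate and is symmetric", {
  m <- small_mesh()
  ls <- line_source_load(m, 0.5)
  expect_equal(sum(ls), 0.5, tolerance = 1e-12)
  expect_equal(sum(line_source_load(m, 0)), 0)
  # mirror symmetry x -> -x
  key <- paste(round(-m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mirror <- match(key, paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9)))
  expect_equal(ls, ls[mirror], tolerance = 1e-12)
  expect_error(line_source_load(m, 1, tag = "nope"), "tagged")
})

test_that("mesh displacement moves coordinates only and detects tangling", {
  m <- tiny_mesh()
  n <- nrow(m$nodes)
  expect_equal(displace_mesh(m, matrix(0, n, 2))$nodes, m$nodes)
  # rigid translation preserves areas
  mt <- displace_mesh(m, matrix(rep(c(3, -2), each = n), n, 2))
  expect_equal(signed_areas(mt$nodes, mt$tri), signed_areas(m$nodes, m$tri),
               tolerance = 1e-12)
  # uniform 1% shrink scales total area by 0.9801
  ms <- displace_mesh(m, -0.01 * m$nodes)
  expect_equal(sum(signed_areas(ms$nodes, ms$tri)),
               0.9801 * sum(signed_areas(m$nodes, m$tri)), tolerance = 1e-10)
  # gross fold-over must abort
  u_bad <- matrix(0, n, 2)
  u_bad[1, ] <- c(50, 50)
  expect_error(displace_mesh(m, u_bad), "tangling")
})

test_that("transport assembly rejects inconsistent inputs", {
  m <- tiny_mesh()
  m2 <- build_rect_mesh(8, 8, 4, 4, 4)
  expect_error(assemble_transport_matrices(m, m2, 1, 0, 0.1), "connectivity")
  expect_error(transport_step(rep(1, nrow(m$nodes)), m, m, D = -1, kappa = 0, dt = 0.1),
               "diffusivity")
})
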