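# Kelvin-Voigt viscoelastic momentum balance on the deforming mesh.
#
# Total stress sigma = sigma_elas + eta * sigma_visco with plane-strain
# isotropic Hooke elasticity and a rate part discretised by backward
# Euler in the total displacement u (measured from the initial
# configuration). The Robin condition sigma.n + kappa_f u = 0 acts on the
# outer boundary; cell forces enter as Dirac point loads.

#' Mechanics parameter set
#'
#' @param E substrate Young's modulus (kg/(\eqn{\mu m} h^2)).
#' @param nu Poisson ratio (plane strain, `0 < nu < 0.5`).
#' @param eta weight of the viscoelastic stress (dimensionless).
#' @param kappa_f Robin spring constant on the outer boundary (1/\eqn{\mu m}).
#' @param P_f,P_m temporary force magnitude per unit cell-boundary length
#'   for fibroblasts and myofibroblasts (kg \eqn{\mu m}/h^2).
#' @param Q_max saturation magnitude of the plastic force density.
#' @return a named list of class `ws_mech_params`.
#' @export
mechanics_params <- function(E = 50, nu = 0.48, eta = 1, kappa_f = 3,
                             P_f = 8.32, P_m = 33.28, Q_max = 33) {
  if (!(nu > 0 && nu < 0.5)) stop("Poisson ratio must lie in (0, 0.5)")
  if (any(c(E, eta, kappa_f, P_f, P_m, Q_max) < 0)) stop("negative mechanics parameter")
  structure(list(E = E, nu = nu, eta = eta, kappa_f = kappa_f,
                 P_f = P_f, P_m = P_m, Q_max = Q_max),
            class = "ws_mech_params")
}

# Lame-style coefficients for the two stress contributions
mech_coefs <- function(params) {
  E <- params$E; nu <- params$nu
  list(mu_e = E / (2 * (1 + nu)),
       lam_e = E * nu / ((1 + nu) * (1 - 2 * nu)),
       # sigma_visco = E/(2(1+nu)) deps/dt + (2/3) E/(2(1+nu)) div(du/dt) I
       mu_v = E / (4 * (1 + nu)),
       lam_v = E / (3 * (1 + nu)))
}

# value-slot assembly of the vector P1 elasticity-type operator with
# shear mu and dilatation lam, dof ordering (u_x[1..n], u_y[1..n]);
# entries in the fixed (a, b) x (xx, yy, xy, yx) order of vector_asm()
elastic_x <- function(mesh, mu, lam, geom = get_geom(mesh)) {
  area <- geom$area; g <- geom$g
  asm <- vector_asm(mesh)
  xx <- vector("list", 36); q <- 0
  for (a in 1:3) for (b in 1:3) {
    ga1 <- g[, a, 1]; ga2 <- g[, a, 2]
    gb1 <- g[, b, 1]; gb2 <- g[, b, 2]
    q <- q + 1; xx[[q]] <- area * ((2 * mu + lam) * ga1 * gb1 + mu * ga2 * gb2)
    q <- q + 1; xx[[q]] <- area * ((2 * mu + lam) * ga2 * gb2 + mu * ga1 * gb1)
    q <- q + 1; xx[[q]] <- area * (lam * ga1 * gb2 + mu * ga2 * gb1)
    q <- q + 1; xx[[q]] <- area * (lam * ga2 * gb1 + mu * ga1 * gb2)
  }
  agg_apply(asm$agg36, unlist(xx))
}

robin_vector_x <- function(mesh, kappa_f) {
  asm <- vector_asm(mesh)
  re <- asm$robin_edges
  len <- sqrt(rowSums((mesh$nodes[re[, 1], , drop = FALSE] -
                         mesh$nodes[re[, 2], , drop = FALSE])^2))
  v <- kappa_f * c(len / 3, len / 3, len / 6, len / 6)
  agg_apply(asm$aggR, c(v, v))
}

elastic_operator <- function(mesh, mu, lam) {
  spmat(vector_asm(mesh), elastic_x(mesh, mu, lam))
}

#' Solve one time-discrete momentum step
#'
#' Solves for the total displacement `u_new` (from the initial
#' configuration) with strain rate approximated by
#' `(eps(u_new) - eps(u_prev))/dt`:
#' `(A_e + (eta/dt) A_v + R) u_new = f + (eta/dt) A_v u_prev`.
#'
#' @param mesh current `ws_mesh` (operators are assembled on it).
#' @param load n x 2 nodal force matrix.
#' @param u_prev n x 2 total displacement at the previous step.
#' @param dt time step (h).
#' @param params a [mechanics_params()] list.
#' @return n x 2 total displacement.
#' @export
solve_momentum <- function(mesh, load, u_prev, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  n <- nrow(mesh$nodes)
  geom <- get_geom(mesh)
  cf <- mech_coefs(params)
  asm <- vector_asm(mesh)
  xA <- elastic_x(mesh, cf$mu_e, cf$lam_e, geom)
  f <- c(load[, 1], load[, 2])
  if (params$eta > 0) {
    xv <- elastic_x(mesh, cf$mu_v, cf$lam_v, geom)
    Av <- spmat(asm, xv)
    xA <- xA + (params$eta / dt) * xv
    f <- f + (params$eta / dt) * as.numeric(Av %*% c(u_prev[, 1], u_prev[, 2]))
  }
  if (params$kappa_f > 0) xA <- xA + robin_vector_x(mesh, params$kappa_f)
  A <- spmat(asm, xA)
  u <- tryCatch(as.numeric(Matrix::solve(A, f)),
                error = function(e) stop("rigid-mode error: momentum system is singular (kappa_f = 0 leaves rigid modes unconstrained)"))
  cbind(u[seq_len(n)], u[n + seq_len(n)])
}

#' Substrate velocity as a finite difference of displacements
#' @param u_curr,u_prev n x 2 total displacements at consecutive steps.
#' @param dt time step (h).
#' @return n x 2 nodal velocity (\eqn{\mu m}/h).
#' @export
substrate_velocity <- function(u_curr, u_prev, dt) {
  if (dt <= 0) stop("dt must be positive")
  (u_curr - u_prev) / dt
}

#' Temporary cell-boundary forces
#'
#' Each (myo)fibroblast boundary is split into three equal arcs; at each
#' arc midpoint a point force of magnitude `P * 2 pi R / 3` acts along
#' the inward normal (toward the cell centre). The per-cell arc phase is
#' fixed at birth to avoid mesh-aligned artefacts.
#'
#' @param cells a `ws_cells` population (only fibroblasts and
#'   myofibroblasts exert forces).
#' @param mesh current `ws_mesh`.
#' @param params a [mechanics_params()] list.
#' @param R cell radius (\eqn{\mu m}).
#' @return n x 2 nodal force load.
#' @export
temporary_force_load <- function(cells, mesh, params, R = 2.5) {
  n <- nrow(mesh$nodes)
  sel <- which(cells$phenotype %in% c("fibroblast", "myofibroblast"))
  if (!length(sel)) return(matrix(0, n, 2))
  P <- ifelse(cells$phenotype[sel] == "myofibroblast", params$P_m, params$P_f)
  ang <- as.vector(outer(cells$phase[sel], c(0, 2, 4) * pi / 3, "+"))
  cx <- rep(cells$x[sel], 3); cy <- rep(cells$y[sel], 3)
  px <- cx + R * cos(ang); py <- cy + R * sin(ang)
  mag <- rep(P, 3) * (2 * pi * R / 3)
  dirx <- -cos(ang); diry <- -sin(ang)
  dirac_point_load(mesh, cbind(px, py), mag, direction = cbind(dirx, diry))
}

#' Update element exposure times
#'
#' `d tau_i/dt = c_TGF(x_i) * max(0, 1 - alpha_rho rho_c(x_i)) * N_myo_i`
#' where `x_i` is the element centroid and `N_myo_i` counts the
#' myofibroblasts whose disc of radius `R` contains it.
#'
#' @param tau per-element exposure times.
#' @param mesh current `ws_mesh`.
#' @param c_tgf nodal TGF-beta concentrations.
#' @param rho_c nodal collagen densities.
#' @param myo_pos q x 2 myofibroblast positions.
#' @param dt time step (h).
#' @param alpha_rho density normalisation constant.
#' @param R cell radius.
#' @return updated exposure times (non-decreasing).
#' @export
update_exposure <- function(tau, mesh, c_tgf, rho_c, myo_pos, dt,
                            alpha_rho = 1e4, R = 2.5) {
  if (is.null(myo_pos) || NROW(myo_pos) == 0) return(tau)
  cent <- get_centroids(mesh)
  nmyo <- integer(nrow(cent))
  for (k in seq_len(NROW(myo_pos))) {
    d2 <- (cent[, 1] - myo_pos[k, 1])^2 + (cent[, 2] - myo_pos[k, 2])^2
    nmyo <- nmyo + (d2 <= R * R)
  }
  active <- nmyo > 0L
  if (!any(active)) return(tau)
  tric <- mesh$tri[active, , drop = FALSE]
  ctgf_e <- (c_tgf[tric[, 1]] + c_tgf[tric[, 2]] + c_tgf[tric[, 3]]) / 3
  rhoc_e <- (rho_c[tric[, 1]] + rho_c[tric[, 2]] + rho_c[tric[, 3]]) / 3
  tau[active] <- tau[active] +
    dt * ctgf_e * pmax(0, 1 - alpha_rho * rhoc_e) * nmyo[active]
  tau
}

#' Plastic force magnitude
#'
#' Saturating exposure response `Q(tau) = Q_max (1 - exp(-tau))`.
#'
#' @param tau non-negative exposure time(s).
#' @param Q_max saturation magnitude.
#' @return force magnitude in `[0, Q_max)`.
#' @export
plastic_magnitude <- function(tau, Q_max = 33) {
  if (any(tau < 0)) stop("negative exposure time")
  Q_max * (1 - exp(-tau))
}

#' Plastic element-edge forces
#'
#' For each element with non-negligible `Q(tau)`, a point force of
#' magnitude `Q * edge length` acts at each of its three edge midpoints
#' along the unit normal pointing into the element; within regions of
#' uniform exposure the interior contributions cancel, so the net load
#' traces exposure gradients (the wound margin).
#'
#' @param mesh current `ws_mesh`.
#' @param tau per-element exposure times.
#' @param params a [mechanics_params()] list.
#' @return n x 2 nodal force load.
#' @export
plastic_force_load <- function(mesh, tau, params) {
  n <- nrow(mesh$nodes)
  Q <- plastic_magnitude(tau, params$Q_max)
  act <- which(Q > 1e-12)
  if (!length(act)) return(matrix(0, n, 2))
  tri <- mesh$tri[act, , drop = FALSE]
  nodes <- mesh$nodes
  fx <- numeric(n); fy <- numeric(n)
  cent <- tri_centroids(nodes, tri)
  for (k in 1:3) {
    a <- tri[, k]; b <- tri[, (k %% 3) + 1L]
    pa <- nodes[a, , drop = FALSE]; pb <- nodes[b, , drop = FALSE]
    ev <- pb - pa
    len <- sqrt(rowSums(ev^2))
    nrm <- cbind(-ev[, 2], ev[, 1]) / len
    mid <- (pa + pb) / 2
    flip <- rowSums(nrm * (cent - mid)) < 0
    nrm[flip, ] <- -nrm[flip, ]
    f <- Q[act] * len
    # P1 value at an edge midpoint: 1/2 on each endpoint
    fx <- fx + rowsum_vec(c(f * nrm[, 1] / 2, f * nrm[, 1] / 2), c(a, b), n)
    fy <- fy + rowsum_vec(c(f * nrm[, 2] / 2, f * nrm[, 2] / 2), c(a, b), n)
  }
  matrix(c(fx, fy), ncol = 2)
}

#' Elastic strain energy over a set of elements
#'
#' \eqn{\sum_e \tfrac12 \sigma_{elas}(\epsilon) : \epsilon \, |e|} with
#' the plane-strain Hooke stress (the viscous part is rate-based and
#' excluded).
#'
#' @param mesh `ws_mesh` whose geometry defines the gradients.
#' @param u n x 2 total displacement.
#' @param params a [mechanics_params()] list.
#' @param elements logical or integer element selector (default: all).
#' @return scalar energy (non-negative).
#' @export
elastic_strain_energy <- function(mesh, u, params, elements = NULL) {
  geom <- get_geom(mesh)
  tri <- mesh$tri
  if (is.null(elements)) elements <- seq_len(nrow(tri))
  if (is.logical(elements)) elements <- which(elements)
  if (!length(elements)) return(0)
  t2 <- tri[elements, , drop = FALSE]
  g <- geom$g[elements, , , drop = FALSE]
  area <- geom$area[elements]
  ux <- matrix(u[t2, 1], ncol = 3); uy <- matrix(u[t2, 2], ncol = 3)
  dudx <- rowSums(ux * g[, , 1]); dudy <- rowSums(ux * g[, , 2])
  dvdx <- rowSums(uy * g[, , 1]); dvdy <- rowSums(uy * g[, , 2])
  e11 <- dudx; e22 <- dvdy; e12 <- (dudy + dvdx) / 2
  cf <- mech_coefs(params)
  tr <- e11 + e22
  s11 <- 2 * cf$mu_e * e11 + cf$lam_e * tr
  s22 <- 2 * cf$mu_e * e22 + cf$lam_e * tr
  s12 <- 2 * cf$mu_e * e12
  sum(0.5 * (s11 * e11 + s22 * e22 + 2 * s12 * e12) * area)
}
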