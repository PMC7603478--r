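# Symmetric 2x2 orientation tensors for fibrin and collagen, stored
# nodally as columns (T11, T12, T22). The trace is the fibre density;
# the eigenstructure encodes alignment. Advection by the substrate
# velocity is carried by the moving mesh nodes (the same ALE convention
# as the concentrations), leaving pointwise decay/deposition updates.

#' Fibre density of an orientation tensor field
#' @param T_field q x 3 matrix of tensor entries (T11, T12, T22), or a
#'   length-3 vector for a single tensor.
#' @return density (trace) per node.
#' @export
tensor_density <- function(T_field) {
  T_field <- rbind_tensor(T_field)
  T_field[, 1] + T_field[, 3]
}

rbind_tensor <- function(T_field) {
  if (is.null(dim(T_field))) matrix(T_field, ncol = 3) else as.matrix(T_field)
}

#' Anisotropy degree of an orientation tensor
#'
#' `e = 1 - lambda_min / lambda_max`; 0 for isotropic tensors, 1 for
#' rank-1 (fully aligned) tensors. Undefined for `lambda_max <= 0`
#' (returns `NA`).
#'
#' @param T_field q x 3 matrix of tensor entries, or a length-3 vector.
#' @return anisotropy degree in `[0, 1]` per row, `NA` where undefined.
#' @export
anisotropy_degree <- function(T_field) {
  T_field <- rbind_tensor(T_field)
  tr <- T_field[, 1] + T_field[, 3]
  det <- T_field[, 1] * T_field[, 3] - T_field[, 2]^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  lmax <- tr / 2 + disc
  lmin <- tr / 2 - disc
  out <- 1 - lmin / lmax
  out[lmax <= 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' One fibrin decay step
#'
#' Implicit entrywise decay by tPA:
#' `Omega_new = Omega_old / (1 + dt * delta_rho * c_tPA)` per node.
#'
#' @param Omega_f q x 3 fibrin tensor field.
#' @param c_tpa nodal tPA concentrations.
#' @param dt time step (h).
#' @param delta_rho fibrin degradation rate coefficient.
#' @return updated fibrin tensor field.
#' @export
step_fibrin <- function(Omega_f, c_tpa, dt, delta_rho = 0.15) {
  if (dt <= 0) stop("dt must be positive")
  Omega_f <- rbind_tensor(Omega_f)
  fac <- 1 / (1 + dt * delta_rho * pmax(c_tpa, 0))
  Omega_f * fac
}

#' Deposit collagen along active cell motion
#'
#' Each (myo)fibroblast adds, at its position, a rank-1 tensor increment
#' `dt * max(0, 1 - alpha_rho (rho_f + rho_c)) * r r^T` where `r` is the
#' unit direction of its active displacement (total minus passive
#' convection). The Dirac increment is converted to a nodal density by
#' barycentric distribution divided by lumped nodal areas, with the
#' saturation prefactor evaluated at each receiving node so the nodal
#' density approaches the healthy value `1/alpha_rho` without
#' overshooting it.
#'
#' @param Omega_c q x 3 collagen tensor field.
#' @param mesh current `ws_mesh`.
#' @param pos k x 2 (myo)fibroblast positions.
#' @param active_dirs k x 2 unit active-direction vectors (rows of zero
#'   displacement are skipped).
#' @param rho_f,rho_c nodal fibrin and collagen densities.
#' @param dt time step (h).
#' @param alpha_rho density normalisation constant.
#' @param loc optional precomputed [locate_points()] for `pos`.
#' @return updated collagen tensor field.
#' @export
deposit_collagen <- function(Omega_c, mesh, pos, active_dirs, rho_f, rho_c,
                             dt, alpha_rho = 1e4, loc = NULL) {
  Omega_c <- rbind_tensor(Omega_c)
  if (is.null(pos) || NROW(pos) == 0) return(Omega_c)
  nrm <- sqrt(rowSums(active_dirs^2))
  keep <- nrm > 1e-14
  if (!any(keep)) return(Omega_c)
  pos <- pos[keep, , drop = FALSE]
  dirs <- active_dirs[keep, , drop = FALSE] / nrm[keep]
  if (is.null(loc)) loc <- locate_points(mesh, pos)
  else loc <- list(elem = loc$elem[keep], bary = loc$bary[keep, , drop = FALSE])
  tri <- mesh$tri[loc$elem, , drop = FALSE]
  la <- lumped_areas(mesh)
  idx <- as.vector(tri)
  # saturation prefactor evaluated at each receiving node: nodal density
  # approaches (and cannot overshoot) the healthy value 1/alpha_rho
  pref_n <- pmax(0, 1 - alpha_rho * (rho_f + rho_c))
  w <- as.vector(loc$bary) * rep(dt, 3) * pref_n[idx]
  n <- nrow(mesh$nodes)
  add <- function(comp) rowsum_vec(w * rep(comp, 3), idx, n) / la
  a11 <- add(dirs[, 1]^2)
  a12 <- add(dirs[, 1] * dirs[, 2])
  a22 <- add(dirs[, 2]^2)
  # projected Euler step of the saturating deposition ODE: a Dirac
  # increment concentrated on a node can exceed the remaining capacity
  # max(0, 1/alpha_rho - (rho_f + rho_c)) within one step, so the
  # rank-1 addition is rescaled to land exactly on the cap (direction
  # and positive semidefiniteness are preserved)
  tr_add <- a11 + a22
  avail <- pmax(0, 1 / alpha_rho - (rho_f + rho_c))
  scale <- ifelse(tr_add > avail, avail / pmax(tr_add, 1e-300), 1)
  Omega_c[, 1] <- Omega_c[, 1] + a11 * scale
  Omega_c[, 2] <- Omega_c[, 2] + a12 * scale
  Omega_c[, 3] <- Omega_c[, 3] + a22 * scale
  Omega_c
}

#' Wound-averaged collagen ratio
#'
#' `alpha_rho` times the average collagen density over the material
#' wound elements; equals 1 in healthy tissue, so values near 1 indicate
#' a fully re-collagenised wound.
#'
#' @param mesh current `ws_mesh`.
#' @param Omega_c nodal collagen tensor field.
#' @param alpha_rho density normalisation constant.
#' @return dimensionless ratio.
#' @export
collagen_ratio <- function(mesh, Omega_c, alpha_rho = 1e4) {
  rho <- tensor_density(Omega_c)
  geom <- get_geom(mesh)
  w <- which(mesh$wound_elem)
  tri <- mesh$tri[w, , drop = FALSE]
  rho_e <- (rho[tri[, 1]] + rho[tri[, 2]] + rho[tri[, 3]]) / 3
  alpha_rho * sum(rho_e * geom$area[w]) / sum(geom$area[w])
}
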