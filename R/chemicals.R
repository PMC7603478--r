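# Time stepping of the signalling molecules PDGF, TGF-beta and tPA on the
# deforming mesh. PDGF diffuses with a constant coefficient and has no
# source (platelets are inactive after wounding); TGF-beta is secreted as
# a Dirac point source by every viable macrophage; tPA enters along the
# wound interface. The TGF-beta and tPA diffusivities interpolate between
# their minimum (fibrin-rich clot) and maximum (fibrin-free tissue).

#' Fibrin-dependent diffusivity mix
#'
#' \eqn{D(\rho^f) = (\alpha_\rho \rho^f) D_{min} + (1 - \alpha_\rho \rho^f) D_{max}},
#' with \eqn{\alpha_\rho \rho^f} clamped to \[0, 1\] (deposition can
#' transiently overshoot the healthy-tissue density \eqn{1/\alpha_\rho}).
#'
#' @param rho_f fibrin density per node (trace of the fibrin tensor).
#' @param D_min,D_max diffusivity bounds (\eqn{\mu m^2/h}).
#' @param alpha_rho density normalisation (dimensionless, default 1e4).
#' @return nodal diffusivity in `[D_min, D_max]`.
#' @export
mix_diffusivity <- function(rho_f, D_min, D_max, alpha_rho) {
  if (D_min > D_max) stop("D_min exceeds D_max")
  if (any(rho_f < 0)) stop("negative fibrin density")
  s <- pmin(pmax(alpha_rho * rho_f, 0), 1)
  s * D_min + (1 - s) * D_max
}

#' One PDGF step
#' @param c nodal PDGF concentration on `mesh_prev`.
#' @param mesh_prev,mesh_curr meshes before/after the mesh displacement.
#' @param dt time step (h).
#' @param params a [chemistry_params()] list.
#' @return updated nodal concentration.
#' @export
step_pdgf <- function(c, mesh_prev, mesh_curr, dt, params) {
  transport_step(c, mesh_prev, mesh_curr, params$D_PDGF, params$kappa, dt)
}

#' One TGF-beta step
#'
#' Diffusivity mixes with the local fibrin density; each viable
#' macrophage contributes a Dirac source of strength `k_TGF`.
#'
#' @param c nodal TGF-beta concentration.
#' @param macrophage_pos q x 2 positions of viable macrophages.
#' @param rho_f nodal fibrin density.
#' @param mesh_prev,mesh_curr meshes.
#' @param dt time step (h).
#' @param params a [chemistry_params()] list.
#' @return updated nodal concentration.
#' @export
step_tgf <- function(c, macrophage_pos, rho_f, mesh_prev, mesh_curr, dt, params) {
  D <- mix_diffusivity(rho_f, params$D_TGF_min, params$D_TGF_max, params$alpha_rho)
  load <- NULL
  if (!is.null(macrophage_pos) && NROW(macrophage_pos) > 0) {
    load <- dirac_point_load(mesh_curr, macrophage_pos, params$k_TGF)
  }
  transport_step(c, mesh_prev, mesh_curr, D, params$kappa, dt, load = load)
}

#' One tPA step
#'
#' Diffusivity mixes with fibrin density; the source is the normalized
#' line distribution on the wound interface scaled by `k_tPA`.
#'
#' @inheritParams step_tgf
#' @return updated nodal concentration.
#' @export
step_tpa <- function(c, rho_f, mesh_prev, mesh_curr, dt, params) {
  D <- mix_diffusivity(rho_f, params$D_tPA_min, params$D_tPA_max, params$alpha_rho)
  load <- if (params$k_tPA > 0) line_source_load(mesh_curr, params$k_tPA) else NULL
  transport_step(c, mesh_prev, mesh_curr, D, params$kappa, dt, load = load)
}

#' Chemistry parameter set
#'
#' Defaults are the baseline values of the model: constant PDGF
#' diffusivity, fibrin-dependent TGF-beta and tPA diffusivities,
#' per-macrophage TGF-beta secretion and wound-interface tPA secretion.
#'
#' @param D_PDGF PDGF diffusivity (\eqn{\mu m^2/h}).
#' @param D_TGF_min,D_TGF_max TGF-beta diffusivity bounds.
#' @param D_tPA_min,D_tPA_max tPA diffusivity bounds.
#' @param k_TGF TGF-beta secretion rate per macrophage (kg/(\eqn{\mu m^3} h)).
#' @param k_tPA total tPA secretion rate on the wound interface.
#' @param alpha_rho density normalisation constant.
#' @param kappa Robin mass-transfer coefficient on the outer boundary
#'   (1/\eqn{\mu m}). The default 100 makes the outer boundary nearly
#'   absorbing, so signalling molecules stay localised around the wound
#'   and decay once their sources stop; see the methods vignette for the
#'   reading of the printed table value.
#' @param c0_PDGF initial PDGF concentration inside the wound.
#' @param c0_tPA initial tPA concentration on the wound interface.
#' @return a named list of class `ws_chem_params`.
#' @export
chemistry_params <- function(D_PDGF = 10, D_TGF_min = 10.6, D_TGF_max = 100.6,
                             D_tPA_min = 0.711, D_tPA_max = 14.1,
                             k_TGF = 2.5, k_tPA = 0.5, alpha_rho = 1e4,
                             kappa = 100, c0_PDGF = 1, c0_tPA = 1) {
  p <- list(D_PDGF = D_PDGF, D_TGF_min = D_TGF_min, D_TGF_max = D_TGF_max,
            D_tPA_min = D_tPA_min, D_tPA_max = D_tPA_max,
            k_TGF = k_TGF, k_tPA = k_tPA, alpha_rho = alpha_rho,
            kappa = kappa, c0_PDGF = c0_PDGF, c0_tPA = c0_tPA)
  bad <- names(p)[vapply(p, function(x) any(x < 0), logical(1))]
  if (length(bad)) stop("negative chemistry parameter(s): ", paste(bad, collapse = ", "))
  if (D_TGF_min > D_TGF_max || D_tPA_min > D_tPA_max) stop("D_min exceeds D_max")
  class(p) <- "ws_chem_params"
  p
}
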