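# Scalar observables of a simulation state: wound polygon area
# (shoelace), area ratio, wound strain energy, cell counts.

#' Shoelace polygon area
#'
#' `A = 1/2 |sum_i (x_i y_{i+1} - x_{i+1} y_i)|`; the absolute value
#' makes the result orientation-invariant. Vertices must be sorted along
#' the polygon.
#'
#' @param polygon p x 2 matrix of ordered vertices (closed implicitly).
#' @return positive area.
#' @export
shoelace_area <- function(polygon) {
  polygon <- matrix(as.numeric(polygon), ncol = 2)
  p <- nrow(polygon)
  if (p < 3) stop("polygon needs at least 3 vertices")
  i2 <- c(2:p, 1)
  abs(sum(polygon[, 1] * polygon[i2, 2] - polygon[i2, 1] * polygon[, 2])) / 2
}

#' Wound area ratio
#' @param A current wound area.
#' @param A0 initial wound area (positive).
#' @return `A / A0`.
#' @export
area_ratio <- function(A, A0) {
  if (any(A0 <= 0)) stop("initial area must be positive")
  A / A0
}

#' Elastic strain energy over the material wound region
#'
#' @param mesh current `ws_mesh`.
#' @param u n x 2 total displacement.
#' @param params a [mechanics_params()] list.
#' @return non-negative energy.
#' @export
wound_strain_energy <- function(mesh, u, params) {
  elastic_strain_energy(mesh, u, params, elements = mesh$wound_elem)
}

#' First time the wound area has settled
#'
#' The equilibrium time is the first time at which `|dA/dt|` stays below
#' `tol` for `run` consecutive steps; `NA` if never reached.
#'
#' @param t times (h), strictly increasing.
#' @param area wound areas.
#' @param tol area-rate tolerance (\eqn{\mu m^2}/h).
#' @param run required number of consecutive quiet steps.
#' @return equilibrium time or `NA`.
#' @export
equilibrium_time <- function(t, area, tol = 1e-3, run = 50L) {
  n <- length(t)
  if (n < run + 1L) return(NA_real_)
  rate <- abs(diff(area) / diff(t))
  quiet <- rate < tol
  cnt <- 0L
  for (i in seq_along(quiet)) {
    cnt <- if (quiet[i]) cnt + 1L else 0L
    if (cnt >= run) return(t[i - run + 1L])
  }
  NA_real_
}
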