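# Discrete cells: macrophages, fibroblasts, myofibroblasts. Cells are
# circles of fixed radius; overlapping neighbours repel through a Hertz
# contact energy density, stochastic division/differentiation/apoptosis
# follow exponential clocks, and displacement combines repulsion,
# saturating chemotaxis, passive convection with the substrate and a
# small random walk.

#' Cell model parameter set
#'
#' Contact mechanics, motility and event-rate constants. The event-rate
#' additive constants (`div_const`, `apop_rate`, `lambda_appear`) are the
#' quantities resampled by the Monte Carlo layer.
#'
#' @param E_c cell elasticity (kg/(\eqn{\mu m} h^2)).
#' @param F_i traction force parameter entering the motility
#'   `alpha_i = beta_i R^3 / (mu F_i)` only.
#' @param beta_i cell surface mobility (1/h).
#' @param mu cell-substrate friction coefficient.
#' @param R cell radius (\eqn{\mu m}).
#' @param v speed of biased movement (\eqn{\mu m}/h).
#' @param sigma_rw random-walk weight.
#' @param gamma chemotaxis gradient regulariser (concentration-gradient
#'   units). Set to the scale of typical wound-edge gradients so the
#'   chemotactic speed responds to signal strength instead of
#'   saturating; see the methods vignette.
#' @param div_tgf_coef,div_const division rate `div_tgf_coef * c^2 +
#'   div_const` (the constant applies below the strain-energy threshold).
#' @param apop_rate apoptosis rate above the strain-energy threshold.
#' @param myo_tgf_coef,myo_const differentiation rate above the TGF
#'   threshold.
#' @param se_div_threshold,se_apop_threshold strain-energy-density
#'   thresholds gating division and apoptosis (kg/(\eqn{\mu m} h^2)).
#' @param tgf_threshold TGF-beta concentration gating differentiation.
#' @param mature_steps_mother,mature_steps_daughter growth time (steps)
#'   before a mother/daughter fibroblast may divide or differentiate.
#' @param macro_death_rate exponential removal rate of macrophages once
#'   the local PDGF signal has faded (1/h).
#' @param macro_pdgf_threshold PDGF concentration below which macrophage
#'   recruitment stops and the removal clock latches on.
#' @param lambda_appear per-site Poisson rate of macrophage appearance on
#'   the wound interface (1/h).
#' @param init_fibro_density initial fibroblast density in the undamaged
#'   region (cells/\eqn{\mu m^2}).
#' @param init_macro_count initial (resident) macrophage count on the
#'   wound edge; small, since the inflammatory infiltrate arrives
#'   through the influx process over the first days.
#' @param n_entry_sites number of fixed macrophage entry sites equally
#'   spaced on the wound interface (mesh-independent).
#' @return a named list of class `ws_cell_params`.
#' @export
cell_params <- function(E_c = 5, F_i = 10, beta_i = 1, mu = 0.2, R = 2.5,
                        v = 2.5, sigma_rw = 0.01, gamma = 0.02,
                        div_tgf_coef = 20, div_const = 2, apop_rate = 10,
                        myo_tgf_coef = 60, myo_const = 10,
                        se_div_threshold = 0.05, se_apop_threshold = 0.07,
                        tgf_threshold = 0.01,
                        mature_steps_mother = 50, mature_steps_daughter = 100,
                        macro_death_rate = 0.05, macro_pdgf_threshold = 0.05,
                        lambda_appear = 0.04,
                        init_fibro_density = 0.01, init_macro_count = 4,
                        n_entry_sites = 20) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("negative cell parameter")
  if (p$gamma <= 0) stop("gamma must be positive")
  p$alpha_i <- beta_i * R^3 / (mu * F_i)
  class(p) <- "ws_cell_params"
  p
}

#' Construct a cell population
#' @param phenotype character vector in
#'   `c("macrophage", "fibroblast", "myofibroblast")`.
#' @param x,y centre positions (\eqn{\mu m}).
#' @param age age in steps since birth.
#' @param mature_at maturation threshold in steps.
#' @param phase force-arc orientation phase (radians, fixed at birth).
#' @param clock_on logical; macrophage removal clock latched on.
#' @return a `ws_cells` list of parallel vectors.
#' @export
new_cells <- function(phenotype = character(0), x = numeric(0), y = numeric(0),
                      age = integer(0), mature_at = integer(0),
                      phase = numeric(0), clock_on = logical(0)) {
  k <- length(phenotype)
  stopifnot(all(phenotype %in% c("macrophage", "fibroblast", "myofibroblast")))
  structure(list(phenotype = phenotype,
                 x = as.numeric(x), y = as.numeric(y),
                 age = rep_len(as.integer(age), k),
                 mature_at = rep_len(as.integer(mature_at), k),
                 phase = rep_len(as.numeric(phase), k),
                 clock_on = rep_len(as.logical(clock_on), k)),
            class = "ws_cells")
}

n_cells <- function(cells) length(cells$phenotype)

cells_subset <- function(cells, keep) {
  structure(lapply(unclass(cells), function(v) v[keep]), class = "ws_cells")
}

cells_bind <- function(a, b) {
  structure(Map(c, unclass(a), unclass(b)), class = "ws_cells")
}

#' Hertz contact energy density between two cells
#'
#' `M = (1/30) (E_c/pi) (h/R)^{5/2}` with fictitious overlap
#' `h = max(2R - d, 0)`.
#'
#' @param d centre distance(s), or `r_i`/`r_j` positions via `...`.
#' @param R cell radius.
#' @param E_c cell elasticity.
#' @return energy density (0 without overlap).
#' @export
hertz_energy <- function(d, R = 2.5, E_c = 5) {
  h <- pmax(2 * R - d, 0)
  (E_c / (30 * pi)) * (h / R)^2.5
}

# memoized upper-triangle index pairs for small within-bin counts
.pair_tmpl <- new.env(parent = emptyenv())
upper_pairs <- function(na) {
  key <- as.character(na)
  p <- .pair_tmpl[[key]]
  if (is.null(p)) {
    idx <- which(upper.tri(matrix(0, na, na)), arr.ind = TRUE)
    p <- idx
    .pair_tmpl[[key]] <- p
  }
  p
}

# candidate contact pairs within cutoff by uniform binning
contact_pairs <- function(x, y, cutoff) {
  k <- length(x)
  if (k < 2) return(matrix(integer(0), 0, 2))
  bx <- floor(x / cutoff); by <- floor(y / cutoff)
  span <- max(bx) - min(bx) + 3
  key <- (bx - min(bx) + 1) + span * (by - min(by))
  sp <- split(seq_len(k), key)
  keys <- as.numeric(names(sp))
  out <- vector("list", 5 * length(sp)); q <- 0
  offs <- c(0, 1, span - 1, span, span + 1)
  for (b in seq_along(sp)) {
    ia <- sp[[b]]
    for (off in offs) {
      if (off == 0) {
        na <- length(ia)
        if (na >= 2) {
          idx <- upper_pairs(na)
          q <- q + 1; out[[q]] <- cbind(ia[idx[, 1]], ia[idx[, 2]])
        }
      } else {
        hit <- match(keys[b] + off, keys)
        jb <- if (is.na(hit)) NULL else sp[[hit]]
        if (!is.null(jb)) {
          q <- q + 1
          out[[q]] <- cbind(rep(ia, each = length(jb)), rep(jb, length(ia)))
        }
      }
    }
  }
  if (q == 0) return(matrix(integer(0), 0, 2))
  pr <- do.call(rbind, out[seq_len(q)])
  d2 <- (x[pr[, 1]] - x[pr[, 2]])^2 + (y[pr[, 1]] - y[pr[, 2]])^2
  pr[d2 < cutoff^2, , drop = FALSE]
}

#' Net repulsion energy and direction for every cell
#'
#' For each cell, the total contact energy density
#' `M_hat = -sum_j M_ij` (non-positive) and the unit direction `z_hat`
#' pointing away from the net contact pressure
#' (`z = sum_j (-M_ij) e_ij`, normalised). Cells without contacts get
#' `M_hat = 0` and a zero direction; exactly coincident centres are
#' separated by a random direction.
#'
#' @param cells a `ws_cells` population.
#' @param R cell radius.
#' @param E_c cell elasticity.
#' @return list with `M_hat` (length k, `<= 0`) and `z_hat` (k x 2).
#' @export
net_repulsion <- function(cells, R = 2.5, E_c = 5) {
  k <- n_cells(cells)
  M_hat <- numeric(k)
  z <- matrix(0, k, 2)
  if (k >= 2) {
    pr <- contact_pairs(cells$x, cells$y, 2 * R)
    if (nrow(pr)) {
      dx <- cells$x[pr[, 2]] - cells$x[pr[, 1]]
      dy <- cells$y[pr[, 2]] - cells$y[pr[, 1]]
      d <- sqrt(dx^2 + dy^2)
      zero <- d < 1e-12
      if (any(zero)) {     # coincident centres: random separation axis
        th <- runif(sum(zero), 0, 2 * pi)
        dx[zero] <- cos(th) * 1e-9; dy[zero] <- sin(th) * 1e-9
        d[zero] <- 1e-9
      }
      M <- hertz_energy(d, R, E_c)
      ex <- dx / d; ey <- dy / d
      M_hat <- M_hat - rowsum_vec(c(M, M), c(pr[, 1], pr[, 2]), k)
      # z contribution on i: -M e_ij ; on j: -M e_ji = +M e_ij
      z[, 1] <- rowsum_vec(c(-M * ex, M * ex), c(pr[, 1], pr[, 2]), k)
      z[, 2] <- rowsum_vec(c(-M * ey, M * ey), c(pr[, 1], pr[, 2]), k)
    }
  }
  nz <- sqrt(rowSums(z^2))
  has <- nz > 0
  z[has, ] <- z[has, , drop = FALSE] / nz[has]
  list(M_hat = M_hat, z_hat = z)
}

#' Per-step event probability of an exponential clock
#' @param lambda rate (1/h), non-negative.
#' @param dt time step (h).
#' @return probability `1 - exp(-lambda dt)` in `[0, 1)`.
#' @export
event_probability <- function(lambda, dt) {
  if (any(lambda < 0)) stop("negative rate")
  if (dt <= 0) stop("dt must be positive")
  1 - exp(-lambda * dt)
}

#' Stochastic event rates
#'
#' Division: `div_tgf_coef * c^2 + div_const` when the contact strain
#' energy density is below `se_div_threshold` (otherwise the constant is
#' dropped). Apoptosis: `apop_rate` when it is at or above
#' `se_apop_threshold`. Differentiation to myofibroblast:
#' `myo_tgf_coef * c^2 + myo_const` when `c > tgf_threshold` (strict),
#' else 0.
#'
#' @param kind one of `"division"`, `"apoptosis"`, `"differentiation"`.
#' @param c_tgf local TGF-beta concentration(s).
#' @param M_hat local contact energy density (its magnitude is used).
#' @param params a [cell_params()] list.
#' @return rate(s) in 1/h.
#' @export
event_rate <- function(kind, c_tgf, M_hat, params = cell_params()) {
  if (any(c_tgf < 0)) stop("negative concentration")
  m <- abs(M_hat)
  switch(kind,
    division = params$div_tgf_coef * c_tgf^2 +
      ifelse(m < params$se_div_threshold, params$div_const, 0),
    apoptosis = ifelse(m >= params$se_apop_threshold, params$apop_rate, 0),
    differentiation = ifelse(c_tgf > params$tgf_threshold,
                             params$myo_tgf_coef * c_tgf^2 + params$myo_const, 0),
    stop("unknown event kind: ", kind))
}

#' Divide a mature fibroblast
#'
#' The mother centre moves by `R` in a uniformly random direction and
#' the daughter appears diametrically opposite; both age clocks reset
#' and the daughter matures more slowly than the mother.
#'
#' @param cells a `ws_cells` population.
#' @param idx index of the dividing fibroblast.
#' @param params a [cell_params()] list.
#' @return the population with the mother moved and the daughter added.
#' @export
divide_cell <- function(cells, idx, params = cell_params()) {
  if (cells$phenotype[idx] != "fibroblast") {
    stop("only regular fibroblasts divide")
  }
  phi <- runif(1, 0, 2 * pi)
  R <- params$R
  x0 <- cells$x[idx]; y0 <- cells$y[idx]
  cells$x[idx] <- x0 + R * cos(phi)
  cells$y[idx] <- y0 + R * sin(phi)
  cells$age[idx] <- 0L
  cells$mature_at[idx] <- as.integer(params$mature_steps_mother)
  daughter <- new_cells("fibroblast", x0 - R * cos(phi), y0 - R * sin(phi),
                        age = 0L,
                        mature_at = as.integer(params$mature_steps_daughter),
                        phase = runif(1, 0, 2 * pi), clock_on = FALSE)
  cells_bind(cells, daughter)
}

#' Spawn macrophages on the wound interface
#'
#' Each candidate site runs an independent Bernoulli trial with
#' `p = 1 - exp(-lambda dt)` per step; accepted sites receive a new
#' macrophage at the site position.
#'
#' @param sites s x 2 candidate positions (wound-interface nodes).
#' @param lambda_appear per-site appearance rate (1/h).
#' @param dt time step (h).
#' @return a `ws_cells` population of new macrophages (possibly empty).
#' @export
spawn_macrophages <- function(sites, lambda_appear, dt) {
  sites <- matrix(as.numeric(sites), ncol = 2)
  if (nrow(sites) == 0L || lambda_appear <= 0) return(new_cells())
  p <- event_probability(lambda_appear, dt)
  hit <- runif(nrow(sites)) < p
  if (!any(hit)) return(new_cells())
  k <- sum(hit)
  new_cells(rep("macrophage", k), sites[hit, 1], sites[hit, 2],
            age = 0L, mature_at = 0L,
            phase = runif(k, 0, 2 * pi), clock_on = FALSE)
}

#' Displace all cells over one step
#'
#' Macrophages drift up the PDGF gradient; (myo)fibroblasts drift up the
#' TGF-beta gradient, with the chemotactic response premultiplied by
#' `(1 - a) I + a Omega_hat_c` (`a = alpha_rho rho_c`,
#' `Omega_hat_c` the trace-normalised collagen orientation; set
#' `literal_collagen_weight = TRUE` to use the unnormalised tensor as
#' printed in the governing equation). All cells share the repulsion
#' drift `alpha_i |M_hat| z_hat`, passive convection with the substrate
#' and an isotropic random walk; positions reflect at the outer boundary.
#'
#' @param cells a `ws_cells` population.
#' @param mesh current `ws_mesh`.
#' @param c_pdgf,c_tgf nodal concentrations.
#' @param Omega_c nodal collagen tensor field (q x 3).
#' @param rho_f,rho_c nodal fibrin/collagen densities.
#' @param v_nodal n x 2 substrate velocity.
#' @param dt time step (h).
#' @param params a [cell_params()] list.
#' @param alpha_rho density normalisation constant.
#' @param random_walk logical toggle.
#' @param literal_collagen_weight use the literal density-scaled collagen
#'   weighting (see Details).
#' @return list with `cells` (moved) and `active` (k x 2 active
#'   displacement, total minus passive convection).
#' @export
displace_cells <- function(cells, mesh, c_pdgf, c_tgf, Omega_c, rho_f, rho_c,
                           v_nodal, dt, params = cell_params(),
                           alpha_rho = 1e4, random_walk = TRUE,
                           literal_collagen_weight = FALSE) {
  k <- n_cells(cells)
  if (k == 0L) return(list(cells = cells, active = matrix(0, 0, 2)))
  pos <- cbind(cells$x, cells$y)
  loc <- locate_points(mesh, pos)
  tri <- mesh$tri[loc$elem, , drop = FALSE]
  interp <- function(v) rowSums(matrix(v[tri], ncol = 3) * loc$bary)
  geom <- get_geom(mesh)
  grad_of <- function(v) {  # P1 gradient, constant per element
    vv <- matrix(v[tri], ncol = 3)
    cbind(rowSums(vv * geom$g[loc$elem, , 1]),
          rowSums(vv * geom$g[loc$elem, , 2]))
  }

  rep_ <- net_repulsion(cells, params$R, params$E_c)
  drift <- params$alpha_i * abs(rep_$M_hat) * rep_$z_hat

  mu_c <- params$v * pmax(0, 1 - alpha_rho * (interp(rho_f) + interp(rho_c)) / 2)
  is_mac <- cells$phenotype == "macrophage"
  chemo <- matrix(0, k, 2)
  if (any(is_mac)) {
    gp <- grad_of(c_pdgf)[is_mac, , drop = FALSE]
    gn <- sqrt(rowSums(gp^2))
    chemo[is_mac, ] <- mu_c[is_mac] * gp / (gn + params$gamma)
  }
  if (any(!is_mac)) {
    sel <- which(!is_mac)
    gt <- grad_of(c_tgf)[sel, , drop = FALSE]
    gn <- sqrt(rowSums(gt^2))
    dir <- gt / (gn + params$gamma)
    a <- pmin(pmax(alpha_rho * interp(rho_c)[sel], 0), 1)
    # collagen weighting matrix applied to the saturated gradient
    o11 <- interp(Omega_c[, 1])[sel]
    o12 <- interp(Omega_c[, 2])[sel]
    o22 <- interp(Omega_c[, 3])[sel]
    if (!literal_collagen_weight) {
      tr <- o11 + o22
      ok <- tr > 1e-300
      o11 <- ifelse(ok, o11 / tr, 0.5); o22 <- ifelse(ok, o22 / tr, 0.5)
      o12 <- ifelse(ok, o12 / tr, 0)
      a <- ifelse(ok, a, 0)
    }
    # literal form keeps Omega_c in density units (then a * o is O(rho))
    w11 <- (1 - a) + a * o11; w12 <- a * o12; w22 <- (1 - a) + a * o22
    chemo[sel, 1] <- mu_c[sel] * (w11 * dir[, 1] + w12 * dir[, 2])
    chemo[sel, 2] <- mu_c[sel] * (w12 * dir[, 1] + w22 * dir[, 2])
  }

  passive <- cbind(interp(v_nodal[, 1]), interp(v_nodal[, 2]))
  rw <- if (random_walk) {
    params$sigma_rw * sqrt(dt) * matrix(rnorm(2 * k), k, 2)
  } else matrix(0, k, 2)

  active <- (drift + chemo) * dt + rw
  newpos <- pos + active + passive * dt

  # reflect at the outer rectangle
  g <- mesh$geom
  newpos[, 1] <- reflect_into(newpos[, 1], -g["x0"], g["x0"])
  newpos[, 2] <- reflect_into(newpos[, 2], -g["y0"], g["y0"])

  cells$x <- newpos[, 1]; cells$y <- newpos[, 2]
  list(cells = cells, active = active)
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
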