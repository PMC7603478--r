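# Orchestration of one simulation: initial conditions, the fixed
# operator-splitting sweep, observable recording.
#
# Sweep order per step: (1) stochastic cell events (spawn, apoptosis,
# differentiation, division); (2) chemical field ALE steps; (3) exposure
# update and force loads; (4) momentum solve, substrate velocity, mesh
# displacement; (5) cell displacement SDEs with the new velocity;
# (6) tensor updates with the active directions; (7) observables.

#' Initialize the full simulation state
#'
#' Initial conditions: PDGF equals `c0_PDGF` inside the wound and 0
#' outside; TGF-beta is 0; tPA equals `c0_tPA` on the wound interface
#' nodes; the fibrin tensor is `I/(2 alpha_rho)` inside the wound, the
#' collagen tensor the same outside; displacements, exposure times and
#' stresses are zero; fibroblasts are seeded uniformly at random over
#' the undamaged region, macrophages equally spaced on the wound
#' interface, and there are no myofibroblasts.
#'
#' @param config a [sim_config()].
#' @return state list (mesh, fields, tensors, cells, clocks).
#' @export
initialize_state <- function(config) {
  mesh <- build_rect_mesh(config$x0, config$y0, config$xw, config$yw,
                          config$target_edge)
  n <- nrow(mesh$nodes)
  in_wound <- abs(mesh$nodes[, 1]) < config$xw - 1e-9 &
    abs(mesh$nodes[, 2]) < config$yw - 1e-9
  on_edge <- rep(FALSE, n); on_edge[mesh$wound_node_ids] <- TRUE
  inside <- in_wound | on_edge

  c_pdgf <- ifelse(inside, config$chem$c0_PDGF, 0)
  c_tgf <- numeric(n)
  c_tpa <- ifelse(on_edge, config$chem$c0_tPA, 0)

  iso <- 1 / (2 * config$alpha_rho)
  Om_f <- cbind(ifelse(inside, iso, 0), 0, ifelse(inside, iso, 0))
  Om_c <- cbind(ifelse(inside, 0, iso), 0, ifelse(inside, 0, iso))

  streams <- rng_streams(config$seed)
  cells <- with_stream(streams, "init", init_cells(mesh, config))

  # fixed macrophage entry sites: the wound-interface nodes closest to
  # n_entry_sites equally spaced perimeter points (material nodes, so
  # the sites move with the tissue and the influx intensity does not
  # scale with mesh resolution)
  sites <- perimeter_points(mesh, max(1L, as.integer(config$cellp$n_entry_sites)))
  entry_nodes <- vapply(seq_len(nrow(sites)), function(k) {
    d2 <- (mesh$nodes[mesh$wound_node_ids, 1] - sites[k, 1])^2 +
      (mesh$nodes[mesh$wound_node_ids, 2] - sites[k, 2])^2
    mesh$wound_node_ids[which.min(d2)]
  }, integer(1))

  list(mesh = mesh, mesh_old = mesh, mesh0 = mesh,
       entry_nodes = unique(entry_nodes),
       u = matrix(0, n, 2), u_prev = matrix(0, n, 2),
       tau = numeric(nrow(mesh$tri)),
       c_pdgf = c_pdgf, c_tgf = c_tgf, c_tpa = c_tpa,
       Om_f = Om_f, Om_c = Om_c,
       cells = cells, streams = streams,
       t = 0, step = 0L,
       A0 = shoelace_area(wound_polygon(mesh)))
}

# n points equally spaced along the wound interface perimeter
perimeter_points <- function(mesh, n) {
  poly <- wound_polygon(mesh)
  per <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(per)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n + 1L)[-(n + 1L)]
  i <- findInterval(tgt, s, rightmost.closed = TRUE)
  w <- (tgt - s[i]) / seg[i]
  cbind(per[i, 1] + w * (per[i + 1L, 1] - per[i, 1]),
        per[i, 2] + w * (per[i + 1L, 2] - per[i, 2]))
}

init_cells <- function(mesh, config) {
  g <- mesh$geom
  cp <- config$cellp
  A_und <- 4 * g["x0"] * g["y0"] - 4 * g["xw"] * g["yw"]
  n_f <- max(0L, round(cp$init_fibro_density * A_und))
  xs <- ys <- numeric(0)
  while (length(xs) < n_f) {
    m <- 2 * (n_f - length(xs)) + 8
    cx <- runif(m, -g["x0"], g["x0"]); cy <- runif(m, -g["y0"], g["y0"])
    ok <- !(abs(cx) < g["xw"] & abs(cy) < g["yw"])
    xs <- c(xs, cx[ok])[seq_len(min(n_f, length(xs) + sum(ok)))]
    ys <- c(ys, cy[ok])[seq_len(length(xs))]
  }
  fib <- new_cells(rep("fibroblast", n_f), xs, ys, age = cp$mature_steps_mother,
                   mature_at = cp$mature_steps_mother,
                   phase = runif(n_f, 0, 2 * pi), clock_on = FALSE)
  # resident macrophages on an evenly spread subset of the entry sites
  n_m <- as.integer(cp$init_macro_count)
  if (n_m > 0) {
    sites <- perimeter_points(mesh, max(n_m, as.integer(cp$n_entry_sites)))
    pick <- unique(floor(seq(0, nrow(sites) - 1, length.out = n_m)) + 1L)
    mac <- new_cells(rep("macrophage", length(pick)),
                     sites[pick, 1], sites[pick, 2], age = 0L, mature_at = 0L,
                     phase = runif(length(pick), 0, 2 * pi), clock_on = FALSE)
    cells_bind(fib, mac)
  } else fib
}

# stage 1: stochastic events; returns updated cells
step_events <- function(state, config) {
  cells <- state$cells
  cp <- config$cellp
  dt <- config$dt
  mesh <- state$mesh

  # macrophage influx at the fixed entry sites while the local PDGF
  # signal persists (recruitment is PDGF-driven)
  sites <- mesh$nodes[state$entry_nodes, , drop = FALSE]
  site_pdgf <- state$c_pdgf[state$entry_nodes]
  site_ok <- site_pdgf >= cp$macro_pdgf_threshold
  if (any(site_ok)) {
    born <- with_stream(state$streams, "spawn",
                        spawn_macrophages(sites[site_ok, , drop = FALSE],
                                          cp$lambda_appear, dt))
    if (n_cells(born)) cells <- cells_bind(cells, born)
  }

  k <- n_cells(cells)
  if (k == 0L) { state$cells <- cells; return(state) }

  loc <- locate_points(mesh, cbind(cells$x, cells$y))
  tri <- mesh$tri[loc$elem, , drop = FALSE]
  ctgf <- rowSums(matrix(state$c_tgf[tri], ncol = 3) * loc$bary)
  cpdgf <- rowSums(matrix(state$c_pdgf[tri], ncol = 3) * loc$bary)
  rep_ <- with_stream(state$streams, "events", net_repulsion(cells, cp$R, cp$E_c))
  m <- abs(rep_$M_hat)

  is_mac <- cells$phenotype == "macrophage"
  is_fib <- cells$phenotype == "fibroblast"
  is_myo <- cells$phenotype == "myofibroblast"
  mature <- cells$age >= cells$mature_at

  # latch macrophage removal clocks once local PDGF has faded
  cells$clock_on <- cells$clock_on | (is_mac & cpdgf < cp$macro_pdgf_threshold)

  # crowding apoptosis applies to (myo)fibroblasts; macrophage removal is
  # its own PDGF-gated exponential clock
  lam_a <- ifelse(is_mac, 0, event_rate("apoptosis", ctgf, m, cp))
  lam_a[is_mac & cells$clock_on] <- cp$macro_death_rate
  # differentiation happens to fibroblasts that have entered the wound
  in_wound <- mesh$wound_elem[loc$elem]
  lam_dif <- ifelse(is_fib & mature & in_wound,
                    event_rate("differentiation", ctgf, m, cp), 0)
  lam_div <- ifelse(is_fib & mature, event_rate("division", ctgf, m, cp), 0)

  u <- with_stream(state$streams, "events", matrix(runif(3 * k), k, 3))
  die <- u[, 1] < event_probability(lam_a, dt)
  diff_ <- !die & u[, 2] < event_probability(lam_dif, dt)
  div <- !die & !diff_ & u[, 3] < event_probability(lam_div, dt)

  cells$phenotype[diff_] <- "myofibroblast"
  cells$age <- cells$age + 1L

  div_idx <- which(div)
  if (length(div_idx)) {
    for (i in rev(div_idx)) {   # reverse: indices stay valid while appending
      cells <- with_stream(state$streams, "division", divide_cell(cells, i, cp))
    }
  }
  if (any(die)) cells <- cells_subset(cells, !die)
  state$cells <- cells
  state
}

#' Advance the simulation by one step
#'
#' @param state state list from [initialize_state()].
#' @param config a [sim_config()].
#' @return updated state.
#' @export
sim_step <- function(state, config) {
  dt <- config$dt
  if (config$events_on) state <- step_events(state, config)

  # (2) chemical fields: ALE step from the mesh before the last
  # displacement to the current one
  rho_f <- tensor_density(state$Om_f)
  state$c_pdgf <- step_pdgf(state$c_pdgf, state$mesh_old, state$mesh, dt, config$chem)
  mac <- state$cells$phenotype == "macrophage"
  mac_pos <- cbind(state$cells$x[mac], state$cells$y[mac])
  state$c_tgf <- step_tgf(state$c_tgf, mac_pos, rho_f,
                          state$mesh_old, state$mesh, dt, config$chem)
  state$c_tpa <- step_tpa(state$c_tpa, rho_f, state$mesh_old, state$mesh, dt, config$chem)

  # (3) exposure + force loads
  myo <- state$cells$phenotype == "myofibroblast"
  rho_c <- tensor_density(state$Om_c)
  state$tau <- update_exposure(state$tau, state$mesh, state$c_tgf, rho_c,
                               cbind(state$cells$x[myo], state$cells$y[myo]),
                               dt, config$alpha_rho, config$cellp$R)
  n <- nrow(state$mesh$nodes)
  load <- matrix(0, n, 2)
  if (config$forces_on) {
    load <- temporary_force_load(state$cells, state$mesh, config$mech,
                                 R = config$cellp$R) +
      plastic_force_load(state$mesh, state$tau, config$mech)
  }

  # (4) momentum, velocity, mesh motion
  u_new <- solve_momentum(state$mesh, load, state$u, dt, config$mech)
  v <- substrate_velocity(u_new, state$u, dt)
  state$mesh_old <- state$mesh
  state$mesh <- displace_mesh(state$mesh, u_new - state$u)
  state$u_prev <- state$u
  state$u <- u_new

  # (5) cell displacement with the new substrate velocity
  rho_f <- tensor_density(state$Om_f)
  disp <- with_stream(state$streams, "walk",
                      displace_cells(state$cells, state$mesh, state$c_pdgf,
                                     state$c_tgf, state$Om_c, rho_f, rho_c,
                                     v, dt, config$cellp, config$alpha_rho,
                                     random_walk = config$random_walk,
                                     literal_collagen_weight = config$literal_collagen_weight))
  state$cells <- disp$cells

  # (6) tensors: fibrin decay, collagen deposition along active motion
  state$Om_f <- step_fibrin(state$Om_f, state$c_tpa, dt, config$delta_rho)
  fb <- state$cells$phenotype %in% c("fibroblast", "myofibroblast")
  if (any(fb)) {
    state$Om_c <- deposit_collagen(state$Om_c, state$mesh,
                                   cbind(state$cells$x[fb], state$cells$y[fb]),
                                   disp$active[fb, , drop = FALSE],
                                   rho_f, tensor_density(state$Om_c),
                                   dt, config$alpha_rho)
  }

  state$t <- state$t + dt
  state$step <- state$step + 1L
  state
}

observe <- function(state, config) {
  A <- shoelace_area(wound_polygon(state$mesh))
  ph <- state$cells$phenotype
  c(t_h = state$t,
    area_um2 = A,
    ratio = A / state$A0,
    strain_energy = wound_strain_energy(state$mesh, state$u, config$mech),
    n_macro = sum(ph == "macrophage"),
    n_fibro = sum(ph == "fibroblast"),
    n_myo = sum(ph == "myofibroblast"),
    n_total = length(ph),
    mean_tgf = mean(state$c_tgf),
    collagen_ratio = collagen_ratio(state$mesh, state$Om_c, config$alpha_rho),
    max_tgf = max(state$c_tgf))
}

#' Run a full simulation
#'
#' Steps the model to the horizon, recording the observable time series
#' and the headline contraction summary (minimal/final/day-4 areas and
#' their times, collagen ratios at those times, equilibrium time).
#'
#' @param config a [sim_config()].
#' @param progress print progress every `progress` hours (0 = quiet).
#' @return data frame of class `ws_timeseries` with one row per step;
#'   the summary is in `attr(, "summary")`.
#' @export
run_simulation <- function(config, progress = 0) {
  state <- initialize_state(config)
  n_steps <- ceiling(config$horizon / config$dt - 1e-9)
  rows <- matrix(NA_real_, n_steps + 1L, 11L)
  rows[1L, ] <- observe(state, config)
  for (s in seq_len(n_steps)) {
    state <- sim_step(state, config)
    rows[s + 1L, ] <- observe(state, config)
    if (progress > 0 && s %% round(progress / config$dt) == 0) {
      message(sprintf("t = %.1f h, cells = %d, ratio = %.4f",
                      state$t, n_cells(state$cells), rows[s + 1L, 3]))
    }
  }
  ts <- as.data.frame(rows)
  names(ts) <- c("t_h", "area_um2", "ratio", "strain_energy", "n_macro",
                 "n_fibro", "n_myo", "n_total", "mean_tgf", "collagen_ratio",
                 "max_tgf")
  class(ts) <- c("ws_timeseries", "data.frame")
  attr(ts, "summary") <- summarize_run(ts, config)
  attr(ts, "final_state") <- state
  ts
}

summarize_run <- function(ts, config) {
  i_min <- which.min(ts$area_um2)
  i_day4 <- which.min(abs(ts$t_h - 96))
  n_eq <- equilibrium_time(ts$t_h, ts$area_um2, config$equil_tol, config$equil_run)
  list(A0 = ts$area_um2[1],
       n = if (is.na(n_eq)) ts$t_h[nrow(ts)] else n_eq,
       n_min = ts$t_h[i_min],
       Area_final = ts$area_um2[nrow(ts)],
       Area_min = ts$area_um2[i_min],
       Area_4days = ts$area_um2[i_day4],
       rho_c_hat_final = ts$collagen_ratio[nrow(ts)],
       rho_c_hat_min = ts$collagen_ratio[i_min],
       t_peak_mean_tgf = ts$t_h[which.max(ts$mean_tgf)],
       t_peak_max_tgf = ts$t_h[which.max(ts$max_tgf)])
}

#' Write the canonical time-series CSV
#'
#' Columns: `t_h, area_um2, ratio, strain_energy, n_macro, n_fibro,
#' n_myo, n_total, mean_tgf, collagen_ratio`.
#'
#' @param ts a `ws_timeseries`.
#' @param path output file.
#' @export
write_timeseries_csv <- function(ts, path) {
  cols <- c("t_h", "area_um2", "ratio", "strain_energy", "n_macro",
            "n_fibro", "n_myo", "n_total", "mean_tgf", "collagen_ratio")
  write.csv(ts[, cols], path, row.names = FALSE)
  invisible(path)
}
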