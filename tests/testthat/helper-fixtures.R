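# Shared fixtures: small meshes and cached runs (built once per session).

.fixture_env <- new.env(parent = emptyenv())

small_mesh <- function(edge = 5) {
  key <- paste0("mesh_", edge)
  m <- .fixture_env[[key]]
  if (is.null(m)) {
    m <- build_rect_mesh(60, 40, 20, 15, edge)
    .fixture_env[[key]] <- m
  }
  m
}

tiny_mesh <- function() {
  m <- .fixture_env$tiny
  if (is.null(m)) {
    m <- build_rect_mesh(8, 8, 4, 4, 2)
    .fixture_env$tiny <- m
  }
  m
}

# default-resolution baseline run shared by the behavioural acceptance
# tests; 500 h covers inflammation, peak contraction and recovery
cached_baseline <- function() {
  ts <- .fixture_env$baseline
  if (is.null(ts)) {
    cfg <- sim_config(target_edge = 5, horizon = 500, seed = 42L)
    ts <- run_simulation(cfg)
    .fixture_env$baseline <- ts
  }
  ts
}

# coarse-mesh baseline shared as the middle point of the sensitivity
# comparisons (paired seed with coarse_run)
cached_coarse_baseline <- function() {
  ts <- .fixture_env$coarse_baseline
  if (is.null(ts)) {
    ts <- coarse_run()
    .fixture_env$coarse_baseline <- ts
  }
  ts
}

coarse_run <- function(horizon = 250, seed = 7L, ...) {
  cfg <- sim_config(target_edge = 10, horizon = horizon, seed = seed, ...)
  run_simulation(cfg)
}

# mean contraction depth over a run: robust summary of an area curve
contraction_integral <- function(ts) mean(1 - ts$ratio)
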