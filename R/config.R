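# Simulation configuration: every numeric default is either a table
# value of the model or a documented design choice (see the methods
# vignette). Geometry values are half-lengths of the standard layout:
# domain (-60,60) x (-40,40), wound (-20,20) x (-15,15) micrometre.

#' Simulation configuration
#'
#' @param x0,y0 domain half-width/height (\eqn{\mu m}).
#' @param xw,yw wound half-lengths (\eqn{\mu m}).
#' @param target_edge mesh spacing (\eqn{\mu m}); 5 resolves one cell
#'   diameter per element edge.
#' @param dt time step (h).
#' @param horizon simulated time (h).
#' @param seed master seed; all stochastic substreams derive from it.
#' @param chem a [chemistry_params()] list.
#' @param mech a [mechanics_params()] list.
#' @param cellp a [cell_params()] list.
#' @param delta_rho fibrin degradation rate coefficient.
#' @param alpha_rho density normalisation (shared by all modules).
#' @param forces_on master toggle for cell forces (temporary + plastic).
#' @param events_on master toggle for stochastic cell events.
#' @param random_walk toggle for the cell Wiener term.
#' @param literal_collagen_weight see [displace_cells()].
#' @param equil_tol,equil_run equilibrium detection (see
#'   [equilibrium_time()]).
#' @return a list of class `ws_config`.
#' @export
sim_config <- function(x0 = 60, y0 = 40, xw = 20, yw = 15,
                       target_edge = 5, dt = 0.1, horizon = 700,
                       seed = 1L,
                       chem = chemistry_params(),
                       mech = mechanics_params(),
                       cellp = cell_params(),
                       delta_rho = 0.15, alpha_rho = 1e4,
                       forces_on = TRUE, events_on = TRUE,
                       random_walk = TRUE,
                       literal_collagen_weight = FALSE,
                       equil_tol = 1e-3, equil_run = 50L) {
  if (dt <= 0) stop("dt must be positive")
  if (horizon < dt) stop("horizon must be at least one step")
  stopifnot(inherits(chem, "ws_chem_params"),
            inherits(mech, "ws_mech_params"),
            inherits(cellp, "ws_cell_params"))
  structure(as.list(environment()), class = "ws_config")
}

# --- reproducible named substreams -----------------------------------
# One master seed spawns independent substreams ("events", "walk",
# "division", "spawn", "init"); draws for one purpose never perturb the
# others, so toggling e.g. the random walk leaves event histories intact.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629)
}

rng_streams <- function(seed, names = c("init", "events", "walk", "division", "spawn")) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(names)) {
    set.seed(derive_seed(seed, i))
    assign(names[i], get(".Random.seed", globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  env
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  val <- force(expr)
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  val
}
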