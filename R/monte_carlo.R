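# Monte Carlo layer over patient-variability input distributions:
# substrate stiffness, fibroblast division constant, myofibroblast
# apoptosis rate and macrophage appearance rate are resampled per run;
# per-run contraction summaries are collected and summarised, including
# a two-parameter Weibull fit of the reversed day-4 wound areas.

#' Monte Carlo input distribution specification
#'
#' Batch 1 uses a log-normal substrate stiffness (second parameter read
#' as the SD of the log); batch 2 replaces it by a wide uniform.
#'
#' @param batch 1 or 2.
#' @return list of distribution descriptors of class `ws_mc_spec`.
#' @export
mc_input_spec <- function(batch = 1) {
  es <- if (batch == 1) list(dist = "lognormal", meanlog = log(50), sdlog = 0.1)
  else list(dist = "uniform", min = 23.90, max = 300.00)
  structure(list(
    E_s = es,
    lambda_d = list(dist = "uniform", min = 1.5, max = 2.5),
    lambda_a = list(dist = "normal", mean = 10, sd = 0.1),
    lambda_appear = list(dist = "lognormal", meanlog = log(0.04), sdlog = 1e-5)
  ), class = "ws_mc_spec")
}

draw_one <- function(d, n) {
  switch(d$dist,
    lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
    uniform = runif(n, d$min, d$max),
    normal = rnorm(n, d$mean, d$sd),
    stop("unknown distribution: ", d$dist))
}

#' Sample Monte Carlo inputs
#'
#' Draws `n` independent parameter rows; draws that violate positivity
#' are resampled.
#'
#' @param spec a [mc_input_spec()].
#' @param n number of rows.
#' @param seed RNG seed.
#' @return data frame with one column per input parameter.
#' @export
sample_inputs <- function(spec = mc_input_spec(), n, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  out <- lapply(spec, function(d) {
    x <- draw_one(d, n)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- draw_one(d, length(bad))
      bad <- which(x <= 0)
    }
    x
  })
  as.data.frame(out)
}

#' Run a Monte Carlo ensemble
#'
#' One simulation per parameter row; the per-row seed is derived from
#' the global seed and row index, so the ensemble is reproducible and
#' independent of execution order. Failed rows are recorded as `NA`.
#'
#' @param samples data frame from [sample_inputs()].
#' @param base_config a [sim_config()] used as the template.
#' @param seed global seed.
#' @param progress print one line per run.
#' @return data frame with the inputs and response columns `n`, `n_min`,
#'   `Area_final`, `Area_min`, `Area_4days`, `rho_c_hat_final`,
#'   `rho_c_hat_min`.
#' @export
run_ensemble <- function(samples, base_config, seed = 1L, progress = FALSE) {
  res <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    cfg <- base_config
    cfg$mech$E <- samples$E_s[i]
    cfg$cellp$div_const <- samples$lambda_d[i]
    cfg$cellp$apop_rate <- samples$lambda_a[i]
    cfg$cellp$lambda_appear <- samples$lambda_appear[i]
    cfg$seed <- derive_seed(seed, i)
    row <- tryCatch({
      ts <- run_simulation(cfg)
      s <- attr(ts, "summary")
      c(n = s$n, n_min = s$n_min, Area_final = s$Area_final,
        Area_min = s$Area_min, Area_4days = s$Area_4days,
        rho_c_hat_final = s$rho_c_hat_final, rho_c_hat_min = s$rho_c_hat_min)
    }, error = function(e) {
      warning("run ", i, " failed: ", conditionMessage(e))
      c(n = NA_real_, n_min = NA_real_, Area_final = NA_real_,
        Area_min = NA_real_, Area_4days = NA_real_,
        rho_c_hat_final = NA_real_, rho_c_hat_min = NA_real_)
    })
    res[[i]] <- row
    if (progress) message("run ", i, "/", nrow(samples), " done")
  }
  cbind(samples, as.data.frame(do.call(rbind, res)))
}

#' Summarise an ensemble
#'
#' Per-column means and SDs, the pairwise Pearson correlation matrix
#' with p-values, and empirical CDF evaluators for the area columns.
#' Constant columns yield `NA` correlations.
#'
#' @param results data frame from [run_ensemble()].
#' @return list with `mean`, `sd`, `correlation`, `p_value`, `ecdf`.
#' @export
summarize_ensemble <- function(results) {
  num <- results[vapply(results, is.numeric, logical(1))]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3) stop("need at least 3 complete rows")
  mu <- vapply(num, mean, numeric(1))
  sd_ <- vapply(num, sd, numeric(1))
  p <- ncol(num)
  r <- pv <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (sd_[i] > 0 && sd_[j] > 0) {
      if (i == j) { r[i, j] <- 1; pv[i, j] <- 0 }
      else {
        ct <- stats::cor.test(num[[i]], num[[j]])
        r[i, j] <- unname(ct$estimate); pv[i, j] <- ct$p.value
      }
    }
  }
  cdfs <- lapply(num[grep("Area|ratio|rho", names(num), value = TRUE)], ecdf)
  list(mean = mu, sd = sd_, correlation = r, p_value = pv, ecdf = cdfs)
}

#' Two-parameter Weibull fit of reversed day-4 areas
#'
#' The day-4 wound areas cluster just below the initial area; the
#' reversal `y = (max(x) + eps) - x` makes them positive and
#' right-skewed, which a two-parameter Weibull describes well. Maximum
#' likelihood via [MASS::fitdistr()].
#'
#' @param day4_areas numeric vector (at least 10 values).
#' @param epsilon small positive offset; default `1e-6 * max(x)`.
#' @return list with `shape`, `scale`, `loglik`, `aic`, `epsilon`.
#' @export
weibull_fit_reversed <- function(day4_areas, epsilon = NULL) {
  x <- day4_areas[is.finite(day4_areas)]
  if (length(x) < 10) stop("need at least 10 values")
  if (is.null(epsilon)) epsilon <- 1e-6 * max(x)
  if (epsilon <= 0) stop("epsilon must be positive")
  y <- (max(x) + epsilon) - x
  # standardise to O(1) for the optimiser; shape is scale-invariant and
  # the log-likelihood shifts by -n log(s)
  s <- stats::median(y)
  # suppressWarnings: the optimiser probes invalid (negative) parameter
  # values while converging, which raises harmless NaN warnings
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(y / s, "weibull")),
    error = function(e) stop("Weibull fit did not converge: ", conditionMessage(e)))
  shape <- unname(fit$estimate["shape"])
  scale <- unname(fit$estimate["scale"]) * s
  ll <- as.numeric(stats::logLik(fit)) - length(y) * log(s)
  list(shape = shape, scale = scale, loglik = ll, aic = 2 * 2 - 2 * ll,
       epsilon = epsilon)
}
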