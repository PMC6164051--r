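#' Root mean squared error between two mass series
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (M_{sim}(t_i) - M_{exp}(t_i))^2 / N}}.
#'
#' @param m_sim,m_exp numeric vectors of equal length >= 1.
#' @return non-negative scalar in the units of the inputs.
#' @export
rmse <- function(m_sim, m_exp) {
  if (base::length(m_sim) != base::length(m_exp))
    stop("`m_sim` and `m_exp` must have equal length")
  if (base::length(m_sim) < 1) stop("series must be non-empty")
  sqrt(mean((m_sim - m_exp)^2))
}

#' Settings for the diffusivity least-squares fit
#'
#' The fit searches over `log10(D)` (enforcing positivity and conditioning
#' the problem across orders of magnitude) and the equilibrium mass `M_inf`,
#' within box bounds, using Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]).
#'
#' @param D_init initial diffusivity, m^2 s^-1.
#' @param D_bounds lower/upper diffusivity bounds, m^2 s^-1.
#' @param Minf_init initial equilibrium mass, ug; `NULL` uses the last
#'   observed mass of the step.
#' @param max_iter maximum optimizer iterations.
#' @param tol convergence tolerance on the scaled objective.
#' @param multistart if `TRUE`, restart from 5 log-spaced initial D values
#'   across `D_bounds` and keep the best fit (guards against local minima).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(D_init = 1e-12, D_bounds = c(1e-16, 1e-8),
                       Minf_init = NULL, max_iter = 200L, tol = 1e-10,
                       multistart = FALSE) {
  stopifnot(base::length(D_bounds) == 2, D_bounds[1] > 0,
            D_bounds[1] < D_init, D_init < D_bounds[2],
            max_iter >= 1, tol > 0)
  structure(list(D_init = D_init, D_bounds = D_bounds,
                 Minf_init = Minf_init, max_iter = as.integer(max_iter),
                 tol = tol, multistart = isTRUE(multistart)),
            class = "fit_config")
}

fit_step_once <- function(t, m, model, D_init, Minf_init, cfg, series_cfg) {
  resid_fn <- function(par) {
    D <- 10^par[1]
    par[2] * population_uptake(t, D, model, series_cfg, fraction = TRUE) - m
  }
  lo <- c(log10(cfg$D_bounds[1]), 0)
  hi <- c(log10(cfg$D_bounds[2]), Inf)
  fit <- minpack.lm::nls.lm(
    par = c(log10(D_init), Minf_init), lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = cfg$max_iter, ftol = cfg$tol, ptol = cfg$tol))
  list(D = 10^fit$par[1], Minf = fit$par[2],
       rmse = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4, info = fit$info)
}

#' Fit diffusivity and equilibrium mass to one sorption step
#'
#' Identifies the apparent diffusivity `D` and equilibrium mass `M_inf` that
#' minimize the RMSE between the observed incremental mass uptake of one RH
#' step and the population sorption model (a single-class model reproduces
#' the global-descriptor fit; a multi-class model the PSD-aware fit).
#'
#' @param step a `sorption_step` from [segment_steps()], or any data.frame
#'   with columns `t_rel_s` and `mass_ug` (>= 5 rows).
#' @param model a [population_model()] (its `M_inf` is ignored: the
#'   equilibrium mass is a fitted parameter).
#' @param cfg a [fit_config()].
#' @param series_cfg a [series_config()].
#' @return an object of class `fit_result`: list with `D_hat` (m^2 s^-1),
#'   `Minf_hat` (ug), `rmse` (ug), `n_points`, `converged`, `rh_percent`,
#'   `equilibrium`.
#' @export
fit_step <- function(step, model, cfg = fit_config(),
                     series_cfg = series_config()) {
  stopifnot(inherits(model, "population_model"), inherits(cfg, "fit_config"))
  if (!all(c("t_rel_s", "mass_ug") %in% names(step)))
    stop("`step` must have columns t_rel_s and mass_ug")
  if (nrow(step) < 5) stop("step must have at least 5 points")
  t <- step$t_rel_s
  m <- step$mass_ug
  Minf_init <- cfg$Minf_init
  if (is.null(Minf_init)) Minf_init <- max(abs(m[base::length(m)]), 1e-12)
  starts <- if (cfg$multistart) {
    10^seq(log10(cfg$D_bounds[1] * 10), log10(cfg$D_bounds[2] / 10),
           length.out = 5)
  } else cfg$D_init
  best <- NULL
  for (D0 in starts) {
    cand <- fit_step_once(t, m, model, D0, Minf_init, cfg, series_cfg)
    if (is.null(best) || cand$rmse < best$rmse) best <- cand
  }
  init_rmse <- rmse(Minf_init *
    population_uptake(t, cfg$D_init, model, series_cfg, fraction = TRUE), m)
  structure(list(D_hat = best$D, Minf_hat = best$Minf, rmse = best$rmse,
                 n_points = base::length(t),
                 converged = best$converged && best$rmse <= init_rmse + 1e-15,
                 rh_percent = attr(step, "rh_percent"),
                 equilibrium = attr(step, "equilibrium")),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> D = ", format(x$D_hat, digits = 4), " m^2/s, M_inf = ",
      format(x$Minf_hat, digits = 4), " ug, RMSE = ",
      format(x$rmse, digits = 3), " ug (", x$n_points, " pts",
      if (!is.null(x$rh_percent)) paste0(", RH ", x$rh_percent, "%"), ", ",
      if (isTRUE(x$converged)) "converged" else "NOT converged", ")\n",
      sep = "")
  invisible(x)
}

#' Fit every step of a segmented experiment
#'
#' @param steps list of sorption steps from [segment_steps()].
#' @inheritParams fit_step
#' @return list of [fit_step()] results.
#' @export
fit_steps <- function(steps, model, cfg = fit_config(),
                      series_cfg = series_config()) {
  lapply(steps, fit_step, model = model, cfg = cfg, series_cfg = series_cfg)
}

#' Temporal mean of per-step diffusivity estimates
#'
#' Apparent diffusivity is fitted independently per RH step; when RH has no
#' systematic effect the step estimates are summarized by their arithmetic
#' mean and standard deviation over converged steps.
#'
#' @param results list of [fit_step()] results (>= 1 converged).
#' @return an object of class `diffusivity_summary`: list with `per_step`,
#'   `temporal_mean`, `temporal_sd`, `n_converged`, `sd_defined` (`FALSE`
#'   when only one converged step: sd reported as 0).
#' @export
temporal_mean_diffusivity <- function(results) {
  if (inherits(results, "fit_result")) results <- list(results)
  conv <- Filter(function(r) isTRUE(r$converged), results)
  if (base::length(conv) == 0) stop("no converged fit results")
  D <- vapply(conv, function(r) r$D_hat, numeric(1))
  sd_def <- base::length(D) > 1
  structure(list(per_step = results, temporal_mean = mean(D),
                 temporal_sd = if (sd_def) stats::sd(D) else 0,
                 n_converged = base::length(D), sd_defined = sd_def),
            class = "diffusivity_summary")
}

#' @export
print.diffusivity_summary <- function(x, ...) {
  cat("<diffusivity_summary> D = ", format(x$temporal_mean, digits = 3),
      " +/- ", format(x$temporal_sd, digits = 3), " m^2/s (temporal mean, ",
      x$n_converged, " converged step(s))\n", sep = "")
  invisible(x)
}

#' Compare size descriptors for diffusivity estimation
#'
#' Fits every RH step under a family of population representations and
#' summarizes the temporal-mean diffusivity per configuration:
#' global volume-mean and volume-median single cylinders, PSD grids
#' (center / mean / median class descriptors) at each requested mesh, and
#' the exact all-particles model (each particle its own class).
#'
#' @param pop a [particle_population()].
#' @param steps list of sorption steps from [segment_steps()].
#' @param meshes numeric vector of class sides, um.
#' @param descriptors subset of `c("center", "mean", "median")`.
#' @param domain optional binning domain, see [bin_population()].
#' @param include_global include global mean/median single-cylinder fits.
#' @param include_all_particles include the exact all-particles fit.
#' @inheritParams fit_step
#' @return data.frame with one row per configuration: `descriptor`, `mesh`
#'   (NA for global/all-particles rows), `n_classes`, `D_mean`, `D_sd`
#'   (m^2 s^-1), `rmse_mean` (ug), `n_steps`. The list of per-configuration
#'   [temporal_mean_diffusivity()] summaries is attached as attribute
#'   `"summaries"`.
#' @export
compare_descriptors <- function(pop, steps, meshes = c(20, 10, 5, 2.5, 1),
                                descriptors = c("center", "mean", "median"),
                                domain = NULL, include_global = TRUE,
                                include_all_particles = TRUE,
                                cfg = fit_config(),
                                series_cfg = series_config()) {
  stopifnot(inherits(pop, "particle_population"))
  configs <- list()
  if (include_global) {
    for (s in c("mean", "median")) {
      configs[[paste0("global-", s)]] <- list(
        label = paste0("global-", s), mesh = NA_real_,
        model = population_model_single(global_descriptor(pop, s, "volume")))
    }
  }
  for (mesh in meshes) {
    for (d in descriptors) {
      grid <- bin_population(pop, mesh, d, domain)
      configs[[paste0("psd-", d, "-", mesh)]] <- list(
        label = paste0("psd-", d), mesh = mesh,
        model = population_model_from_grid(grid))
    }
  }
  if (include_all_particles) {
    configs[["all-particles"]] <- list(
      label = "all-particles", mesh = NA_real_,
      model = population_model_all_particles(pop))
  }
  summaries <- lapply(configs, function(cf) {
    temporal_mean_diffusivity(fit_steps(steps, cf$model, cfg, series_cfg))
  })
  tab <- do.call(rbind, Map(function(cf, su) {
    data.frame(descriptor = cf$label, mesh = cf$mesh,
               n_classes = base::length(cf$model$weights),
               D_mean = su$temporal_mean, D_sd = su$temporal_sd,
               rmse_mean = mean(vapply(su$per_step, function(r) r$rmse,
                                       numeric(1))),
               n_steps = base::length(su$per_step))
  }, configs, summaries))
  rownames(tab) <- NULL
  attr(tab, "summaries") <- summaries
  tab
}

#' Write per-step fit results to CSV
#'
#' @param results list of [fit_step()] results.
#' @param path output CSV path (columns `rh_percent`, `D_m2s`, `Minf_ug`,
#'   `rmse`, `converged`).
#' @export
write_fit_results <- function(results, path) {
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(rh_percent = if (is.null(r$rh_percent)) NA else r$rh_percent,
               D_m2s = r$D_hat, Minf_ug = r$Minf_hat, rmse = r$rmse,
               converged = r$converged)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
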