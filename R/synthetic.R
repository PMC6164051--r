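with_preserved_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic particle population
#'
#' Generative model for heterogeneous micrometric particle samples: a
#' mixture of correlated bivariate lognormal components in (length,
#' diameter), clipped to a rectangular domain and to `length >= diameter`
#' by resampling. The default is a four-component mixture — a dense
#' small-particle component, a sparse thin elongated component, a medium
#' chunky band, and a minority of big particles carrying a large volume
#' share — whose summaries emulate a polydisperse cellulose powder: roughly
#' two thirds of particles with length in \[5, 35\] um and diameter in
#' \[5, 20\] um, about 5-6% of particles longer than 50 um, an aspect ratio
#' of the volume-mean dimensions near 1.7, and a volume-weighted median
#' (around 35-45 um length by 19-25 um diameter) that falls in the medium
#' band, well below the big-particle sizes dominating the slow end of the
#' sorption kinetics.
#'
#' @param n_particles number of particles (default 3300).
#' @param components list of components, each a list with `weight`,
#'   `meanlog_length`, `sdlog_length`, `meanlog_diameter`, `sdlog_diameter`,
#'   `correlation`; weights must sum to 1.
#' @param domain `c(length_max, diameter_max)` clip bounds, um.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_particles = 3300L,
                            components = default_psd_components(),
                            domain = c(120, 60)) {
  stopifnot(n_particles >= 1, base::length(domain) == 2, all(domain > 0))
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  for (cc in components) {
    stopifnot(cc$sdlog_length >= 0, cc$sdlog_diameter >= 0,
              abs(cc$correlation) <= 1)
  }
  structure(list(n_particles = as.integer(n_particles),
                 components = components, domain = as.numeric(domain)),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
default_psd_components <- function() {
  list(
    small = list(weight = 0.885,
                 meanlog_length = log(12), sdlog_length = 0.55,
                 meanlog_diameter = log(8.4), sdlog_diameter = 0.52,
                 correlation = 0.75),
    thin = list(weight = 0.062,
                meanlog_length = log(58), sdlog_length = 0.30,
                meanlog_diameter = log(6.0), sdlog_diameter = 0.30,
                correlation = 0.40),
    medium = list(weight = 0.046,
                  meanlog_length = log(30), sdlog_length = 0.22,
                  meanlog_diameter = log(18), sdlog_diameter = 0.20,
                  correlation = 0.85),
    large = list(weight = 0.007,
                 meanlog_length = log(65), sdlog_length = 0.28,
                 meanlog_diameter = log(43), sdlog_diameter = 0.25,
                 correlation = 0.85))
}

draw_component <- function(n, cc, domain) {
  out_l <- numeric(0); out_d <- numeric(0)
  remaining <- n
  degenerate <- cc$sdlog_length == 0 && cc$sdlog_diameter == 0
  tries <- 0
  while (remaining > 0) {
    m <- max(remaining * 2L, 16L)
    z1 <- stats::rnorm(m)
    z2 <- cc$correlation * z1 +
      sqrt(1 - cc$correlation^2) * stats::rnorm(m)
    l <- exp(cc$meanlog_length + cc$sdlog_length * z1)
    d <- exp(cc$meanlog_diameter + cc$sdlog_diameter * z2)
    ok <- l >= d & l <= domain[1] & d <= domain[2]
    if (degenerate && !any(ok))
      stop("degenerate component violates length >= diameter or domain")
    keep <- which(ok)[seq_len(min(remaining, sum(ok)))]
    out_l <- c(out_l, l[keep]); out_d <- c(out_d, d[keep])
    remaining <- n - base::length(out_l)
    tries <- tries + 1
    if (tries > 1000) stop("resampling failed: acceptance region too small")
  }
  cbind(out_l, out_d)
}

#' Generate a synthetic particle population
#'
#' Draws a [particle_population()] from a [population_spec()]. Reproducible
#' under a fixed `seed` (the global RNG state is preserved).
#'
#' @param spec a [population_spec()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [particle_population()] with the generating `spec` attached as
#'   attribute `"spec"`.
#' @export
generate_population <- function(spec = population_spec(), seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  w <- vapply(spec$components, function(cc) cc$weight, numeric(1))
  if (any(w == 1 & vapply(spec$components, function(cc)
      cc$sdlog_length == 0 && cc$sdlog_diameter == 0, logical(1))))
    warning("single degenerate component: all particles will be identical")
  with_preserved_rng(seed, {
    comp <- sample.int(base::length(spec$components), spec$n_particles,
                       replace = TRUE, prob = w)
    n_by <- tabulate(comp, nbins = base::length(spec$components))
    parts <- Map(function(cc, n) {
      if (n == 0) return(cbind(numeric(0), numeric(0)))
      draw_component(n, cc, spec$domain)
    }, spec$components, n_by)
    ld <- do.call(rbind, parts)
    pop <- particle_population(ld[, 1], ld[, 2])
    attr(pop, "spec") <- spec
    pop
  })
}

#' Specification of a simulated multi-step QCM sorption trace
#'
#' Forward model for a synthetic experiment: a known diffusivity `D_true`,
#' an RH step schedule, per-step equilibrium uptakes (by default
#' proportional to the RH increment with a configurable total — order of
#' magnitude ~10% of a ~1.2 ug deposited sample), a sampling interval, and
#' additive iid Gaussian mass noise at the QCM sensitivity floor.
#'
#' @param D_true true diffusivity, m^2 s^-1.
#' @param schedule an [rh_schedule()]; default 8 contiguous 600-s steps from
#'   10% to 80% RH.
#' @param step_Minf per-step equilibrium uptakes, ug; `NULL` distributes
#'   `total_uptake` proportionally to the RH increments.
#' @param total_uptake total equilibrium uptake over the schedule, ug.
#' @param sampling_interval trace sampling interval, s.
#' @param noise_sd additive mass noise standard deviation, ug (default
#'   7e-7, the QCM detection floor).
#' @return an object of class `trace_spec`.
#' @export
trace_spec <- function(D_true = 3.1e-12,
                       schedule = rh_schedule(seq(0, 4200, by = 600),
                                              seq(600, 4800, by = 600),
                                              seq(10, 80, by = 10)),
                       step_Minf = NULL, total_uptake = 0.12,
                       sampling_interval = 1, noise_sd = 7e-7) {
  stopifnot(D_true > 0, inherits(schedule, "rh_schedule"),
            sampling_interval > 0, noise_sd >= 0)
  if (is.null(step_Minf)) {
    d_rh <- diff(c(0, schedule$rh_percent))
    if (any(d_rh <= 0)) stop("default uptake needs increasing RH steps")
    step_Minf <- total_uptake * d_rh / sum(d_rh)
  }
  if (base::length(step_Minf) != nrow(schedule))
    stop("`step_Minf` must have one value per schedule step")
  stopifnot(all(step_Minf > 0))
  structure(list(D_true = D_true, schedule = schedule, step_Minf = step_Minf,
                 sampling_interval = sampling_interval, noise_sd = noise_sd),
            class = "trace_spec")
}

#' Simulate a multi-step QCM frequency trace
#'
#' Composes the population sorption model forward: per RH step, the
#' incremental sorbed mass follows the heterogeneous-population uptake
#' solution at `D_true` with that step's equilibrium mass; the cumulative
#' mass (continuous across step boundaries) is converted to a frequency
#' shift by the inverse Sauerbrey relation, and seeded Gaussian mass noise
#' is added. By default the model is the exact all-particles representation
#' of `x`.
#'
#' @param x a [particle_population()], a [bin_population()] grid, or a
#'   [population_model()].
#' @param spec a [trace_spec()].
#' @param q a [quartz_params()].
#' @param seed integer seed for the noise stream, or `NULL`.
#' @param series_cfg a [series_config()].
#' @return list with elements `trace` (a [frequency_trace()]) and `truth`
#'   (list: `D_true`, `step_Minf`, `schedule`, `model`, `mass_true_ug` the
#'   noiseless cumulative mass).
#' @export
simulate_trace <- function(x, spec = trace_spec(), q = quartz_params(),
                           seed = 1L, series_cfg = series_config()) {
  stopifnot(inherits(spec, "trace_spec"))
  model <- if (inherits(x, "population_model")) x
    else if (inherits(x, "particle_population"))
      population_model_all_particles(x)
    else if (inherits(x, "size_class_grid") || is.data.frame(x))
      population_model_from_grid(x)
    else stop("`x` must be a population, size-class grid or population model")
  sched <- spec$schedule
  t <- seq(min(sched$start_s), max(sched$end_s), by = spec$sampling_interval)
  mass <- numeric(base::length(t))
  base_m <- 0
  for (k in seq_len(nrow(sched))) {
    g_end <- population_uptake(sched$end_s[k] - sched$start_s[k],
                               spec$D_true, model, series_cfg,
                               fraction = TRUE)
    in_step <- t >= sched$start_s[k] & t <= sched$end_s[k]
    g <- population_uptake(t[in_step] - sched$start_s[k], spec$D_true,
                           model, series_cfg, fraction = TRUE)
    mass[in_step] <- base_m + spec$step_Minf[k] * g
    after <- t > sched$end_s[k]
    base_m <- base_m + spec$step_Minf[k] * g_end
    mass[after] <- base_m   # hold through any schedule gap
  }
  noisy <- with_preserved_rng(seed,
    mass + stats::rnorm(base::length(mass), 0, spec$noise_sd))
  list(trace = frequency_trace(t, inverse_sauerbrey(noisy, q)),
       truth = list(D_true = spec$D_true, step_Minf = spec$step_Minf,
                    schedule = sched, model = model, mass_true_ug = mass))
}
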