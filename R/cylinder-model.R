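.cyl_cache <- new.env(parent = emptyenv())

#' First positive zeros of the Bessel function J0
#'
#' Locates the first `n` positive roots \eqn{\alpha_n} of \eqn{J_0(x) = 0}.
#' These index the radial eigenmodes of diffusion in a cylinder: the radial
#' eigenvalues of a cylinder of radius R are \eqn{q_n = \alpha_n / R}.
#'
#' Roots are bracketed with the McMahon asymptotic expansion
#' \eqn{\alpha_k \approx \beta + 1/(8\beta)} with \eqn{\beta = (k - 1/4)\pi}
#' (accurate to well under the inter-root spacing of \eqn{\pi}) and polished
#' with [stats::uniroot()] on [base::besselJ()].
#'
#' @param n number of zeros (integer, >= 1).
#' @return numeric vector of the first `n` zeros, strictly increasing.
#' @examples
#' bessel_j0_zeros(3) # 2.404826, 5.520078, 8.653728
#' @export
bessel_j0_zeros <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a single integer >= 1")
  n <- as.integer(n)
  cached <- .cyl_cache$j0_zeros
  if (is.null(cached) || length(cached) < n) {
    k <- seq_len(max(n, 64L))
    beta <- (k - 0.25) * pi
    x0 <- beta + 1 / (8 * beta) - 124 / (3 * (8 * beta)^3)
    cached <- vapply(x0, function(x) {
      stats::uniroot(function(z) besselJ(z, 0), c(x - 0.5, x + 0.5),
                     tol = 1e-14)$root
    }, numeric(1))
    .cyl_cache$j0_zeros <- cached
  }
  cached[seq_len(n)]
}

#' Series truncation settings for the cylinder uptake solution
#'
#' The analytical uptake fraction is a product of two infinite series
#' (radial Bessel series, axial Fourier series). Both converge geometrically
#' for t > 0; `n_roots` and `n_terms` cap the number of terms and `tail_tol`
#' stops summation early once a term falls below it (terms are positive and
#' strictly decreasing, so early stopping is safe).
#'
#' @param n_roots number of radial Bessel-root terms (>= 1).
#' @param n_terms number of axial Fourier terms (>= 1).
#' @param tail_tol absolute early-stop tolerance for a single term (>= 0).
#' @return an object of class `series_config`.
#' @export
series_config <- function(n_roots = 50L, n_terms = 50L, tail_tol = 1e-14) {
  stopifnot(n_roots >= 1, n_terms >= 1, tail_tol >= 0)
  structure(list(n_roots = as.integer(n_roots), n_terms = as.integer(n_terms),
                 tail_tol = tail_tol),
            class = "series_config")
}

#' Fractional mass uptake of a single finite cylinder
#'
#' Analytical Fickian sorption solution for a finite cylinder of radius
#' `radius` and length `length` with uniform initial concentration and a
#' constant surface concentration: the fractional uptake is
#' \deqn{M_t/M_\infty = 1 -
#'   \Big[\sum_n \frac{4}{\alpha_n^2} e^{-D\alpha_n^2 t/R^2}\Big]
#'   \Big[\sum_n \frac{8}{(2n+1)^2\pi^2} e^{-D(2n+1)^2\pi^2 t/L^2}\Big],}
#' the product of the infinite-cylinder (radial) and plane-sheet (axial)
#' remainders, with \eqn{\alpha_n} the positive zeros of \eqn{J_0}.
#'
#' At `t = 0` the value 0 is returned exactly without evaluating the series
#' (which converges slowly there). Truncated partial sums are clipped to
#' \[0, 1\].
#'
#' @param t time, s (vector, all >= 0).
#' @param D diffusivity, m^2 s^-1 (> 0).
#' @param radius cylinder radius R, m (> 0).
#' @param length cylinder length L, m (> 0).
#' @param cfg a [series_config()].
#' @return vector of uptake fractions in \[0, 1\], same length as `t`.
#' @seealso [population_uptake()] for heterogeneous populations,
#'   [fd_uptake_cylinder()] for the finite-difference validation solver.
#' @examples
#' uptake_fraction_cylinder(c(0, 5, 60), D = 1e-12, radius = 9.5e-6,
#'                          length = 3.2e-5)
#' @export
uptake_fraction_cylinder <- function(t, D, radius, length,
                                     cfg = series_config()) {
  check_time_diffusivity(t, D)
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.finite(length) || length <= 0) stop("`length` must be > 0")
  alpha <- bessel_j0_zeros(cfg$n_roots)
  out <- cpp_population_uptake_fraction(as.numeric(t), D, length, radius, 1.0,
                                        alpha, cfg$n_terms, cfg$tail_tol)
  attr(out, "n_clipped") <- NULL
  out
}

check_time_diffusivity <- function(t, D) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (length(D) != 1L || !is.finite(D) || D <= 0) stop("`D` must be > 0")
  invisible(TRUE)
}

#' Heterogeneous cylinder population model
#'
#' A population structured in N classes, each a homogeneous sub-population of
#' cylinders with length `lengths_m[i]`, radius `radii_m[i]` and mass (=
#' volume) fraction `weights[i]`. The total equilibrium uptake `M_inf`
#' distributes over classes proportionally to the weights, so the population
#' uptake is the weight-mixture of single-cylinder solutions.
#'
#' @param lengths_m class cylinder lengths, m (> 0).
#' @param radii_m class cylinder radii, m (> 0).
#' @param weights mass fractions, summing to 1 (tolerance 1e-9).
#' @param M_inf total equilibrium sorbed mass (default 1: fractional uptake).
#' @return an object of class `population_model`.
#' @seealso [population_model_from_grid()], [population_model_all_particles()]
#' @export
population_model <- function(lengths_m, radii_m, weights, M_inf = 1) {
  n <- length(lengths_m)
  if (length(radii_m) != n || length(weights) != n)
    stop("`lengths_m`, `radii_m` and `weights` must have equal length")
  if (n < 1) stop("model needs at least one class")
  if (any(!is.finite(lengths_m)) || any(lengths_m <= 0) ||
      any(!is.finite(radii_m)) || any(radii_m <= 0))
    stop("class dimensions must be finite and > 0")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("class weights must sum to 1 (tolerance 1e-9); got ",
         format(sum(weights)))
  if (!is.finite(M_inf) || M_inf <= 0) stop("`M_inf` must be > 0")
  structure(list(lengths_m = as.numeric(lengths_m),
                 radii_m = as.numeric(radii_m),
                 weights = as.numeric(weights), M_inf = M_inf),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> ", length(x$weights), " class(es), M_inf = ",
      format(x$M_inf), "\n", sep = "")
  cat("  length [m]: ", format(min(x$lengths_m), digits = 3), " .. ",
      format(max(x$lengths_m), digits = 3), "\n", sep = "")
  cat("  radius [m]: ", format(min(x$radii_m), digits = 3), " .. ",
      format(max(x$radii_m), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Mass uptake of a heterogeneous cylinder population
#'
#' Evaluates the population sorption solution
#' \deqn{M_t = \sum_i w_i M_\infty f(t; D, L_i, R_i)}
#' with \eqn{f} the single finite-cylinder uptake fraction (see
#' [uptake_fraction_cylinder()]). With a single class this reduces exactly to
#' `M_inf * uptake_fraction_cylinder(...)`.
#'
#' @inheritParams uptake_fraction_cylinder
#' @param model a [population_model()].
#' @param fraction if `TRUE`, return the normalized uptake \eqn{M_t/M_\infty}
#'   instead of mass units.
#' @return vector of sorbed mass (or fraction), same length as `t`.
#' @export
population_uptake <- function(t, D, model, cfg = series_config(),
                              fraction = FALSE) {
  stopifnot(inherits(model, "population_model"))
  check_time_diffusivity(t, D)
  alpha <- bessel_j0_zeros(cfg$n_roots)
  f <- cpp_population_uptake_fraction(as.numeric(t), D, model$lengths_m,
                                      model$radii_m, model$weights, alpha,
                                      cfg$n_terms, cfg$tail_tol)
  nclip <- attr(f, "n_clipped")
  attr(f, "n_clipped") <- NULL
  if (!is.null(nclip) && nclip > 0)
    message(nclip, " truncated partial sum(s) clipped to [0, 1]")
  if (fraction) f else model$M_inf * f
}

#' Finite-difference solution of cylinder sorption (validation oracle)
#'
#' Integrates the axisymmetric diffusion equation
#' \deqn{\partial C/\partial t = D(\tfrac1r \partial C/\partial r +
#'   \partial^2 C/\partial r^2 + \partial^2 C/\partial z^2)}
#' on \eqn{r \in [0, R]}, \eqn{z \in [0, L/2]} (axial symmetry) with
#' \eqn{C(0) = 0} inside and \eqn{C = 1} on the surface, and returns the
#' volume-averaged concentration, i.e. the uptake fraction
#' \eqn{M_t/M_\infty}, at the requested times. This path shares nothing with
#' the analytical series and serves to validate its truncation accuracy for
#' arbitrary geometries.
#'
#' The problem is solved in dimensionless form (Fourier time
#' \eqn{Fo = Dt/R^2}, aspect ratio \eqn{L/R}) by Peaceman-Rachford
#' alternating-direction-implicit time stepping (Crank-Nicolson accuracy)
#' with geometrically growing steps from `dt0` and a few backward-Euler
#' startup steps to damp the initial boundary discontinuity.
#'
#' @inheritParams uptake_fraction_cylinder
#' @param nr,nz number of grid intervals over the radius and the half length
#'   (>= 100 recommended for ~1e-3 uptake accuracy).
#' @param dt0 initial dimensionless time step.
#' @param growth geometric step-growth factor (> 1).
#' @param dt_max cap on the dimensionless step; default scales with the
#'   latest requested time.
#' @param n_startup number of damped backward-Euler startup steps.
#' @return vector of uptake fractions at `t`.
#' @export
fd_uptake_cylinder <- function(t, D, radius, length, nr = 200L, nz = 200L,
                               dt0 = 1e-8, growth = 1.05, dt_max = NULL,
                               n_startup = 20L) {
  check_time_diffusivity(t, D)
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.finite(length) || length <= 0) stop("`length` must be > 0")
  if (nr < 3 || nz < 3) stop("grid must have at least 3 intervals per axis")
  if (is.unsorted(t)) stop("`t` must be non-decreasing")
  if (growth <= 1) stop("`growth` must be > 1")
  fo <- as.numeric(t) * D / radius^2
  if (is.null(dt_max)) dt_max <- max(max(fo) / 400, dt0)
  cpp_fd_uptake(fo, length / radius, as.integer(nr), as.integer(nz),
                dt0, growth, dt_max, as.integer(n_startup))
}

#' Build a population model from a size-class grid
#'
#' Converts the um-scale representative dimensions of a [bin_population()]
#' grid into an SI-unit [population_model()] (class length L_i, radius
#' R_i = diameter/2, weight w_i).
#'
#' @param grid a [bin_population()] result (or a data.frame read back with
#'   [read_grid()]).
#' @param M_inf total equilibrium sorbed mass (default 1).
#' @return a [population_model()].
#' @export
population_model_from_grid <- function(grid, M_inf = 1) {
  need <- c("rep_length_um", "rep_diameter_um", "weight")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "))
  w <- grid$weight / sum(grid$weight)   # guard CSV round-trip rounding
  population_model(grid$rep_length_um * 1e-6,
                   grid$rep_diameter_um / 2 * 1e-6, w, M_inf)
}

#' Build an all-particles population model
#'
#' Uses every particle as its own class (weight = its volume fraction):
#' the exact, unbinned population representation.
#'
#' @param pop a [particle_population()].
#' @inheritParams population_model_from_grid
#' @return a [population_model()] with one class per particle.
#' @export
population_model_all_particles <- function(pop, M_inf = 1) {
  stopifnot(inherits(pop, "particle_population"))
  population_model(pop$length_um * 1e-6, pop$diameter_um / 2 * 1e-6,
                   pop$volume_um3 / sum(pop$volume_um3), M_inf)
}

#' Single-cylinder model from a global descriptor
#'
#' Wraps a [global_descriptor()] (or any (length, diameter) pair in um) as a
#' one-class [population_model()], i.e. the homogeneous-population
#' approximation used when fitting with a global size descriptor.
#'
#' @param desc a `descriptor_2d` from [global_descriptor()], or a numeric
#'   `c(length_um, diameter_um)`.
#' @inheritParams population_model_from_grid
#' @return a single-class [population_model()].
#' @export
population_model_single <- function(desc, M_inf = 1) {
  if (inherits(desc, "descriptor_2d")) desc <- c(desc$length, desc$diameter)
  stopifnot(base::length(desc) == 2)
  population_model(desc[1] * 1e-6, desc[2] / 2 * 1e-6, 1, M_inf)
}
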