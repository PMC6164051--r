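#' Volume of a cylindrical particle
#'
#' Particles are modelled as cylinders whose major axis is the length and
#' whose minor axis is the diameter, so
#' \eqn{V = \pi (d/2)^2 \ell}.
#'
#' @param length cylinder length(s), um (> 0).
#' @param diameter cylinder diameter(s), um (> 0).
#' @return volume(s), um^3.
#' @examples
#' cylinder_volume(10, 10)   # 250 * pi
#' @export
cylinder_volume <- function(length, diameter) {
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`length` and `diameter` must be finite and > 0")
  pi * (diameter / 2)^2 * length
}

#' Construct a particle population
#'
#' Builds a population from per-particle length (major axis) and diameter
#' (minor axis) measurements, attaching derived cylinder volumes. Rows where
#' the minor axis exceeds the major axis are canonicalized by swapping the
#' two (with a warning), so `length >= diameter` always holds.
#'
#' @param length major-axis lengths, um.
#' @param diameter minor-axis diameters, um.
#' @param canonicalize swap length/diameter where diameter > length
#'   (default `TRUE`); with `FALSE` such rows raise an error.
#' @return a `particle_population`: a data.frame with columns `length_um`,
#'   `diameter_um`, `volume_um3`.
#' @export
particle_population <- function(length, diameter, canonicalize = TRUE) {
  if (base::length(length) != base::length(diameter))
    stop("`length` and `diameter` must have equal length")
  if (base::length(length) == 0) stop("population must not be empty")
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(diameter)) || any(diameter <= 0))
    stop("particle dimensions must be finite and > 0")
  swap <- diameter > length
  if (any(swap)) {
    if (!canonicalize)
      stop("diameter > length in row(s) ",
           paste(utils::head(which(swap), 5), collapse = ", "))
    warning(sum(swap), " particle(s) had minor axis > major axis; swapped")
    tmp <- length[swap]
    length[swap] <- diameter[swap]
    diameter[swap] <- tmp
  }
  out <- data.frame(length_um = as.numeric(length),
                    diameter_um = as.numeric(diameter))
  out$volume_um3 <- cylinder_volume(out$length_um, out$diameter_um)
  class(out) <- c("particle_population", "data.frame")
  out
}

#' @export
print.particle_population <- function(x, ...) {
  cat("<particle_population> ", nrow(x), " particles\n", sep = "")
  cat("  length [um]:   ", paste(format(round(stats::quantile(x$length_um,
      c(0, .5, 1)), 2)), collapse = " / "), " (min/med/max)\n", sep = "")
  cat("  diameter [um]: ", paste(format(round(stats::quantile(x$diameter_um,
      c(0, .5, 1)), 2)), collapse = " / "), "\n", sep = "")
  cat("  total volume [um^3]: ", format(sum(x$volume_um3), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Read a per-particle measurement table
#'
#' Accepts a comma-separated table with a header, either in the ImageJ
#' particle-analysis dialect (columns `Major`, `Minor`, in um) or with
#' explicit columns `length_um`, `diameter_um`. Rows with missing values are
#' rejected with their row numbers.
#'
#' @param path CSV file path.
#' @param ... passed to [particle_population()] (e.g. `canonicalize`).
#' @return a [particle_population()].
#' @export
read_particles <- function(path, ...) {
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- names(tab)
  if (all(c("length_um", "diameter_um") %in% nm)) {
    len <- tab$length_um; dia <- tab$diameter_um
  } else if (all(c("Major", "Minor") %in% nm)) {
    len <- tab$Major; dia <- tab$Minor
  } else {
    stop("expected columns Major/Minor or length_um/diameter_um; found: ",
         paste(nm, collapse = ", "))
  }
  bad <- which(!is.finite(len) | !is.finite(dia))
  if (base::length(bad) > 0)
    stop("missing or non-numeric values in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  particle_population(len, dia, ...)
}

#' Write a particle population to CSV
#'
#' @param pop a [particle_population()].
#' @param path output CSV path (columns `length_um`, `diameter_um`).
#' @export
write_particles <- function(pop, path) {
  stopifnot(inherits(pop, "particle_population"))
  utils::write.csv(pop[, c("length_um", "diameter_um")], path,
                   row.names = FALSE)
  invisible(path)
}

weighted_mean2 <- function(x, w) sum(w * x) / sum(w)

# value at which cumulative weight (sorted by x) first reaches half the total
weighted_median2 <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= 0.5 * sum(w))[1]]
}

#' Global size descriptor of a population
#'
#' Computes a single (length, diameter) pair summarizing the population:
#' the mean or the median of each dimension, weighted either by particle
#' count or by particle volume. The volume-weighted median of a dimension is
#' the value at which the cumulative volume of particles sorted by that
#' dimension first reaches 50% of the total volume.
#'
#' @param pop a [particle_population()].
#' @param statistic `"mean"` or `"median"`.
#' @param weighting `"volume"` (default, relevant for mass transfer) or
#'   `"number"`.
#' @return a list of class `descriptor_2d` with elements `length`, `diameter`
#'   (um), `statistic`, `weighting`.
#' @export
global_descriptor <- function(pop, statistic = c("median", "mean"),
                              weighting = c("volume", "number")) {
  stopifnot(inherits(pop, "particle_population"), nrow(pop) > 0)
  statistic <- match.arg(statistic)
  weighting <- match.arg(weighting)
  w <- if (weighting == "volume") pop$volume_um3 else rep(1, nrow(pop))
  fn <- if (statistic == "mean") weighted_mean2 else weighted_median2
  structure(list(length = fn(pop$length_um, w),
                 diameter = fn(pop$diameter_um, w),
                 statistic = statistic, weighting = weighting),
            class = "descriptor_2d")
}

#' @export
print.descriptor_2d <- function(x, ...) {
  cat("<descriptor_2d> ", x$weighting, "-weighted ", x$statistic,
      ": length = ", format(x$length, digits = 4), " um, diameter = ",
      format(x$diameter, digits = 4), " um\n", sep = "")
  invisible(x)
}

#' Aspect-ratio (elongation factor) distribution
#'
#' Histogram of the length-to-diameter ratio, weighted by count or volume.
#' Bins are half-open `[k b, (k+1) b)` anchored at 0; frequencies sum to 1.
#'
#' @param pop a [particle_population()].
#' @param bin_width histogram bin width (dimensionless, > 0).
#' @param weighting `"volume"` or `"number"`.
#' @return data.frame with columns `ratio_lo`, `ratio_hi`, `ratio_mid`,
#'   `frequency` (non-empty bins only).
#' @export
aspect_ratio_distribution <- function(pop, bin_width = 0.25,
                                      weighting = c("volume", "number")) {
  stopifnot(inherits(pop, "particle_population"), nrow(pop) > 0)
  if (!is.finite(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  weighting <- match.arg(weighting)
  ratio <- pop$length_um / pop$diameter_um
  w <- if (weighting == "volume") pop$volume_um3 else rep(1, nrow(pop))
  idx <- floor(ratio / bin_width)
  agg <- rowsum(w, idx)
  k <- as.numeric(rownames(agg))
  data.frame(ratio_lo = k * bin_width, ratio_hi = (k + 1) * bin_width,
             ratio_mid = (k + 0.5) * bin_width,
             frequency = as.numeric(agg) / sum(w))
}

#' Bin a population into a 2D size-class grid
#'
#' Partitions the (length, diameter) plane into squared cells of side `mesh`
#' (half-open `[k m, (k+1) m)` anchored at 0; a particle exactly at the
#' domain maximum falls in the last cell) and computes, per non-empty class,
#' the volume fraction \eqn{w_i} (equal to the mass fraction, all particles
#' being the same material) and a representative dimension pair:
#' \describe{
#'   \item{center}{geometric center of the cell (independent of members);}
#'   \item{mean}{volume-weighted mean of member dimensions;}
#'   \item{median}{volume-weighted median of member dimensions.}
#' }
#'
#' @param pop a [particle_population()].
#' @param mesh cell side, um (> 0).
#' @param descriptor `"center"`, `"mean"` or `"median"`.
#' @param domain optional `c(length_max, diameter_max)` in um; particles
#'   outside an explicit domain raise an error naming the first offending
#'   rows. Default: the smallest mesh-aligned box covering the data.
#' @return a `size_class_grid`: data.frame with columns `class_i` (length
#'   index, 0-based), `class_j` (diameter index), `rep_length_um`,
#'   `rep_diameter_um`, `weight`, `count`; attributes `mesh`, `domain`,
#'   `descriptor`, `n_cells` (total cells including empty ones).
#' @examples
#' pop <- particle_population(c(7, 23), c(3, 12))
#' bin_population(pop, mesh = 10, descriptor = "mean",
#'                domain = c(120, 60))
#' @export
bin_population <- function(pop, mesh,
                           descriptor = c("center", "mean", "median"),
                           domain = NULL) {
  stopifnot(inherits(pop, "particle_population"), nrow(pop) > 0)
  if (!is.finite(mesh) || mesh <= 0) stop("`mesh` must be > 0")
  descriptor <- match.arg(descriptor)
  if (is.null(domain)) {
    domain <- c(ceiling(max(pop$length_um) / mesh) * mesh,
                ceiling(max(pop$diameter_um) / mesh) * mesh)
  } else {
    if (base::length(domain) != 2 || any(domain <= 0))
      stop("`domain` must be c(length_max, diameter_max), both > 0")
    out_of <- which(pop$length_um > domain[1] | pop$diameter_um > domain[2])
    if (base::length(out_of) > 0)
      stop("particle(s) outside domain: row(s) ",
           paste(utils::head(out_of, 10), collapse = ", "))
  }
  ni <- ceiling(domain[1] / mesh)
  nj <- ceiling(domain[2] / mesh)
  i <- pmin(floor(pop$length_um / mesh), ni - 1)
  j <- pmin(floor(pop$diameter_um / mesh), nj - 1)
  key <- i * nj + j
  split_idx <- split(seq_len(nrow(pop)), key)
  total_v <- sum(pop$volume_um3)
  rows <- lapply(split_idx, function(rr) {
    v <- pop$volume_um3[rr]
    ci <- i[rr[1]]; cj <- j[rr[1]]
    rep <- switch(descriptor,
      center = c((ci + 0.5) * mesh, (cj + 0.5) * mesh),
      mean = c(weighted_mean2(pop$length_um[rr], v),
               weighted_mean2(pop$diameter_um[rr], v)),
      median = c(weighted_median2(pop$length_um[rr], v),
                 weighted_median2(pop$diameter_um[rr], v)))
    data.frame(class_i = ci, class_j = cj, rep_length_um = rep[1],
               rep_diameter_um = rep[2], weight = sum(v) / total_v,
               count = base::length(rr))
  })
  grid <- do.call(rbind, rows)
  grid <- grid[order(grid$class_i, grid$class_j), ]
  rownames(grid) <- NULL
  structure(grid, mesh = mesh, domain = domain, descriptor = descriptor,
            n_cells = as.integer(ni * nj), class = c("size_class_grid", "data.frame"))
}

#' @export
print.size_class_grid <- function(x, ...) {
  cat("<size_class_grid> mesh ", attr(x, "mesh"), " um, descriptor '",
      attr(x, "descriptor"), "', domain ", attr(x, "domain")[1], " x ",
      attr(x, "domain")[2], " um\n", sep = "")
  cat("  ", nrow(x), " occupied of ", attr(x, "n_cells"), " cells; sum(w) = ",
      format(sum(x$weight)), "\n", sep = "")
  invisible(x)
}

#' Write / read a size-class grid as CSV
#'
#' @param grid a [bin_population()] result.
#' @param path CSV path (columns `class_i`, `class_j`, `rep_length_um`,
#'   `rep_diameter_um`, `weight`, `count`).
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "size_class_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("class_i", "class_j", "rep_length_um", "rep_diameter_um",
            "weight", "count")
  if (!all(need %in% names(tab)))
    stop("grid CSV must have columns ", paste(need, collapse = ", "))
  tab
}

#' Two-dimensional (diameter x length) frequency table
#'
#' Joint histogram of particle length and diameter with squared bins of side
#' `bin`, weighted by particle count or by particle volume. Frequencies sum
#' to 1.
#'
#' @param pop a [particle_population()].
#' @param bin bin side, um (> 0).
#' @param weighting `"volume"` or `"number"`.
#' @return data.frame with columns `length_lo`, `diameter_lo`, `length_mid`,
#'   `diameter_mid`, `frequency` (non-empty bins only).
#' @export
histogram_2d <- function(pop, bin = 1, weighting = c("volume", "number")) {
  stopifnot(inherits(pop, "particle_population"), nrow(pop) > 0)
  if (!is.finite(bin) || bin <= 0) stop("`bin` must be > 0")
  weighting <- match.arg(weighting)
  w <- if (weighting == "volume") pop$volume_um3 else rep(1, nrow(pop))
  i <- floor(pop$length_um / bin)
  j <- floor(pop$diameter_um / bin)
  key <- paste(i, j, sep = ":")
  agg <- rowsum(w, key)
  ij <- do.call(rbind, strsplit(rownames(agg), ":", fixed = TRUE))
  i2 <- as.numeric(ij[, 1]); j2 <- as.numeric(ij[, 2])
  out <- data.frame(length_lo = i2 * bin, diameter_lo = j2 * bin,
                    length_mid = (i2 + 0.5) * bin,
                    diameter_mid = (j2 + 0.5) * bin,
                    frequency = as.numeric(agg) / sum(w))
  out[order(out$length_lo, out$diameter_lo), ]
}
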