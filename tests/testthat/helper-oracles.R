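# Plain-R reference implementations, independent of the package's C++ path.

# finite-cylinder uptake fraction by direct summation of the two remainders
ref_uptake <- function(t, D, R, L, n_roots = 80, n_terms = 80) {
  alpha <- ref_j0_zeros(n_roots)
  vapply(t, function(tv) {
    if (tv <= 0) return(0)
    Sr <- sum(4 / alpha^2 * exp(-alpha^2 * D * tv / R^2))
    k <- 2 * seq(0, n_terms - 1) + 1
    Sz <- sum(8 / (k^2 * pi^2) * exp(-k^2 * pi^2 * D * tv / L^2))
    min(max(1 - Sr * Sz, 0), 1)
  }, numeric(1))
}

# J0 zeros by brute bisection on besselJ over consecutive unit intervals
ref_j0_zeros <- function(n) {
  zeros <- numeric(0)
  lo <- 1e-6
  while (length(zeros) < n) {
    hi <- lo + 0.5
    if (besselJ(lo, 0) * besselJ(hi, 0) < 0) {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (besselJ(lo, 0) * besselJ(mid, 0) <= 0) hi <- mid else lo <- mid
      }
      zeros <- c(zeros, (lo + hi) / 2)
    }
    lo <- hi
  }
  zeros
}

# volume-weighted median by explicit cumulative enumeration
ref_vw_median <- function(x, v) {
  o <- order(x)
  x <- x[o]; v <- v[o]
  cum <- cumsum(v)
  x[min(which(cum >= sum(v) / 2))]
}

make_test_pop <- function(n = 40, seed = 7) {
  set.seed(seed)
  len <- exp(rnorm(n, log(15), 0.5))
  dia <- pmin(len, exp(rnorm(n, log(9), 0.4)))
  particle_population(len, dia)
}
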