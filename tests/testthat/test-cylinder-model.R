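test_that("J0 zeros are correct, ordered, and asymptotically pi-spaced", {
  a <- bessel_j0_zeros(50)
  expect_equal(a[1], 2.404826, tolerance = 1e-6)
  expect_true(all(abs(besselJ(a, 0)) < 1e-10))
  expect_true(all(diff(a) > 0))
  expect_lt(abs((a[20] - a[19]) - pi), 1e-3)
  expect_equal(a[1:10], ref_j0_zeros(10), tolerance = 1e-9)
  expect_error(bessel_j0_zeros(0), ">= 1")
})

test_that("single-cylinder uptake honors limits and matches reference sum", {
  D <- 1e-12; R <- 9.5e-6; L <- 3.2e-5
  expect_identical(uptake_fraction_cylinder(0, D, R, L), 0)
  t_inf <- 100 * max(R, L)^2 / D
  expect_equal(uptake_fraction_cylinder(t_inf, D, R, L), 1,
               tolerance = 1e-10)
  tt <- c(0.5, 2, 5, 20, 60, 200)
  expect_equal(uptake_fraction_cylinder(tt, D, R, L),
               ref_uptake(tt, D, R, L), tolerance = 1e-10)
  expect_error(uptake_fraction_cylinder(-1, D, R, L), "t")
  expect_error(uptake_fraction_cylinder(1, -D, R, L), "D")
  expect_error(uptake_fraction_cylinder(1, D, 0, L), "radius")
})

test_that("uptake is monotone in time and diffusivity and scale invariant", {
  R <- 5e-6; L <- 1.5e-5
  tt <- exp(seq(log(0.01), log(500), length.out = 40))
  f <- uptake_fraction_cylinder(tt, 1e-12, R, L)
  expect_true(all(diff(f) >= 0))
  unsat <- f < 1 - 1e-12   # strictly increasing until saturated in doubles
  expect_true(all(diff(f[unsat]) > 0))
  f_fast <- uptake_fraction_cylinder(10, 5e-12, R, L)
  f_slow <- uptake_fraction_cylinder(10, 1e-12, R, L)
  expect_gt(f_fast, f_slow)
  # (R, L, t) -> (aR, aL, a^2 t) leaves the fraction unchanged
  a <- 3.7
  expect_equal(uptake_fraction_cylinder(tt, 1e-12, R, L),
               uptake_fraction_cylinder(a^2 * tt, 1e-12, a * R, a * L),
               tolerance = 1e-12)
})

test_that("finite-cylinder remainder factorizes into radial x axial parts", {
  # exact algebraic identity at fixed term counts: 1 - f equals the product
  # of the radial (Bessel) and axial (Fourier) partial-sum remainders
  D <- 2e-12; R <- 6e-6; L <- 1.8e-5
  tt <- c(1, 5, 20, 80)
  alpha <- bessel_j0_zeros(50)
  k <- 2 * (0:49) + 1
  Sr <- vapply(tt, function(tv) sum(4 / alpha^2 * exp(-alpha^2 * D * tv / R^2)),
               numeric(1))
  Sz <- vapply(tt, function(tv)
    sum(8 / (k^2 * pi^2) * exp(-k^2 * pi^2 * D * tv / L^2)), numeric(1))
  f_fin <- uptake_fraction_cylinder(tt, D, R, L,
                                    series_config(50, 50, tail_tol = 0))
  expect_equal(1 - f_fin, Sr * Sz, tolerance = 1e-12)
})

test_that("plane-sheet and infinite-cylinder limits are recovered", {
  # when one dimension is 1e3 x the other, the finite-cylinder solution
  # approaches the 1D limit; the residual axial (or radial) uptake scales
  # with sqrt(Fo) of the dropped dimension, so late times converge tightest
  D <- 2e-12; R <- 6e-6
  cfg <- series_config(400, 400, tail_tol = 0)
  alpha <- bessel_j0_zeros(400)
  fo_r <- c(0.2, 1, 2)
  tt <- fo_r * R^2 / D
  f_cyl_ref <- vapply(tt, function(tv)
    1 - sum(4 / alpha^2 * exp(-alpha^2 * D * tv / R^2)), numeric(1))
  f <- uptake_fraction_cylinder(tt, D, R, 1e3 * R, cfg)
  rel <- abs(f - f_cyl_ref) / f_cyl_ref
  expect_lt(rel[1], 1e-3)
  expect_lt(rel[3], 1e-6)
  L <- 1.2e-5
  k <- 2 * (0:399) + 1
  fo_z <- c(0.2, 1, 2)
  tz <- fo_z * L^2 / D
  f_sheet_ref <- vapply(tz, function(tv)
    1 - sum(8 / (k^2 * pi^2) * exp(-k^2 * pi^2 * D * tv / L^2)), numeric(1))
  f2 <- uptake_fraction_cylinder(tz, D, 1e3 * L, L, cfg)
  rel2 <- abs(f2 - f_sheet_ref) / f_sheet_ref
  expect_lt(rel2[1], 1e-3)
  expect_lt(rel2[3], 1e-6)
})

test_that("population model validates weights and reduces to one class", {
  expect_error(population_model(1e-5, 5e-6, 0.9), "sum to 1")
  expect_error(population_model(c(1e-5, 2e-5), 5e-6, c(0.5, 0.5)),
               "equal length")
  mod1 <- population_model(2e-5, 7e-6, 1, M_inf = 0.3)
  tt <- c(0, 1, 10, 100)
  expect_equal(population_uptake(tt, 1e-12, mod1),
               0.3 * uptake_fraction_cylinder(tt, 1e-12, 7e-6, 2e-5))
  # two identical classes at w = 0.5 merge invariantly
  mod2 <- population_model(rep(2e-5, 2), rep(7e-6, 2), c(0.5, 0.5),
                           M_inf = 0.3)
  expect_equal(population_uptake(tt, 1e-12, mod2),
               population_uptake(tt, 1e-12, mod1))
})

test_that("population uptake equals brute-force weighted summation", {
  set.seed(21)
  n <- 10
  L <- exp(rnorm(n, log(2e-5), 0.4))
  R <- exp(rnorm(n, log(6e-6), 0.4))
  w <- runif(n); w <- w / sum(w)
  mod <- population_model(L, R, w)
  tt <- c(0.5, 3, 12, 60, 300)
  direct <- colSums(w * t(sapply(seq_len(n), function(i)
    ref_uptake(tt, 2.5e-12, R[i], L[i]))))
  expect_equal(population_uptake(tt, 2.5e-12, mod, fraction = TRUE), direct,
               tolerance = 1e-9)
})

test_that("model builders convert um grids and populations to SI classes", {
  pop <- make_test_pop()
  mod <- population_model_all_particles(pop)
  expect_equal(length(mod$weights), nrow(pop))
  expect_equal(mod$lengths_m, pop$length_um * 1e-6)
  expect_equal(mod$weights, pop$volume_um3 / sum(pop$volume_um3))
  g <- bin_population(pop, 10, "median")
  modg <- population_model_from_grid(g)
  expect_equal(modg$radii_m, g$rep_diameter_um / 2 * 1e-6)
  desc <- global_descriptor(pop, "median", "volume")
  mods <- population_model_single(desc)
  expect_equal(mods$lengths_m, desc$length * 1e-6)
  expect_equal(mods$weights, 1)
})

test_that("finite-difference solver reproduces the analytical series", {
  D <- 1e-12; R <- 1e-5; L <- 2e-5
  tt <- R^2 / D * exp(seq(log(3e-4), log(2), length.out = 12))
  fd <- fd_uptake_cylinder(tt, D, R, L, nr = 120, nz = 120)
  an <- uptake_fraction_cylinder(tt, D, R, L)
  expect_lt(max(abs(fd - an)), 1e-3)
  expect_identical(fd_uptake_cylinder(0, D, R, L, nr = 10, nz = 10), 0)
  t_long <- 3 * max(R, L)^2 / D
  expect_equal(fd_uptake_cylinder(t_long, D, R, L, nr = 60, nz = 60), 1,
               tolerance = 1e-3)
})
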