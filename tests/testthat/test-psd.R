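test_that("cylinder volume follows pi r^2 L and rejects bad input", {
  expect_equal(cylinder_volume(10, 10), 250 * pi)
  expect_equal(cylinder_volume(1, 2), pi)
  expect_equal(cylinder_volume(18, 15), 1012.5 * pi)
  expect_equal(cylinder_volume(c(10, 1), c(10, 2)), c(250 * pi, pi))
  expect_error(cylinder_volume(0, 5), "> 0")
  expect_error(cylinder_volume(5, -1), "> 0")
})

test_that("population canonicalizes swapped axes and derives volumes", {
  expect_warning(pop <- particle_population(c(5, 3), c(2, 8)), "swapped")
  expect_equal(pop$length_um, c(5, 8))
  expect_equal(pop$diameter_um, c(2, 3))
  expect_equal(pop$volume_um3, cylinder_volume(pop$length_um, pop$diameter_um))
  expect_error(particle_population(numeric(0), numeric(0)), "empty")
  expect_error(particle_population(c(5, 3), c(2, 8), canonicalize = FALSE),
               "row")
})

test_that("global descriptors match hand-computed weighted statistics", {
  # identical particles: every statistic/weighting degenerates to the particle
  pop_id <- particle_population(rep(5, 6), rep(2, 6))
  for (s in c("mean", "median")) for (w in c("number", "volume")) {
    d <- global_descriptor(pop_id, s, w)
    expect_equal(c(d$length, d$diameter), c(5, 2))
  }
  # two particles with volumes v and 8v
  pop2 <- particle_population(c(1, 2), c(1, 2))
  expect_equal(global_descriptor(pop2, "mean", "volume")$length, 17 / 9)
  expect_equal(global_descriptor(pop2, "mean", "number")$length, 1.5)
  expect_equal(global_descriptor(pop2, "median", "volume")$length, 2)
  # random population vs enumeration oracle
  pop <- make_test_pop()
  d <- global_descriptor(pop, "median", "volume")
  expect_equal(d$length, ref_vw_median(pop$length_um, pop$volume_um3))
  expect_equal(d$diameter, ref_vw_median(pop$diameter_um, pop$volume_um3))
})

test_that("aspect ratio histogram is normalized and places single bin", {
  pop <- particle_population(rep(3, 4), rep(2, 4))
  h <- aspect_ratio_distribution(pop, bin_width = 0.25)
  expect_equal(nrow(h), 1)
  expect_equal(h$frequency, 1)
  expect_true(h$ratio_lo <= 1.5 && 1.5 < h$ratio_hi)
  h2 <- aspect_ratio_distribution(make_test_pop(), bin_width = 0.1)
  expect_equal(sum(h2$frequency), 1)
  h3 <- aspect_ratio_distribution(make_test_pop(), bin_width = 0.1,
                                  weighting = "number")
  expect_equal(sum(h3$frequency), 1)
})

test_that("size-class grid reproduces printed cell counts on 120x60 domain", {
  pop <- make_test_pop()
  counts <- c("20" = 18, "10" = 72, "5" = 288, "2.5" = 1152, "1" = 7200)
  for (mesh in names(counts)) {
    g <- bin_population(pop, as.numeric(mesh), "center", domain = c(120, 60))
    expect_identical(attr(g, "n_cells"), as.integer(counts[[mesh]]))
  }
})

test_that("grid weights sum to one and are mesh-invariant", {
  pop <- make_test_pop(n = 120, seed = 11)
  for (mesh in c(20, 10, 3, 0.5)) {
    g <- bin_population(pop, mesh, "mean")
    expect_equal(sum(g$weight), 1, tolerance = 1e-12)
    expect_true(all(g$weight >= 0))
    expect_equal(sum(g$count), nrow(pop))
  }
})

test_that("single-particle class reduces to the particle for mean/median", {
  pop <- particle_population(7, 3)
  for (d in c("mean", "median")) {
    g <- bin_population(pop, 10, d)
    expect_equal(nrow(g), 1)
    expect_equal(c(g$rep_length_um, g$rep_diameter_um), c(7, 3))
    expect_equal(g$weight, 1)
  }
  gc <- bin_population(pop, 10, "center")
  expect_equal(c(gc$rep_length_um, gc$rep_diameter_um), c(5, 5))
})

test_that("tiny mesh makes mean/median exact per particle, center not", {
  pop <- make_test_pop(n = 25, seed = 3)
  for (d in c("mean", "median")) {
    g <- bin_population(pop, 0.01, d)
    expect_equal(nrow(g), nrow(pop))
    expect_equal(sort(g$rep_length_um), sort(pop$length_um), tolerance = 1e-9)
  }
  gc <- bin_population(pop, 0.01, "center")
  expect_gt(max(abs(sort(gc$rep_length_um) - sort(pop$length_um))), 0)
})

test_that("binning validates mesh and explicit domain", {
  pop <- particle_population(c(7, 40), c(3, 20))
  expect_error(bin_population(pop, 0), "mesh")
  expect_error(bin_population(pop, 10, domain = c(30, 60)), "row")
  # particle exactly at the domain maximum goes in the last cell
  pop_edge <- particle_population(120, 60)
  g <- bin_population(pop_edge, 10, "center", domain = c(120, 60))
  expect_equal(c(g$class_i, g$class_j), c(11, 5))
})

test_that("2D histogram normalizes under both weightings", {
  pop1 <- particle_population(7, 3)
  for (w in c("number", "volume")) {
    h <- histogram_2d(pop1, 1, w)
    expect_equal(nrow(h), 1)
    expect_equal(h$frequency, 1)
  }
  # two equal-volume particles in different cells: 0.5 each in volume
  pop2 <- particle_population(c(4, 16), c(4, 2))
  h2 <- histogram_2d(pop2, 1, "volume")
  expect_equal(h2$frequency, c(0.5, 0.5))
  # number- vs volume-weighted tables checked against direct accumulation
  pop <- make_test_pop(n = 60, seed = 5)
  hv <- histogram_2d(pop, 2, "volume")
  hn <- histogram_2d(pop, 2, "number")
  key <- paste(floor(pop$length_um / 2), floor(pop$diameter_um / 2))
  for (k in seq_len(nrow(hv))) {
    sel <- key == paste(hv$length_lo[k] / 2, hv$diameter_lo[k] / 2)
    expect_equal(hv$frequency[k],
                 sum(pop$volume_um3[sel]) / sum(pop$volume_um3))
  }
  expect_gt(max(abs(hv$frequency - hn$frequency[match(
    paste(hv$length_lo, hv$diameter_lo),
    paste(hn$length_lo, hn$diameter_lo))])), 0)
})

test_that("particle reader accepts ImageJ and explicit dialects", {
  path <- system.file("extdata", "example_particles.csv", package = "cyldiff")
  pop <- read_particles(path)
  expect_s3_class(pop, "particle_population")
  expect_equal(nrow(pop), 24)
  expect_true(all(pop$length_um >= pop$diameter_um))

  tmp <- tempfile(fileext = ".csv")
  write_particles(pop, tmp)
  pop2 <- read_particles(tmp)
  expect_equal(pop2$length_um, pop$length_um)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("Major,Minor", "5,3", "NA,2", "4,"), bad)
  expect_error(read_particles(bad), "row")
  ugly <- tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), ugly)
  expect_error(read_particles(ugly), "expected columns")
})

test_that("grid CSV round-trips through write_grid/read_grid", {
  g <- bin_population(make_test_pop(), 10, "median")
  tmp <- tempfile(fileext = ".csv")
  write_grid(g, tmp)
  g2 <- read_grid(tmp)
  expect_equal(g2$weight, g$weight)
  expect_equal(g2$rep_length_um, g$rep_length_um)
  mod <- population_model_from_grid(g2)
  expect_equal(sum(mod$weights), 1)
})
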