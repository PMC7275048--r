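test_that("energy unit conversions round-trip exactly", {
  expect_equal(kj_to_kcal(0.3), 0.0717, tolerance = 1e-4)
  x <- c(0.3, 1, 25.7)
  expect_equal(kcal_to_kj(kj_to_kcal(x)), x, tolerance = 1e-12)
})

test_that("adaptive widths are windowed sds clipped at the floor", {
  const <- data.frame(time = 1:10 / 10, s = rep(1, 10), z = rep(2, 10))
  expect_equal(unname(adaptive_width(const, window = 1, floor = 0.03)),
               c(0.03, 0.03))
  set.seed(1)
  h <- data.frame(s = rnorm(200, sd = 0.1), z = rnorm(200, sd = 0.5))
  w <- adaptive_width(h, floor = 0.03)
  expect_equal(unname(w), c(sd(h$s), sd(h$z)), tolerance = 1e-12)
  expect_error(adaptive_width(data.frame(s = 1, z = 1)), "fewer than 2")
})

test_that("deposits store kcal/mol heights and enforce the width floor", {
  log <- hill_log(stride = 1)
  log <- deposit(log, c(1, 0), c(0.1, 0.1), height = 0.3, units = "kJ/mol")
  expect_equal(nrow(log$hills), 1L)
  expect_equal(log$hills$height, 0.0717, tolerance = 1e-4)
  expect_error(deposit(log, c(1, 0), c(0.01, 0.1), 0.3), "floor")
  for (i in 2:50) log <- deposit(log, c(i / 10, 0), c(0.1, 0.1), 0.3)
  expect_equal(log$hills$time[50], 50)
})

test_that("bias_at sums Gaussians and matches a direct loop", {
  log <- deposit(hill_log(), c(1, 2), c(0.2, 0.5), height = 1,
                 units = "kcal/mol")
  expect_equal(bias_at(log, c(1, 2)), 1)
  expect_lt(bias_at(log, c(1 + 5 * 0.2, 2)), 1e-4)
  set.seed(2)
  for (i in 1:40) {
    log <- deposit(log, rnorm(2), c(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3)),
                   height = runif(1, 0.1, 1), units = "kcal/mol")
  }
  pt <- c(0.3, -0.2)
  manual <- 0
  for (i in seq_len(nrow(log$hills))) {
    h <- log$hills[i, ]
    manual <- manual + h$height * exp(-(pt[1] - h$s)^2 / (2 * h$sigma_s^2)
                                      - (pt[2] - h$z)^2 / (2 * h$sigma_z^2))
  }
  expect_equal(bias_at(log, pt), manual, tolerance = 1e-12)
  # time-resolved sum respects up_to_time
  half <- log$hills$time[20]
  sub <- log; sub$hills <- log$hills[log$hills$time <= half, ]
  expect_equal(bias_at(log, pt, up_to_time = half), bias_at(sub, pt),
               tolerance = 1e-14)
})

test_that("the reconstructed FES is the negated bias, shifted to zero", {
  log <- deposit(hill_log(), c(0, 0), c(0.3, 0.3), height = 2,
                 units = "kcal/mol")
  fes <- reconstruct_fes(log, s_axis = seq(-2, 2, length.out = 81),
                         z_axis = seq(-2, 2, length.out = 81))
  expect_equal(min(fes$values), 0)
  # single hill: an inverted well of depth = height at center
  expect_equal(fes$values[41, 41], 0)
  expect_equal(fes$values[1, 1], 2, tolerance = 1e-3)
  # grid values equal direct bias summation everywhere (up to the shift)
  direct <- vapply(seq(-2, 2, length.out = 81),
                   function(s) bias_at(log, c(s, 0)), numeric(1))
  expect_equal(fes$values[, 41], max(direct) - direct + fes$values[41, 41],
               tolerance = 1e-12)
  # symmetric two-hill log gives a symmetric surface
  log2 <- deposit(deposit(hill_log(), c(-1, 0), c(0.3, 0.3), 1, "kcal/mol"),
                  c(1, 0), c(0.3, 0.3), 1, "kcal/mol")
  f2 <- reconstruct_fes(log2, s_axis = seq(-2, 2, length.out = 81),
                        z_axis = seq(-1, 1, length.out = 21))
  expect_equal(f2$values, f2$values[81:1, ], tolerance = 1e-10)
  expect_error(reconstruct_fes(hill_log()), "empty")
})

test_that("minimax barriers match construction and brute force", {
  sax <- seq(-1.5, 1.5, length.out = 61)
  zax <- seq(-1, 1, length.out = 41)
  land <- gen_toy_landscape("double-well", barrier = 5)
  vals <- outer(sax, zax, function(s, z) land$f(s, z))
  fes <- structure(list(s_axis = sax, z_axis = zax, values = vals),
                   class = "free_energy_surface")
  bb <- basins_and_barrier(fes, list(s = c(-1.3, -0.7), z = c(-0.5, 0.5)),
                           list(s = c(0.7, 1.3), z = c(-0.5, 0.5)))
  expect_equal(bb$barrier, 5, tolerance = 0.05)
  expect_equal(bb$offset, 0, tolerance = 1e-9)
  expect_gte(bb$saddle, bb$basin_b$value)
  # single-well surface: no local minimum in the far hint region
  bowl <- structure(list(s_axis = sax, z_axis = zax,
                         values = outer(sax, zax, function(s, z) s^2 + z^2)),
                    class = "free_energy_surface")
  expect_error(basins_and_barrier(bowl, list(s = c(-0.1, 0.1), z = c(-0.1, 0.1)),
                                  list(s = c(1.2, 1.5), z = c(-1, 1))),
               "local minimum")
  # random smooth surfaces vs exhaustive flood-fill oracle on coarse grids
  for (s in 1:6) {
    set.seed(s)
    g <- matrix(rnorm(15 * 12), 15, 12)
    g <- (g + g[, 12:1]) / 2 + outer(seq(-2, 2, length.out = 15)^2,
                                     rep(1, 12))
    from <- c(2, 3); to <- c(14, 10)
    got <- introntoggle:::minimax_connect(g, from, to)
    expect_equal(got, minimax_bruteforce(g, from, to), tolerance = 1e-12)
  }
})

test_that("raising the saddle raises the minimax barrier", {
  sax <- seq(-1.5, 1.5, length.out = 41)
  zax <- seq(-1, 1, length.out = 21)
  base <- outer(sax, zax, function(s, z) 3 * (s^2 - 1)^2 + z^2)
  hints <- list(list(s = c(-1.2, -0.8), z = c(-0.3, 0.3)),
                list(s = c(0.8, 1.2), z = c(-0.3, 0.3)))
  b0 <- -Inf
  for (lift in c(0, 1, 2)) {
    v <- base + lift * exp(-(outer(sax, zax, function(s, z) s^2 + z^2)) / 0.1)
    fes <- structure(list(s_axis = sax, z_axis = zax, values = v - min(v)),
                     class = "free_energy_surface")
    b <- basins_and_barrier(fes, hints[[1]], hints[[2]])$barrier
    expect_gte(b, b0)
    b0 <- b
  }
})

test_that("hill logs round-trip through the plain-text dialect", {
  set.seed(9)
  log <- hill_log(stride = 1)
  for (i in 1:20) {
    log <- deposit(log, rnorm(2), c(runif(1, 0.05, 0.2), runif(1, 0.05, 0.2)),
                   height = 0.3, units = "kJ/mol")
  }
  path <- withr::local_tempfile()
  write_hills(log, path)
  back <- read_hills(path)
  expect_equal(back$hills$height, log$hills$height, tolerance = 1e-9)
  expect_equal(back$hills$s, log$hills$s, tolerance = 1e-9)
  expect_equal(back$stride, 1)
})

test_that("the Langevin sampler is seed-reproducible and stationary at zero noise", {
  flat <- function(s, z) 0 * s
  still <- langevin_sample(flat, steps = 200, dt = 0.01, temperature = 0,
                           seed = 1, x0 = c(0.5, -0.5), deposit_hills = FALSE)
  expect_true(all(abs(still$cv$s - 0.5) < 1e-12))
  expect_true(all(abs(still$cv$z + 0.5) < 1e-12))
  land <- gen_toy_landscape("double-well")
  r1 <- langevin_sample(land, steps = 3000, seed = 42)
  r2 <- langevin_sample(land, steps = 3000, seed = 42)
  expect_identical(r1$log$hills, r2$log$hills)
  r3 <- langevin_sample(land, steps = 3000, seed = 43)
  expect_false(identical(r3$log$hills$s, r1$log$hills$s))
  # divergence guard
  steep <- function(s, z) -100 * s
  expect_error(langevin_sample(steep, steps = 5000, dt = 0.05,
                               temperature = 0, seed = 1, x0 = c(0.1, 0),
                               deposit_hills = FALSE), "smaller dt")
})

test_that("unbiased harmonic sampling satisfies equipartition", {
  k <- 4
  well <- function(s, z) 0.5 * k * s^2 + 0.5 * k * z^2
  kT <- 1.987204258640832e-3 * 300
  run <- langevin_sample(well, steps = 400000, dt = 0.005, temperature = 300,
                         seed = 7, x0 = c(0, 0), deposit_hills = FALSE)
  burn <- -(1:20000)
  expect_equal(var(run$cv$s[burn]), kT / k, tolerance = 0.05)
  expect_equal(var(run$cv$z[burn]), kT / k, tolerance = 0.05)
})

test_that("a far-away constant hill shifts the surface but not the barrier", {
  land <- gen_toy_landscape("double-well", barrier = 2)
  sax <- seq(-1.5, 1.5, length.out = 41); zax <- seq(-1, 1, length.out = 21)
  mk_fes <- function(log) reconstruct_fes(log, s_axis = sax, z_axis = zax)
  # two hill clusters create two pronounced FES wells at (-1, 0) and (1, 0)
  log <- hill_log()
  set.seed(12)
  for (i in 1:15) {
    log <- deposit(log, c(-1 + rnorm(1, sd = 0.1), rnorm(1, sd = 0.1)),
                   c(0.25, 0.25), 1, "kcal/mol")
    log <- deposit(log, c(1 + rnorm(1, sd = 0.1), rnorm(1, sd = 0.1)),
                   c(0.25, 0.25), 1, "kcal/mol")
  }
  hints <- list(list(s = c(-1.4, -0.6), z = c(-0.6, 0.6)),
                list(s = c(0.6, 1.4), z = c(-0.6, 0.6)))
  b0 <- basins_and_barrier(mk_fes(log), hints[[1]], hints[[2]])
  # a wide hill centered far outside the grid is ~constant over it
  log2 <- deposit(log, c(500, 0), c(2000, 2000), 1, "kcal/mol")
  b1 <- basins_and_barrier(mk_fes(log2), hints[[1]], hints[[2]])
  expect_equal(b1$barrier, b0$barrier, tolerance = 1e-3)
  expect_equal(b1$offset, b0$offset, tolerance = 1e-3)
})
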