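test_that("pair_distance computes Euclidean distances per frame", {
  topo <- as_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  traj <- as_trajectory(topo)
  d <- pair_distance(traj, 1L, 2L)
  expect_equal(d$values, 5)
  expect_equal(d$units, "A")
  # multi-atom selection is a selection error
  expect_error(pair_distance(traj, "elem C", 2L), "exactly one atom")
})

test_that("synthetic active-site fixtures hit their descriptor targets", {
  st <- gen_active_site_frame(2.70, 0.17, target_dk1 = 4.3, noise_sd = 0)
  traj <- as_trajectory(st)
  d <- pair_distance(traj, "resnum 289 and name O2", "resnum 358 and name N4")
  a <- base_plane_angle(traj, 358, 385)
  k <- pair_distance(traj, "elem K", "resnum 288 and name N7")
  expect_equal(d$values, 2.70, tolerance = 1e-6)
  expect_equal(a$values, 0.17, tolerance = 1e-6)
  expect_equal(k$values, 4.3, tolerance = 1e-6)
  # with noise, targets are recovered within 3 noise sd
  stn <- gen_active_site_frame(2.70, 0.17, noise_sd = 0.05, seed = 2)
  dn <- pair_distance(as_trajectory(stn), "resnum 289 and name O2",
                      "resnum 358 and name N4")
  expect_lt(abs(dn$values - 2.70), 3 * 0.05 * sqrt(2))
})

test_that("base plane angles hit the coplanar and orthogonal limits", {
  st0 <- gen_active_site_frame(2.7, 0, noise_sd = 0)
  expect_equal(base_plane_angle(as_trajectory(st0), 358, 385)$values, 0,
               tolerance = 1e-9)
  st90 <- gen_active_site_frame(2.7, pi / 2, noise_sd = 0)
  expect_equal(base_plane_angle(as_trajectory(st90), 358, 385)$values,
               pi / 2, tolerance = 1e-9)
  # missing ring atom is a named descriptor error
  broken <- st0
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 385 &
                                 broken$atoms$name == "N9"), ]
  expect_error(base_plane_angle(as_trajectory(broken), 358, 385), "N9")
})

test_that("descriptors are invariant under rigid transforms of every frame", {
  st <- gen_active_site_frame(2.9, 0.3, noise_sd = 0.1, seed = 6)
  traj <- as_trajectory(st)
  d0 <- pair_distance(traj, "resnum 289 and name O2",
                      "resnum 358 and name N4")$values
  a0 <- base_plane_angle(traj, 358, 385)$values
  for (s in 1:3) {
    rig <- random_rigid(s + 100)
    st2 <- st
    xyz <- apply_rigid(coords(st), rig)
    st2$atoms$x <- xyz[, 1]; st2$atoms$y <- xyz[, 2]; st2$atoms$z <- xyz[, 3]
    t2 <- as_trajectory(st2)
    expect_equal(pair_distance(t2, "resnum 289 and name O2",
                               "resnum 358 and name N4")$values, d0,
                 tolerance = 1e-6)
    expect_equal(base_plane_angle(t2, 358, 385)$values, a0,
                 tolerance = 1e-6)
  }
})

test_that("triple-helix classification respects thresholds and boundaries", {
  t <- 0:2
  d <- descriptor_series("d", t, c(2.7, 4.88, 3.0), "A")
  a <- descriptor_series("alpha", t, c(0.17, 0.63, 0.35), "rad")
  s <- classify_triple_helix(d, a)
  expect_equal(as.character(s$labels),
               c("TRIPLE_HELIX", "DISRUPTED", "TRIPLE_HELIX"))
  # time misalignment is an error
  a2 <- descriptor_series("alpha", t + 0.5, a$values, "rad")
  expect_error(classify_triple_helix(d, a2), "align")
})

test_that("classification is monotone in d and alpha", {
  set.seed(31)
  t <- seq_len(200) - 1
  d0 <- runif(200, 1, 6); a0 <- runif(200, 0, 1.2)
  lab0 <- classify_triple_helix(descriptor_series("d", t, d0, "A"),
                                descriptor_series("a", t, a0, "rad"))$labels
  for (bump in c(0.3, 1, 2)) {
    lab1 <- classify_triple_helix(
      descriptor_series("d", t, d0 + bump, "A"),
      descriptor_series("a", t, a0, "rad"))$labels
    # increasing d never converts DISRUPTED -> TRIPLE_HELIX
    expect_false(any(lab0 == "DISRUPTED" & lab1 == "TRIPLE_HELIX"))
  }
})

test_that("ion-release detection emits events per the dwell contract", {
  # constant bound series: no events
  t <- seq(0, 200, by = 0.5)
  flat <- descriptor_series("d", t, rep(2.9, length(t)), "A")
  expect_equal(nrow(detect_ion_release(flat)), 0L)
  # step series: bound until 100 ns, released after
  step <- descriptor_series("d", t, ifelse(t < 100, 2.9, 8.0), "A")
  ev <- detect_ion_release(step, bound_cutoff = 3.5, released_cutoff = 6.0,
                           dwell = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$release_time, 100, tolerance = 0.5)
  # no event when max(d) <= released_cutoff
  mid <- descriptor_series("d", t, ifelse(t < 100, 2.9, 5.5), "A")
  expect_equal(nrow(detect_ion_release(mid)), 0L)
  # dwell beyond the series span is a parameter error
  expect_error(detect_ion_release(step, dwell = 500), "dwell")
  # brief excursions shorter than the dwell are not release events
  blip <- descriptor_series("d", t, ifelse(t >= 100 & t < 100.5, 8, 2.9), "A")
  expect_equal(nrow(detect_ion_release(blip, dwell = 1)), 0L)
})

test_that("re-binding after release can start a second event", {
  t <- seq(0, 300, by = 0.5)
  v <- rep(2.9, length(t))
  v[t >= 100 & t < 150] <- 8
  v[t >= 200] <- 8
  two <- detect_ion_release(descriptor_series("d", t, v, "A"), dwell = 1)
  expect_equal(nrow(two), 2L)
  expect_equal(two$release_time, c(100, 200), tolerance = 0.5)
})

test_that("series summaries use the equilibration discard", {
  t <- seq(0, 99)
  expect_equal(summarize_series(descriptor_series("d", t, rep(4.24, 100), "A"),
                                discard = 0),
               list(mean = 4.24, sd = 0, n_frames = 100L, discard = 0))
  s <- summarize_series(descriptor_series("d", 0:27, c(rep(9, 25), 1, 2, 3),
                                          "A"), discard = 25)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n_frames, 3L)
  expect_error(summarize_series(descriptor_series("d", 0:5, 1:6, "A"),
                                discard = 25), "fewer than 2")
})

test_that("generator emission statistics are recovered by summarize_series", {
  p <- toggling_params(rate_th_to_t = 1e-9, rate_t_to_th = 1, n_frames = 10000L,
                       dt = 0.1, seed = 99L)
  g <- gen_toggling_series(p)
  s <- summarize_series(g$d_k1, discard = 0)
  se_mean <- 0.27 / sqrt(10000)
  expect_lt(abs(s$mean - 2.98), 3 * se_mean)
  se_sd <- 0.27 / sqrt(2 * (10000 - 1))
  expect_lt(abs(s$sd - 0.27), 3 * se_sd)
})

test_that("coordination counts match a brute-force recount", {
  # ion with exactly 4 atoms at 2.8 A
  ring <- rbind(c(2.8, 0, 0), c(-2.8, 0, 0), c(0, 2.8, 0), c(0, -2.8, 0),
                c(0, 0, 9))
  topo <- new_structure(data.frame(
    serial = 1:6, name = c("K", paste0("O", 1:5)), resname = c("K", rep("HOH", 5)),
    resno = 1:6, chain = "A", element = c("K", rep("O", 5)),
    x = c(0, ring[, 1]), y = c(0, ring[, 2]), z = c(0, ring[, 3]),
    stringsAsFactors = FALSE))
  traj <- as_trajectory(topo)
  expect_equal(coordination_count(traj, "elem K", 3.5)$values, 4)
  expect_equal(coordination_count(traj, "elem K", 2.0)$values, 0)
  # randomized fixtures vs direct O(n) recount
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:30, 1)
    xyz <- rbind(c(0, 0, 0), matrix(rnorm(3 * n, sd = 3), n))
    st <- as_structure(xyz)
    st$atoms$element[1] <- "K"; st$atoms$name[1] <- "K"
    got <- coordination_count(as_trajectory(st), 1L, 3.5)$values
    want <- sum(sqrt(rowSums(xyz[-1, , drop = FALSE]^2)) <= 3.5)
    expect_identical(got, as.numeric(want))
  }
})

test_that("state-label fraction converges to the Markov stationary occupancy", {
  p <- toggling_params(rate_th_to_t = 0.05, rate_t_to_th = 0.05,
                       n_frames = 20000L, dt = 0.5, seed = 13L,
                       k1_reversible = TRUE)
  g <- gen_toggling_series(p)
  lab <- classify_triple_helix(g$d, g$alpha)$labels
  frac <- mean(lab == "TRIPLE_HELIX")
  # binomial-style se inflated by the dwell correlation length
  n_eff <- 20000 * 0.5 * 0.05  # ~ number of independent dwells
  se <- 0.5 / sqrt(n_eff)
  expect_lt(abs(frac - g$truth$stationary_th), 3 * se + 0.02)
})
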