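# Idealized planar base templates (2D ring coordinates, Angstrom; z = 0).
# Any planar geometry works for plane-angle descriptors; bond lengths are
# near-literature ring dimensions.
base_template <- function(kind = c("pyrimidine", "purine")) {
  kind <- match.arg(kind)
  hex <- function(r, phase = 0) {
    ang <- phase + seq(0, by = pi / 3, length.out = 6L)
    cbind(r * cos(ang), r * sin(ang), 0)
  }
  if (kind == "pyrimidine") {
    xy <- hex(1.38)
    rownames(xy) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    # exocyclic substituents, in-plane, 1.23-1.34 A from their ring carbon
    o2 <- xy["C2", 1:2] * (1 + 1.23 / 1.38)
    n4 <- xy["C4", 1:2] * (1 + 1.34 / 1.38)
    rbind(xy, O2 = c(o2, 0), N4 = c(n4, 0))
  } else {
    xy6 <- hex(1.39)
    rownames(xy6) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    # fused five-membered ring on the C4-C5 edge
    mid <- (xy6["C4", 1:2] + xy6["C5", 1:2]) / 2
    out <- mid / sqrt(sum(mid^2))
    n7 <- xy6["C5", 1:2] + 1.38 * out
    c8 <- mid + 2.1 * out
    n9 <- xy6["C4", 1:2] + 1.38 * out
    o6 <- xy6["C6", 1:2] * (1 + 1.23 / 1.39)
    rbind(xy6, N7 = c(n7, 0), C8 = c(c8, 0), N9 = c(n9, 0), O6 = c(o6, 0))
  }
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3L, 3L, byrow = TRUE)

#' Generate an idealized active-site fragment hitting target descriptors
#'
#' Builds a synthetic fragment — C289 (junction), C358 and its Watson-Crick
#' partner G385, G288 with its Hoogsteen face, and a potassium ion — with
#' ring atoms placed so that the three core descriptors evaluate to the
#' requested targets: d(289-358) = O2(289)-N4(358) distance, alpha =
#' base-plane angle 358/385, and d(K1-N7) = K to N7(288). Gaussian
#' coordinate noise of `noise_sd` is then added. Seed-deterministic.
#'
#' @param target_d Target O2(289)-N4(358) distance, Angstrom (> 0).
#' @param target_alpha Target plane angle, rad, in `[0, pi/2]`.
#' @param target_dk1 Target K-N7(288) distance, Angstrom (default 2.98).
#' @param noise_sd Per-coordinate Gaussian noise, Angstrom (default 0).
#' @param seed RNG seed (default 1).
#' @return An `intron_structure` (synthetic; residues numbered 288, 289,
#'   358, 385 plus a K ion).
#' @export
gen_active_site_frame <- function(target_d, target_alpha, target_dk1 = 2.98,
                                  noise_sd = 0, seed = 1L) {
  if (target_d <= 0) stop("gen_active_site_frame: target_d must be positive")
  if (target_alpha < 0 || target_alpha > pi / 2) {
    stop("gen_active_site_frame: target_alpha outside [0, pi/2]")
  }
  set.seed(as.integer(seed))
  pyr <- base_template("pyrimidine")
  pur <- base_template("purine")

  # C358 at the origin, in the xy plane
  c358 <- pyr
  # G385 rotated by target_alpha about the x axis and shifted along +x
  g385 <- pur %*% t(rot_x(target_alpha))
  g385 <- sweep(g385, 2L, c(9, 0, 0), "+")
  # C289 placed so its O2 sits exactly target_d from N4 of C358, along -y
  n4 <- pyr["N4", ]
  o2_target <- n4 + c(0, -target_d, 0)
  c289 <- sweep(pyr, 2L, o2_target - pyr["O2", ], "+")
  # G288 off to the side; K ion exactly target_dk1 from its N7
  g288 <- sweep(pur, 2L, c(-9, 2, 1), "+")
  k_pos <- g288["N7", ] + target_dk1 * c(0, 0, 1)

  assemble <- function(m, resname, resno) {
    data.frame(name = rownames(m), resname = resname, resno = resno,
               x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
  }
  tab <- rbind(assemble(g288, "G", 288L), assemble(c289, "C", 289L),
               assemble(c358, "C", 358L), assemble(g385, "G", 385L),
               data.frame(name = "K", resname = "K", resno = 500L,
                          x = k_pos[1], y = k_pos[2], z = k_pos[3],
                          stringsAsFactors = FALSE))
  n <- nrow(tab)
  if (noise_sd > 0) {
    tab$x <- tab$x + rnorm(n, 0, noise_sd)
    tab$y <- tab$y + rnorm(n, 0, noise_sd)
    tab$z <- tab$z + rnorm(n, 0, noise_sd)
  }
  atoms <- data.frame(
    serial = seq_len(n), name = tab$name, resname = tab$resname,
    resno = tab$resno, chain = "A",
    element = ifelse(tab$name == "K", "K", substr(tab$name, 1L, 1L)),
    x = tab$x, y = tab$y, z = tab$z, stringsAsFactors = FALSE)
  new_structure(atoms)
}

#' Parameters for the two-state toggling generator
#'
#' Default emission means mirror the study conditions: triple helix at
#' d = 2.7 A, alpha = 0.17 rad, K1 bound at 2.98 A (sd 0.27 A) versus
#' toggled at 4.88 A, 0.63 rad, K1 released at 9 A. Per-state emission
#' widths for d and alpha are narrower than the trajectory-wide spreads
#' (which include inter-state drift): defaults keep each state's
#' distribution at least four standard deviations clear of the
#' classification thresholds, the regime the state classifier assumes.
#'
#' @param rate_th_to_t Triple-helix -> toggled rate, 1/ns (default 0.005).
#' @param rate_t_to_th Toggled -> triple-helix rate, 1/ns (default 0.005).
#' @param mean_th,sd_th Length-3 emission means/sds (d, alpha, d_K1) in the
#'   triple-helix state.
#' @param mean_t,sd_t Same for the toggled state.
#' @param dt Frame interval, ns (default 0.1).
#' @param n_frames Number of frames (default 5000).
#' @param seed RNG seed.
#' @param k1_reversible If `FALSE` (default) the K1 series switches to the
#'   released level at the first toggle and stays released (one-way
#'   release); if `TRUE` it follows the state.
#' @return A `toggling_params` list.
#' @export
toggling_params <- function(rate_th_to_t = 0.005, rate_t_to_th = 0.005,
                            mean_th = c(d = 2.7, alpha = 0.17, dk1 = 2.98),
                            sd_th = c(0.07, 0.04, 0.27),
                            mean_t = c(d = 4.88, alpha = 0.63, dk1 = 9),
                            sd_t = c(0.45, 0.07, 1.0),
                            dt = 0.1, n_frames = 5000L, seed = 1L,
                            k1_reversible = FALSE) {
  stopifnot(rate_th_to_t > 0, rate_t_to_th > 0, all(sd_th >= 0),
            all(sd_t >= 0), dt > 0, n_frames >= 2L)
  if (!(mean_th[1] <= 3 && mean_th[2] <= 0.35)) {
    stop("toggling_params: triple-helix emission means must satisfy the ",
         "classifier thresholds (d <= 3 A, alpha <= 0.35 rad)")
  }
  if (mean_t[1] <= 3 && mean_t[2] <= 0.35) {
    stop("toggling_params: toggled emission means must violate at least one ",
         "classifier threshold")
  }
  structure(list(rate_th_to_t = rate_th_to_t, rate_t_to_th = rate_t_to_th,
                 mean_th = mean_th, sd_th = sd_th, mean_t = mean_t,
                 sd_t = sd_t, dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), k1_reversible = k1_reversible),
            class = "toggling_params")
}

#' Generate a synthetic two-state toggling descriptor series
#'
#' Simulates a continuous-time two-state Markov chain (triple-helix <->
#' toggled) sampled at the frame interval, with Gaussian per-state emissions
#' for the three core descriptors. The K1-contact series follows the release
#' coupling: by default it jumps to the released level at the first toggling
#' event and stays there. The stationary triple-helix occupancy is
#' `rate_t_to_th / (rate_th_to_t + rate_t_to_th)`.
#'
#' @param params A [toggling_params()] object.
#' @return List with `d`, `alpha`, `d_k1` (`descriptor_series`) and `truth`
#'   (list: `states` factor per frame, `release_time` ns or NA, `params`).
#' @export
gen_toggling_series <- function(params) {
  stopifnot(inherits(params, "toggling_params"))
  set.seed(params$seed)
  n <- params$n_frames
  times <- (seq_len(n) - 1L) * params$dt
  total_t <- times[n]
  # exact CTMC path via Gillespie, then frame sampling
  t_now <- 0; state <- 1L  # 1 = triple helix, 2 = toggled
  sw_t <- numeric(0); sw_s <- integer(0)
  while (t_now < total_t) {
    rate <- if (state == 1L) params$rate_th_to_t else params$rate_t_to_th
    t_now <- t_now + rexp(1L, rate)
    state <- 3L - state
    if (t_now < total_t) { sw_t <- c(sw_t, t_now); sw_s <- c(sw_s, state) }
  }
  states <- integer(n); states[] <- 1L
  if (length(sw_t)) {
    idx <- findInterval(times, sw_t)
    states <- ifelse(idx == 0L, 1L, sw_s[pmax(idx, 1L)])
  }
  emit <- function(col) {
    mu <- ifelse(states == 1L, params$mean_th[col], params$mean_t[col])
    s <- ifelse(states == 1L, params$sd_th[col], params$sd_t[col])
    pmax(rnorm(n, mu, s), 0)
  }
  d_vals <- emit(1L)
  a_vals <- pmin(emit(2L), pi / 2)
  release_time <- NA_real_
  if (params$k1_reversible) {
    k1_states <- states
  } else {
    first_t <- which(states == 2L)[1L]
    k1_states <- rep(1L, n)
    if (!is.na(first_t)) {
      k1_states[first_t:n] <- 2L
      release_time <- times[first_t]
    }
  }
  mu_k <- ifelse(k1_states == 1L, params$mean_th[3L], params$mean_t[3L])
  s_k <- ifelse(k1_states == 1L, params$sd_th[3L], params$sd_t[3L])
  k_vals <- pmax(rnorm(n, mu_k, s_k), 0)
  truth <- list(
    states = factor(ifelse(states == 1L, "TRIPLE_HELIX", "DISRUPTED"),
                    levels = c("TRIPLE_HELIX", "DISRUPTED")),
    release_time = release_time,
    stationary_th = params$rate_t_to_th /
      (params$rate_th_to_t + params$rate_t_to_th),
    params = params)
  list(d = descriptor_series("d_289-358", times, d_vals, "A"),
       alpha = descriptor_series("alpha", times, a_vals, "rad"),
       d_k1 = descriptor_series("d_K1-N7G288", times, k_vals, "A"),
       truth = truth)
}

#' Generate a noisy band-fraction splicing time course
#'
#' Replicate-averaged fractions are the closed-form sequential-model values
#' plus truncated Gaussian noise, renormalized to sum to 1 per time point;
#' s.e.m. columns are populated when `n_replicates > 1`.
#'
#' @param k1,k2 True rate constants, 1/min.
#' @param times Sampling times, min.
#' @param noise_sd Per-band Gaussian noise s.d. (fraction units, default 0.02).
#' @param n_replicates Independent replicates averaged (default 3).
#' @param seed RNG seed.
#' @return A `kinetic_dataset`; the true rates are attached as attribute
#'   `truth`.
#' @export
gen_band_timecourse <- function(k1, k2, times = seq(0, 240, length.out = 12L),
                                noise_sd = 0.02, n_replicates = 3L,
                                seed = 1L) {
  set.seed(as.integer(seed))
  m <- sequential_model(k1, k2, times)
  clean <- as.matrix(m[, c("f_precursor", "f_intermediate", "f_product")])
  reps <- array(NA_real_, c(length(times), 3L, n_replicates))
  for (r in seq_len(n_replicates)) {
    noisy <- pmin(pmax(clean + matrix(rnorm(length(clean), 0, noise_sd),
                                      nrow(clean)), 0), 1)
    reps[, , r] <- noisy / rowSums(noisy)
  }
  avg <- apply(reps, c(1L, 2L), mean)
  avg <- avg / rowSums(avg)
  sem <- if (n_replicates > 1L) {
    s <- apply(reps, c(1L, 2L), stats::sd) / sqrt(n_replicates)
    data.frame(sem_precursor = s[, 1], sem_intermediate = s[, 2],
               sem_product = s[, 3])
  } else NULL
  ds <- kinetic_dataset(times, avg[, 1], avg[, 2], avg[, 3], sem = sem,
                        n_replicates = n_replicates)
  attr(ds, "truth") <- list(k1 = k1, k2 = k2, noise_sd = noise_sd,
                            seed = seed)
  ds
}

#' Analytic toy landscapes for validating the free-energy machinery
#'
#' Presets:
#' * `"double-well"`: `V = barrier * (s^2 - 1)^2 + 0.5 * kz * z^2`; minima
#'   at (s, z) = (+/-1, 0) with V = 0, saddle at (0, 0) with V = `barrier`.
#' * `"three-state"`: three Gaussian wells along s (triple helix A, an
#'   intermediate B, and a final toggled state offset `offset` above A),
#'   in a confining quadratic background.
#'
#' @param preset `"double-well"` or `"three-state"`.
#' @param barrier Double-well barrier height, kcal/mol (default 3).
#' @param kz Transverse harmonic constant (default 2).
#' @param offset Three-state final-basin offset above the first basin,
#'   kcal/mol (default 5).
#' @return A `toy_landscape`: list with `f(s, z)`, `grad(s, z)`, `minima`
#'   (list of `list(at, value)`) and (double-well) `saddle`.
#' @export
gen_toy_landscape <- function(preset = c("double-well", "three-state"),
                              barrier = 3, kz = 2, offset = 5) {
  preset <- tryCatch(match.arg(preset), error = function(e) {
    stop("gen_toy_landscape: unknown preset '", preset[1],
         "'; available: double-well, three-state")
  })
  if (preset == "double-well") {
    f <- function(s, z) barrier * (s^2 - 1)^2 + 0.5 * kz * z^2
    grad <- function(s, z) c(4 * barrier * s * (s^2 - 1), kz * z)
    structure(list(
      preset = preset, f = f, grad = grad,
      minima = list(list(at = c(-1, 0), value = 0),
                    list(at = c(1, 0), value = 0)),
      saddle = list(at = c(0, 0), value = barrier)),
      class = "toy_landscape")
  } else {
    # gaussian wells at s = 0, 2, 4; depths chosen so basin energies are
    # 0, +2 and +offset relative to the first, in a weak confining bowl
    centers <- c(0, 2, 4)
    conf <- 0.05
    depths0 <- c(12, 10, 12 - offset)
    depths <- depths0 + conf * centers^2  # absorb the bowl at the centers
    wells <- function(s) {
      vapply(seq_along(centers),
             function(i) -depths[i] * exp(-(s - centers[i])^2 / (2 * 0.35^2)),
             numeric(length(s)))
    }
    f <- function(s, z) {
      w <- wells(s)
      base <- if (is.matrix(w)) rowSums(w) else sum(w)
      base + conf * s^2 + 0.5 * kz * z^2 + depths0[1]
    }
    grad <- function(s, z) {
      gsum <- sum(vapply(seq_along(centers), function(i) {
        depths[i] * (s - centers[i]) / 0.35^2 *
          exp(-(s - centers[i])^2 / (2 * 0.35^2))
      }, numeric(1)))
      c(gsum + 2 * conf * s, kz * z)
    }
    minima <- lapply(seq_along(centers), function(i) {
      list(at = c(centers[i], 0), value = f(centers[i], 0))
    })
    structure(list(preset = preset, f = f, grad = grad, minima = minima,
                   offset = offset),
              class = "toy_landscape")
  }
}
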