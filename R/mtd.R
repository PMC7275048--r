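KJ_PER_KCAL <- 4.184

#' Convert kJ/mol to kcal/mol
#' @param x Energy in kJ/mol.
#' @return Energy in kcal/mol.
#' @export
kj_to_kcal <- function(x) x / KJ_PER_KCAL

#' Convert kcal/mol to kJ/mol
#' @param x Energy in kcal/mol.
#' @return Energy in kJ/mol.
#' @export
kcal_to_kj <- function(x) x * KJ_PER_KCAL

#' Create an empty metadynamics hill log
#'
#' A hill log is the record of all repulsive Gaussians deposited during a
#' metadynamics run on the path collective variables (S, Z). Heights are
#' stored internally in kcal/mol; the interchange file dialect uses kJ/mol.
#'
#' @param stride Deposition stride, ps (default 1).
#' @param width_floor Lower bound on Gaussian widths, in each coordinate's
#'   own unit (default 0.03).
#' @return A `hill_log` object (zero hills).
#' @export
hill_log <- function(stride = 1, width_floor = 0.03) {
  stopifnot(stride > 0, width_floor > 0)
  structure(list(
    hills = data.frame(time = numeric(), s = numeric(), z = numeric(),
                       sigma_s = numeric(), sigma_z = numeric(),
                       height = numeric()),
    stride = stride, width_floor = width_floor),
    class = "hill_log")
}

#' @export
print.hill_log <- function(x, ...) {
  cat("hill_log: ", nrow(x$hills), " hills, stride ", x$stride,
      " ps, width floor ", x$width_floor, "\n", sep = "")
  invisible(x)
}

#' Adaptive Gaussian widths from recent CV fluctuations
#'
#' Per-coordinate sample standard deviation of the (S, Z) samples inside the
#' trailing time window, clipped from below at the width floor — the
#' adaptive-width rule with a 1 ps fluctuation window.
#'
#' @param cv_history Data frame / matrix with columns `time`, `s`, `z` (or
#'   s,z only, all samples used).
#' @param window Trailing window, ps (default 1).
#' @param floor Width floor (default 0.03).
#' @return Numeric `c(sigma_s, sigma_z)`.
#' @export
adaptive_width <- function(cv_history, window = 1, floor = 0.03) {
  h <- as.data.frame(cv_history)
  if ("time" %in% names(h)) {
    h <- h[h$time >= max(h$time) - window, , drop = FALSE]
  }
  if (nrow(h) < 2L) stop("adaptive_width: fewer than 2 samples in window")
  c(sigma_s = max(stats::sd(h$s), floor),
    sigma_z = max(stats::sd(h$z), floor))
}

#' Deposit one hill
#'
#' @param log A `hill_log`.
#' @param state Numeric `c(S, Z)` center.
#' @param widths Numeric `c(sigma_s, sigma_z)`; must be at or above the
#'   log's width floor.
#' @param height Hill height.
#' @param units Unit of `height`: "kJ/mol" (default, the deposition
#'   convention; converted on input) or "kcal/mol".
#' @param time Deposition time, ps; default stride * (current count + 1).
#' @return The log with the hill appended.
#' @export
deposit <- function(log, state, widths, height = 0.3,
                    units = c("kJ/mol", "kcal/mol"), time = NULL) {
  units <- match.arg(units)
  if (any(widths < log$width_floor - 1e-12)) {
    stop("deposit: width ", min(widths), " below floor ", log$width_floor)
  }
  h_kcal <- if (units == "kJ/mol") kj_to_kcal(height) else height
  if (h_kcal <= 0) stop("deposit: height must be positive")
  if (is.null(time)) time <- log$stride * (nrow(log$hills) + 1L)
  nt <- nrow(log$hills)
  if (nt > 0L && time < log$hills$time[nt]) {
    stop("deposit: hill times must be non-decreasing")
  }
  log$hills[nt + 1L, ] <- list(time, state[1], state[2],
                               widths[1], widths[2], h_kcal)
  log
}

#' Total bias at a point
#'
#' Sum of the deposited Gaussians,
#' `V(S,Z) = sum_k h_k exp(-(S-S_k)^2/(2 sigma_Sk^2) - (Z-Z_k)^2/(2 sigma_Zk^2))`,
#' over hills with `time <= up_to_time`.
#'
#' @param log A `hill_log`.
#' @param point Numeric `c(S, Z)`.
#' @param up_to_time Only hills up to this time, ps (default all).
#' @return Bias in kcal/mol.
#' @export
bias_at <- function(log, point, up_to_time = Inf) {
  h <- log$hills[log$hills$time <= up_to_time, , drop = FALSE]
  if (nrow(h) == 0L) return(0)
  sum(h$height * exp(-(point[1] - h$s)^2 / (2 * h$sigma_s^2)
                     - (point[2] - h$z)^2 / (2 * h$sigma_z^2)))
}

bias_grid_values <- function(log, s_axis, z_axis, up_to_time = Inf) {
  h <- log$hills[log$hills$time <= up_to_time, , drop = FALSE]
  v <- matrix(0, length(s_axis), length(z_axis))
  if (nrow(h) == 0L) return(v)
  for (k in seq_len(nrow(h))) {
    es <- exp(-(s_axis - h$s[k])^2 / (2 * h$sigma_s[k]^2))
    ez <- exp(-(z_axis - h$z[k])^2 / (2 * h$sigma_z[k]^2))
    v <- v + h$height[k] * outer(es, ez)
  }
  v
}

#' Reconstruct the free-energy surface from a hill log
#'
#' `F(S,Z) = -V_bias(S,Z)`, shifted so the grid minimum is exactly zero.
#' By default the grid spans the deposited hill centers padded by three
#' widths of the widest hill.
#'
#' @param log A non-empty `hill_log`.
#' @param s_axis,z_axis Optional explicit grid axes.
#' @param n_grid Grid points per axis when axes are derived (default 200).
#' @param up_to_time Use hills up to this time, ps (default all).
#' @return A `free_energy_surface`: list with `s_axis`, `z_axis`, `values`
#'   (matrix, kcal/mol, min 0).
#' @export
reconstruct_fes <- function(log, s_axis = NULL, z_axis = NULL, n_grid = 200L,
                            up_to_time = Inf) {
  h <- log$hills[log$hills$time <= up_to_time, , drop = FALSE]
  if (nrow(h) == 0L) stop("reconstruct_fes: hill log is empty")
  if (is.null(s_axis)) {
    pad <- 3 * max(h$sigma_s)
    s_axis <- seq(min(h$s) - pad, max(h$s) + pad, length.out = n_grid)
  }
  if (is.null(z_axis)) {
    pad <- 3 * max(h$sigma_z)
    z_axis <- seq(min(h$z) - pad, max(h$z) + pad, length.out = n_grid)
  }
  sub <- log; sub$hills <- h
  f <- -bias_grid_values(sub, s_axis, z_axis)
  f <- f - min(f)
  structure(list(s_axis = s_axis, z_axis = z_axis, values = f),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("free_energy_surface: ", length(x$s_axis), " x ", length(x$z_axis),
      " grid, range 0-", signif(max(x$values), 4), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Locate basins and the minimax barrier between them
#'
#' Each basin is the minimum of the surface inside its hinted grid region.
#' The barrier is defined through the minimax path: the smallest value m
#' such that the two basins are connected through grid cells (8-connectivity)
#' with `F <= m`; then `dG = m - F(basinA)` and the offset is
#' `F(basinB) - F(basinA)`. Computed by a union-find sweep over cells in
#' ascending energy order.
#'
#' @param fes A `free_energy_surface`.
#' @param basin_a,basin_b Hint regions: lists `list(s = c(lo, hi), z = c(lo, hi))`.
#' @return List with `basin_a`, `basin_b` (each `s`, `z`, `value`),
#'   `saddle` (minimax path value), `barrier` (kcal/mol) and `offset`
#'   (kcal/mol, basin B relative to basin A).
#' @export
basins_and_barrier <- function(fes, basin_a, basin_b) {
  find_basin <- function(hint, tag) {
    is_ <- which(fes$s_axis >= hint$s[1] & fes$s_axis <= hint$s[2])
    iz <- which(fes$z_axis >= hint$z[1] & fes$z_axis <= hint$z[2])
    if (length(is_) == 0L || length(iz) == 0L) {
      stop("basins_and_barrier: hint region ", tag, " is off-grid")
    }
    sub <- fes$values[is_, iz, drop = FALSE]
    # require an interior local minimum, not a region-boundary artifact
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- is_[k[1]]; j <- iz[k[2]]
    ni <- max(1L, i - 1L):min(nrow(fes$values), i + 1L)
    nj <- max(1L, j - 1L):min(ncol(fes$values), j + 1L)
    if (fes$values[i, j] > min(fes$values[ni, nj])) {
      stop("basins_and_barrier: no local minimum inside hint region ", tag)
    }
    list(i = i, j = j, s = fes$s_axis[i], z = fes$z_axis[j],
         value = fes$values[i, j])
  }
  a <- find_basin(basin_a, "A")
  b <- find_basin(basin_b, "B")
  saddle <- minimax_connect(fes$values, c(a$i, a$j), c(b$i, b$j))
  list(basin_a = a[c("s", "z", "value")], basin_b = b[c("s", "z", "value")],
       saddle = saddle, barrier = saddle - a$value,
       offset = b$value - a$value)
}

# Kruskal-style minimax: add cells in ascending energy, union with already
# present 8-neighbors, stop when source and target connect.  Returns the
# energy of the last-added cell, i.e. the minimax path value.
minimax_connect <- function(values, from, to) {
  nr <- nrow(values); nc <- ncol(values)
  idx <- function(i, j) (j - 1L) * nr + i
  src <- idx(from[1], from[2]); dst <- idx(to[1], to[2])
  if (src == dst) return(values[from[1], from[2]])
  parent <- seq_len(nr * nc)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  active <- logical(nr * nc)
  ord <- order(values)
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (cell in ord) {
    active[cell] <- TRUE
    i <- ((cell - 1L) %% nr) + 1L
    j <- ((cell - 1L) %/% nr) + 1L
    for (k in 1:8) {
      ii <- i + di[k]; jj <- j + dj[k]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
        nb <- idx(ii, jj)
        if (active[nb]) {
          ra <- find(cell); rb <- find(nb)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    if (active[src] && active[dst] && find(src) == find(dst)) {
      return(values[cell])
    }
  }
  stop("minimax_connect: basins never connected (non-finite surface?)")
}

#' Time-averaged free-energy surface over the tail of a hill log
#'
#' Convergence device for non-tempered metadynamics: the surface keeps
#' being raised uniformly once filled, so the estimate is the average of
#' reconstructions at several checkpoints over the final fraction of the
#' deposition time (each min-shifted before averaging, and the average
#' re-shifted to zero).
#'
#' @param log A `hill_log`.
#' @param s_axis,z_axis Grid axes (required so checkpoints share a grid).
#' @param tail_fraction Final fraction of deposition time to average over
#'   (default 0.2).
#' @param n_checkpoints Number of checkpoints in the tail (default 5).
#' @return A `free_energy_surface`.
#' @export
average_fes <- function(log, s_axis, z_axis, tail_fraction = 0.2,
                        n_checkpoints = 5L) {
  t_end <- max(log$hills$time)
  ts <- seq((1 - tail_fraction) * t_end, t_end, length.out = n_checkpoints)
  acc <- NULL
  for (tt in ts) {
    f <- reconstruct_fes(log, s_axis = s_axis, z_axis = z_axis,
                         up_to_time = tt)
    acc <- if (is.null(acc)) f$values else acc + f$values
  }
  acc <- acc / length(ts)
  structure(list(s_axis = s_axis, z_axis = z_axis, values = acc - min(acc)),
            class = "free_energy_surface")
}

#' Toy overdamped Langevin sampler with metadynamics deposition
#'
#' Integrates overdamped Langevin dynamics on an analytic 2D potential with
#' the live metadynamics bias, depositing an adaptive-width hill every
#' stride. This is the validation engine for the free-energy machinery:
#' landscapes with known barriers go in, the reconstruction is compared
#' against them. Units: energy kcal/mol, time ps, friction coefficient 1.
#'
#' @param potential A function `f(s, z) -> kcal/mol`, or a landscape object
#'   from [gen_toy_landscape()] (its analytic gradient is then used).
#' @param steps Number of integration steps.
#' @param dt Time step, ps (default 0.02).
#' @param temperature Temperature, K (default 300).
#' @param seed Integer RNG seed (runs with equal seeds are identical).
#' @param x0 Starting point `c(s, z)` (default the landscape's first minimum,
#'   else c(0, 0)).
#' @param stride Deposition stride, ps (default 1).
#' @param hill_height Hill height, kJ/mol (default 0.3).
#' @param width_floor Width floor (default 0.03).
#' @param bounds Absolute bound on |s|, |z| beyond which the sampler aborts
#'   (default 5; also the extent of the internal force-interpolation grid,
#'   so keep it a small multiple of the landscape's extent).
#' @param deposit_hills If `FALSE`, run plain (unbiased) Langevin dynamics
#'   with an empty hill log — used to validate the integrator itself.
#' @return List with `cv` (data frame time, s, z) and `log` (the hill log).
#' @export
langevin_sample <- function(potential, steps, dt = 0.02, temperature = 300,
                            seed = 1L, x0 = NULL, stride = 1,
                            hill_height = 0.3, width_floor = 0.03,
                            bounds = 5, deposit_hills = TRUE) {
  land <- NULL
  if (inherits(potential, "toy_landscape")) {
    land <- potential
    potential <- land$f
  }
  grad <- if (!is.null(land)) land$grad else function(s, z) {
    eps <- 1e-5
    c((potential(s + eps, z) - potential(s - eps, z)) / (2 * eps),
      (potential(s, z + eps) - potential(s, z - eps)) / (2 * eps))
  }
  if (is.null(x0)) {
    x0 <- if (!is.null(land)) land$minima[[1L]]$at else c(0, 0)
  }
  set.seed(as.integer(seed))
  kB <- 1.987204258640832e-3  # kcal/(mol K)
  kT <- kB * temperature
  noise_amp <- sqrt(2 * kT * dt)
  log <- hill_log(stride = stride, width_floor = width_floor)
  h_kcal <- kj_to_kcal(hill_height)

  # live bias force from an internal interpolation grid (exact hill log is
  # still kept; reconstruction always uses the exact Gaussian sum)
  gs <- seq(-bounds, bounds, length.out = 2001L)
  gz <- seq(-bounds, bounds, length.out = 801L)
  bias_gx <- matrix(0, length(gs), length(gz))
  bias_gz <- matrix(0, length(gs), length(gz))
  interp <- function(m, s, z) {
    i <- findInterval(s, gs, all.inside = TRUE)
    j <- findInterval(z, gz, all.inside = TRUE)
    fs <- (s - gs[i]) / (gs[i + 1L] - gs[i])
    fz <- (z - gz[j]) / (gz[j + 1L] - gz[j])
    (1 - fs) * ((1 - fz) * m[i, j] + fz * m[i, j + 1L]) +
      fs * ((1 - fz) * m[i + 1L, j] + fz * m[i + 1L, j + 1L])
  }

  n_per_stride <- max(1L, round(stride / dt))
  x <- as.numeric(x0)
  times <- numeric(steps); ss <- numeric(steps); zz <- numeric(steps)
  n_dep <- steps %/% n_per_stride + 1L
  ht <- hs <- hz <- hws <- hwz <- numeric(n_dep); n_h <- 0L
  for (st in seq_len(steps)) {
    g <- grad(x[1], x[2])  # gradient of potential; add the bias gradient
    g[1] <- g[1] + interp(bias_gx, x[1], x[2])
    g[2] <- g[2] + interp(bias_gz, x[1], x[2])
    x <- x - dt * g + noise_amp * rnorm(2)
    if (any(abs(x) > bounds)) {
      stop("langevin_sample: trajectory diverged beyond |cv| = ", bounds,
           "; use a smaller dt")
    }
    times[st] <- st * dt; ss[st] <- x[1]; zz[st] <- x[2]
    if (deposit_hills && st %% n_per_stride == 0L && st > 1L) {
      win <- max(1L, st - n_per_stride + 1L):st
      w <- adaptive_width(data.frame(s = ss[win], z = zz[win]),
                          floor = width_floor)
      n_h <- n_h + 1L
      ht[n_h] <- st * dt; hs[n_h] <- x[1]; hz[n_h] <- x[2]
      hws[n_h] <- w[1]; hwz[n_h] <- w[2]
      # accumulate this hill's force on the interpolation grids
      # (local 6-sigma windows; the Gaussian is negligible outside)
      ri <- which(abs(gs - x[1]) <= 6 * w[1])
      rj <- which(abs(gz - x[2]) <= 6 * w[2])
      if (length(ri) && length(rj)) {
        es <- exp(-(gs[ri] - x[1])^2 / (2 * w[1]^2))
        ez <- exp(-(gz[rj] - x[2])^2 / (2 * w[2]^2))
        core <- h_kcal * outer(es, ez)
        bias_gx[ri, rj] <- bias_gx[ri, rj] +
          core * (-(gs[ri] - x[1]) / w[1]^2)
        bias_gz[ri, rj] <- bias_gz[ri, rj] +
          core * matrix(-(gz[rj] - x[2]) / w[2]^2, length(ri), length(rj),
                        byrow = TRUE)
      }
    }
  }
  log$hills <- data.frame(time = ht[seq_len(n_h)], s = hs[seq_len(n_h)],
                          z = hz[seq_len(n_h)], sigma_s = hws[seq_len(n_h)],
                          sigma_z = hwz[seq_len(n_h)],
                          height = rep(h_kcal, n_h))
  list(cv = data.frame(time = times, s = ss, z = zz), log = log)
}

#' Read a hill log from its plain-text dialect
#'
#' Whitespace columns `time S Z sigma_S sigma_Z height`, height in kJ/mol;
#' lines starting with `#` are comments.
#'
#' @param path File to read.
#' @param stride Deposition stride, ps (default: inferred median spacing).
#' @param width_floor Width floor recorded on the log (default 0.03).
#' @return A `hill_log` (heights stored in kcal/mol).
#' @export
read_hills <- function(path, stride = NULL, width_floor = 0.03) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("time", "s", "z", "sigma_s",
                                         "sigma_z", "height"))
  if (any(diff(tab$time) < 0)) stop("read_hills: times must be non-decreasing")
  if (is.null(stride)) {
    stride <- if (nrow(tab) > 1L) stats::median(diff(tab$time)) else 1
  }
  log <- hill_log(stride = stride, width_floor = width_floor)
  tab$height <- kj_to_kcal(tab$height)
  log$hills <- tab
  log
}

#' Write a hill log in the plain-text dialect (heights converted to kJ/mol)
#' @param log A `hill_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time S Z sigma_S sigma_Z height_kJ_mol", con)
  h <- log$hills
  writeLines(sprintf("%.6f %.10g %.10g %.10g %.10g %.10g", h$time, h$s, h$z,
                     h$sigma_s, h$sigma_z, kcal_to_kj(h$height)), con)
  invisible(path)
}

#' Write a free-energy surface as a TSV grid dump
#' @param fes A `free_energy_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  df <- data.frame(s = rep(fes$s_axis, times = length(fes$z_axis)),
                   z = rep(fes$z_axis, each = length(fes$s_axis)),
                   free_energy = as.vector(fes$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
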