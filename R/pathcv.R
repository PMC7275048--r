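#' Linear Cartesian morph between two conformations
#'
#' Superposes the end conformation onto the start over the chosen atoms, then
#' interpolates linearly: set k (k = 0..n+1) is
#' `start + k/(n+1) * (end - start)`. Endpoints are preserved exactly.
#'
#' @param start,end `intron_structure` objects with 1:1 corresponding atoms
#'   over `atoms` (matched by chain/resno/name).
#' @param atoms Selection (string or `atom_index_set` on `start`) of the
#'   atoms to morph; default all heavy atoms.
#' @param n_intermediates Number of interior interpolation sets.
#' @return List of `n_intermediates + 2` coordinate matrices (n x 3).
#' @export
build_linear_morph <- function(start, end, atoms = "heavy",
                               n_intermediates = 30L) {
  ia <- if (inherits(atoms, "atom_index_set")) as.integer(atoms)
        else as.integer(select_atoms(start, atoms))
  key <- function(st, i) paste(st$atoms$chain[i], st$atoms$resno[i],
                               st$atoms$name[i], sep = "|")
  ka <- key(start, ia)
  ib <- match(ka, key(end, seq_len(n_atoms(end))))
  if (anyNA(ib)) {
    stop("build_linear_morph: atoms unmatched in end structure: ",
         paste(head(ka[is.na(ib)], 5L), collapse = ", "),
         if (sum(is.na(ib)) > 5L) " ...")
  }
  a <- coords(start)[ia, , drop = FALSE]
  b <- coords(end)[ib, , drop = FALSE]
  b <- superpose(b, a)$transformed
  n <- as.integer(n_intermediates)
  lapply(0:(n + 1L), function(k) {
    if (k == 0L) a else if (k == n + 1L) b
    else a + (k / (n + 1)) * (b - a)
  })
}

#' RMSD between a conformation and a path node after optimal superposition
#'
#' @param x,node n x 3 coordinate matrices in 1:1 correspondence.
#' @return RMSD in Angstrom.
#' @export
path_distance <- function(x, node) superpose(x, node)$rmsd

#' Resample an ordered set of conformations into equally spaced path nodes
#'
#' Reparametrizes the piecewise-linear chain through the input frames by arc
#' length (cumulative adjacent RMSD) and places `n_nodes` nodes at equal
#' arc-length intervals, interpolating within segments where needed. The
#' first and last nodes coincide with the input endpoints.
#'
#' @param frames List of n x 3 coordinate matrices, ordered along the path.
#' @param n_nodes Number of nodes to keep (default 16).
#' @return A `reference_path`: list with `nodes` (list of matrices),
#'   `mean_spacing` and `max_spacing_dev` (Angstrom), `lambda` (unset, NA).
#' @export
resample_path <- function(frames, n_nodes = 16L) {
  n_nodes <- as.integer(n_nodes)
  if (length(frames) < 2L || n_nodes < 2L) {
    stop("resample_path: need >= 2 frames and >= 2 nodes")
  }
  # align every frame onto its predecessor so segment interpolation is rigid
  aligned <- frames
  for (i in 2:length(frames)) {
    aligned[[i]] <- superpose(aligned[[i]], aligned[[i - 1L]])$transformed
  }
  seg <- vapply(2:length(aligned), function(i) {
    sqrt(mean(rowSums((aligned[[i]] - aligned[[i - 1L]])^2)))
  }, numeric(1))
  total <- sum(seg)
  if (total <= 0) stop("resample_path: path has zero length")
  s_cum <- c(0, cumsum(seg))
  targets <- seq(0, total, length.out = n_nodes)
  nodes <- lapply(targets, function(s) {
    j <- findInterval(s, s_cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(seg))
    f <- if (seg[j] > 0) (s - s_cum[j]) / seg[j] else 0
    aligned[[j]] + f * (aligned[[j + 1L]] - aligned[[j]])
  })
  nodes[[1L]] <- aligned[[1L]]
  nodes[[n_nodes]] <- aligned[[length(aligned)]]
  spac <- vapply(2:n_nodes, function(i) {
    path_distance(nodes[[i]], nodes[[i - 1L]])
  }, numeric(1))
  if (min(spac) <= .Machine$double.eps^0.5) {
    stop("resample_path: path too short for ", n_nodes, " distinct nodes")
  }
  structure(list(nodes = nodes, mean_spacing = mean(spac),
                 max_spacing_dev = max(abs(spac - mean(spac))),
                 spacings = spac, lambda = NA_real_),
            class = "reference_path")
}

#' @export
print.reference_path <- function(x, ...) {
  cat("reference_path: ", length(x$nodes), " nodes, mean spacing ",
      signif(x$mean_spacing, 4), " A, lambda ",
      if (is.na(x$lambda)) "unset" else signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Set the path smoothing parameter lambda from the node spacing
#'
#' Uses the standard overlap prescription `lambda = 2.3 / spacing^2` (in
#' inverse squared Angstrom), which makes adjacent-node Gaussian weights
#' overlap appropriately: `lambda * spacing^2 = 2.3` identically. A 16-node
#' path with mean spacing ~0.31 Angstrom gives lambda ~23.7.
#'
#' @param path A `reference_path`.
#' @return The path with `lambda` set.
#' @export
choose_lambda <- function(path) {
  if (!is.finite(path$mean_spacing) || path$mean_spacing <= 0) {
    stop("choose_lambda: mean spacing is zero")
  }
  path$lambda <- 2.3 / path$mean_spacing^2
  path
}

#' Evaluate the path collective variables S and Z
#'
#' For node distances `d_i = path_distance(coords, node_i)` and P nodes,
#' `S = sum_i i * exp(-lambda d_i^2) / sum_i exp(-lambda d_i^2)` (progress
#' along the path, on the node-index scale 1..P) and
#' `Z = -(1/lambda) * log sum_i exp(-lambda d_i^2)` (squared-Angstrom
#' distance from the path). Computed with a log-sum-exp shift so large
#' `lambda d^2` cannot underflow.
#'
#' @param x n x 3 coordinate matrix, atoms corresponding to the path nodes.
#' @param path A `reference_path` with `lambda` set (see [choose_lambda()]).
#' @return List with `S` (dimensionless), `Z` (Angstrom^2) and `d` (the
#'   per-node RMSD vector).
#' @export
compute_path_cvs <- function(x, path) {
  if (is.na(path$lambda)) {
    stop("compute_path_cvs: path lambda is unset; call choose_lambda() first")
  }
  lam <- path$lambda
  d <- vapply(path$nodes, function(nd) path_distance(x, nd), numeric(1))
  e <- -lam * d^2
  m <- max(e)
  w <- exp(e - m)
  sw <- sum(w)
  s_val <- sum(seq_along(d) * w) / sw
  z_val <- -(m + log(sw)) / lam
  list(S = s_val, Z = z_val, d = d)
}

#' Evaluate S and Z for every frame of a trajectory
#'
#' @param traj An `intron_trajectory`.
#' @param path A `reference_path` with lambda set.
#' @param atoms Selection on the trajectory topology giving the path atoms
#'   (count must match the node atom count); default all atoms.
#' @return Data frame with columns `time`, `S`, `Z`.
#' @export
trajectory_path_cvs <- function(traj, path, atoms = "all") {
  ia <- if (inherits(atoms, "atom_index_set")) as.integer(atoms)
        else as.integer(select_atoms(traj$topology, atoms))
  if (length(ia) != nrow(path$nodes[[1L]])) {
    stop("trajectory_path_cvs: selection has ", length(ia),
         " atoms but path nodes have ", nrow(path$nodes[[1L]]))
  }
  res <- t(vapply(seq_len(n_frames(traj)), function(f) {
    v <- compute_path_cvs(matrix(traj$coords[f, ia, ], ncol = 3L), path)
    c(v$S, v$Z)
  }, numeric(2)))
  data.frame(time = traj$times, S = res[, 1], Z = res[, 2])
}

#' Build a reference path between two endpoint structures
#'
#' Convenience wrapper chaining [build_linear_morph()] (default 30 interior
#' intermediates), [resample_path()] (default 16 nodes) and
#' [choose_lambda()]. The atom set defaults to the heavy atoms of the
#' toggling nucleotides 285-290.
#'
#' @param start,end `intron_structure` endpoint conformations.
#' @param atoms Selection string (default `"resnum 285-290 and heavy"`).
#' @param n_intermediates Interior morph sets (default 30).
#' @param n_nodes Path nodes (default 16).
#' @return A `reference_path` with lambda set.
#' @export
build_reference_path <- function(start, end,
                                 atoms = "resnum 285-290 and heavy",
                                 n_intermediates = 30L, n_nodes = 16L) {
  morph <- build_linear_morph(start, end, atoms, n_intermediates)
  choose_lambda(resample_path(morph, n_nodes))
}
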