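# Shared fixture builders (all in code; no stored data files).

# A tiny handcrafted PDB text with known atoms/coordinates.
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N7  G   A 288      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  O2  C   A 289       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  K   K   A 500      13.000  14.000  10.000  1.00  0.00           K",
    "END"), path)
  path
}

# Random rigid transform (proper rotation + translation).
random_rigid <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}

apply_rigid <- function(x, rig) x %*% t(rig$R) + matrix(rig$t, nrow(x), 3L,
                                                        byrow = TRUE)

# Random non-degenerate point cloud.
random_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3L * n, sd = 2), n, 3L)
}

# A simple two-endpoint pair of coordinate frames related by an isotropic
# expansion about the centroid, so the optimal rotation is the identity and
# the aligned RMSD between them is known in closed form.
scaled_pair <- function(n = 24L, total_rmsd = 4.677, seed = 7L) {
  a <- random_cloud(n, seed)
  a <- sweep(a, 2L, colMeans(a))
  r0 <- sqrt(mean(rowSums(a^2)))
  c_ <- 1 + total_rmsd / r0
  list(a = a, b = c_ * a)
}

# Wrap a bare coordinate matrix as a structure with generic atom identities.
as_structure <- function(xyz, resno = 1L) {
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)), resname = "LIG",
    resno = resno, chain = "A", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# Trajectory with given per-frame coordinates list and times.
traj_from_frames <- function(topology, frames, times) {
  arr <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3L))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  introntoggle:::new_trajectory(topology, arr, times)
}

# Independent minimax-path oracle: smallest threshold m such that a DFS
# flood over cells with value <= m connects source and target
# (8-connectivity).  Linear scan over the sorted unique values.
minimax_bruteforce <- function(values, from, to) {
  nr <- nrow(values); nc <- ncol(values)
  for (m in sort(unique(as.vector(values)))) {
    ok <- values <= m
    if (!ok[from[1], from[2]] || !ok[to[1], to[2]]) next
    seen <- matrix(FALSE, nr, nc)
    stack <- list(from)
    seen[from[1], from[2]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur[1] == to[1] && cur[2] == to[2]) return(m)
      for (di in -1:1) for (dj in -1:1) {
        i <- cur[1] + di; j <- cur[2] + dj
        if (i >= 1 && i <= nr && j >= 1 && j <= nc && ok[i, j] &&
            !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  stop("not connected")
}
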