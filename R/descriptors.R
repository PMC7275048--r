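#' Descriptor series constructor
#'
#' A named per-frame scalar series with units, the common currency of the
#' geometry layer (distances in Angstrom, angles in rad, counts unitless).
#'
#' @param name Descriptor name.
#' @param times Frame times, ns.
#' @param values Per-frame values.
#' @param units One of "A", "rad", "count".
#' @return A `descriptor_series` object.
#' @export
descriptor_series <- function(name, times, values, units = c("A", "rad", "count")) {
  units <- match.arg(units)
  if (length(times) != length(values)) {
    stop("descriptor_series: times and values differ in length")
  }
  if (!all(is.finite(values))) stop("descriptor_series: non-finite values")
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values), units = units),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("descriptor_series '", x$name, "': ", length(x$values), " frames [",
      x$units, "], mean ", signif(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

resolve_one <- function(structure, sel) {
  idx <- if (inherits(sel, "atom_index_set")) as.integer(sel)
         else if (is.character(sel)) as.integer(select_atoms(structure, sel))
         else as.integer(sel)
  if (length(idx) != 1L) {
    stop("selection must resolve to exactly one atom (got ", length(idx),
         if (is.character(sel)) paste0(" for '", sel, "'"), ")")
  }
  idx
}

#' Per-frame distance between two single atoms
#'
#' @param traj An `intron_trajectory` (wrap a structure with
#'   [as_trajectory()] for the single-structure case).
#' @param a,b Single-atom selections: an `atom_index_set`, a selector string,
#'   or a bare index.
#' @param name Optional series name.
#' @return A `descriptor_series` in Angstrom.
#' @export
pair_distance <- function(traj, a, b, name = "distance") {
  ia <- resolve_one(traj$topology, a)
  ib <- resolve_one(traj$topology, b)
  d <- sqrt(rowSums((traj$coords[, ia, , drop = FALSE] -
                     traj$coords[, ib, , drop = FALSE])^2, dims = 1L))
  descriptor_series(name, traj$times, as.numeric(d), "A")
}

#' Minimum heavy-atom distance between two residues' Watson-Crick faces
#'
#' Used for descriptors defined as "closest donor-acceptor pair" rather than
#' a fixed atom pair (e.g. the U2:A287 pairing, and mutant constructs whose
#' substituted bases lack the wild-type atoms).
#'
#' @param traj An `intron_trajectory`.
#' @param res_a,res_b Residue numbers.
#' @param name Optional series name.
#' @return A `descriptor_series` in Angstrom.
#' @export
min_face_distance <- function(traj, res_a, res_b, name = "min_face_distance") {
  face <- c("N1", "C2", "N2", "O2", "N3", "C4", "N4", "O4", "C6", "O6", "N6")
  at <- traj$topology$atoms
  ia <- which(at$resno == res_a & at$name %in% face & at$element != "H")
  ib <- which(at$resno == res_b & at$name %in% face & at$element != "H")
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("min_face_distance: no WC-face atoms for residue ",
         if (length(ia) == 0L) res_a else res_b)
  }
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    pa <- traj$coords[f, ia, , drop = TRUE]
    pb <- traj$coords[f, ib, , drop = TRUE]
    if (is.null(dim(pa))) pa <- matrix(pa, ncol = 3L)
    if (is.null(dim(pb))) pb <- matrix(pb, ncol = 3L)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  descriptor_series(name, traj$times, vals, "A")
}

purine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
pyrimidine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")

ring_atom_names <- function(resname) {
  rn <- toupper(trimws(resname))
  if (rn %in% c("A", "G", "DA", "DG", "ADE", "GUA")) purine_ring
  else if (rn %in% c("C", "U", "T", "DC", "DT", "CYT", "URA", "THY")) pyrimidine_ring
  else stop("base_plane_angle: residue type '", rn, "' is not a nucleotide")
}

ring_indices <- function(structure, resno) {
  at <- structure$atoms
  rows <- which(at$resno == resno & at$element != "H")
  if (length(rows) == 0L) stop("base_plane_angle: residue ", resno, " absent")
  want <- ring_atom_names(at$resname[rows[1]])
  idx <- rows[match(want, at$name[rows])]
  if (anyNA(idx)) {
    stop("base_plane_angle: residue ", resno, " is missing ring atom(s) ",
         paste(want[is.na(idx)], collapse = ", "))
  }
  idx
}

plane_normal <- function(xyz) {
  cov <- stats::cov(xyz)
  ev <- eigen(cov, symmetric = TRUE)
  ev$vectors[, 3L]  # smallest-variance principal direction
}

#' Angle between the least-squares planes of two nucleobases
#'
#' The plane of each base is fitted through its ring atoms (purines: the nine
#' atoms of the fused ring; pyrimidines: the six-membered ring) by principal
#' component analysis; the angle is `acos(|n_a . n_b|)`, folded into
#' `[0, pi/2]` so that the normals' sign convention cannot matter.
#'
#' @param traj An `intron_trajectory`.
#' @param res_a,res_b Residue numbers of the two bases.
#' @param name Optional series name.
#' @return A `descriptor_series` in rad.
#' @export
base_plane_angle <- function(traj, res_a, res_b, name = "alpha") {
  ia <- ring_indices(traj$topology, res_a)
  ib <- ring_indices(traj$topology, res_b)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    na_ <- plane_normal(traj$coords[f, ia, ])
    nb_ <- plane_normal(traj$coords[f, ib, ])
    acos(min(1, abs(sum(na_ * nb_))))
  }, numeric(1))
  descriptor_series(name, traj$times, vals, "rad")
}

#' Classify triple-helix vs disrupted frames
#'
#' A frame is in the triple-helix configuration iff the junction-triad
#' distance and the base-plane angle are both at or below their thresholds
#' (boundaries inclusive); otherwise it is disrupted.
#'
#' @param d `descriptor_series`, the d(289-358)-type distance (Angstrom).
#' @param alpha `descriptor_series`, the plane angle (rad).
#' @param d_max Distance threshold, Angstrom (default 3.0).
#' @param alpha_max Angle threshold, rad (default 0.35).
#' @return A `state_series`: list with `times`, `labels` (factor with levels
#'   `TRIPLE_HELIX`, `DISRUPTED`) and the thresholds used.
#' @export
classify_triple_helix <- function(d, alpha, d_max = 3.0, alpha_max = 0.35) {
  if (length(d$times) != length(alpha$times) ||
      any(abs(d$times - alpha$times) > 1e-9)) {
    stop("classify_triple_helix: series times do not align")
  }
  stopifnot(d_max > 0, alpha_max > 0)
  th <- d$values <= d_max & alpha$values <= alpha_max
  labels <- factor(ifelse(th, "TRIPLE_HELIX", "DISRUPTED"),
                   levels = c("TRIPLE_HELIX", "DISRUPTED"))
  structure(list(times = d$times, labels = labels,
                 d_max = d_max, alpha_max = alpha_max),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  tab <- table(x$labels)
  cat("state_series: ", length(x$labels), " frames; TRIPLE_HELIX ",
      tab[["TRIPLE_HELIX"]], ", DISRUPTED ", tab[["DISRUPTED"]],
      " (d_max ", x$d_max, " A, alpha_max ", x$alpha_max, " rad)\n", sep = "")
  invisible(x)
}

#' Detect ion-release events on a distance series
#'
#' An event is emitted at the first time the ion-contact distance exceeds
#' `released_cutoff` and stays above it for the full dwell window, provided
#' the ion was bound (distance below `bound_cutoff`) at some earlier time.
#' Re-binding after a release may start a further event.
#'
#' @param d `descriptor_series` of the ion-contact distance, Angstrom.
#' @param bound_cutoff Bound threshold, Angstrom (default 3.5).
#' @param released_cutoff Released threshold, Angstrom (default 6.0); must
#'   exceed `bound_cutoff`.
#' @param dwell Minimum time above `released_cutoff`, ns (default 1).
#' @param ion Label stored on the events.
#' @return Data frame with one row per event: `ion`, `release_time` (ns),
#'   `bound_cutoff`, `released_cutoff`, `dwell`.
#' @export
detect_ion_release <- function(d, bound_cutoff = 3.5, released_cutoff = 6.0,
                               dwell = 1, ion = "K1") {
  if (length(d$values) < 2L) stop("detect_ion_release: series too short")
  if (released_cutoff <= bound_cutoff) {
    stop("detect_ion_release: released_cutoff must exceed bound_cutoff")
  }
  span <- diff(range(d$times))
  if (dwell > span) {
    stop("detect_ion_release: dwell (", dwell, " ns) exceeds series span (",
         span, " ns)")
  }
  t <- d$times; v <- d$values
  n <- length(v)
  events <- list()
  bound_seen <- FALSE
  i <- 1L
  while (i <= n) {
    if (v[i] < bound_cutoff) bound_seen <- TRUE
    if (bound_seen && v[i] > released_cutoff) {
      # candidate release: require continuously released through the dwell
      j <- i
      while (j < n && v[j + 1L] > released_cutoff) j <- j + 1L
      if (t[j] - t[i] >= dwell || (j == n && t[n] - t[i] >= dwell)) {
        events[[length(events) + 1L]] <- data.frame(
          ion = ion, release_time = t[i], bound_cutoff = bound_cutoff,
          released_cutoff = released_cutoff, dwell = dwell,
          stringsAsFactors = FALSE)
        bound_seen <- FALSE  # a new event requires re-binding first
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(events) == 0L) {
    data.frame(ion = character(), release_time = numeric(),
               bound_cutoff = numeric(), released_cutoff = numeric(),
               dwell = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, events)
  }
}

#' Summarize a descriptor series after an equilibration discard
#'
#' Mean and sample standard deviation over frames with `time >= discard`,
#' the convention used for all trajectory statistics (default discard 25 ns,
#' the equilibration window).
#'
#' @param series A `descriptor_series`.
#' @param discard Initial time span to drop, ns (default 25).
#' @return List with `mean`, `sd`, `n_frames`, `discard`.
#' @export
summarize_series <- function(series, discard = 25) {
  keep <- series$times >= discard
  if (sum(keep) < 2L) {
    stop("summarize_series: fewer than 2 frames remain after discarding ",
         discard, " ns")
  }
  v <- series$values[keep]
  list(mean = mean(v), sd = stats::sd(v), n_frames = sum(keep),
       discard = discard)
}

#' Per-frame coordination number of an ion
#'
#' Counts non-hydrogen atoms (the ion itself excluded) within `cutoff` of the
#' ion in each frame.
#'
#' @param traj An `intron_trajectory`.
#' @param ion Single-atom selection for the ion.
#' @param cutoff Coordination cutoff, Angstrom (default 3.5).
#' @return A `descriptor_series` of counts.
#' @export
coordination_count <- function(traj, ion, cutoff = 3.5) {
  ii <- resolve_one(traj$topology, ion)
  heavy <- which(traj$topology$atoms$element != "H")
  heavy <- setdiff(heavy, ii)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    p <- traj$coords[f, ii, ]
    m <- matrix(traj$coords[f, heavy, ], ncol = 3L)
    sum(rowSums(sweep(m, 2L, p)^2) <= cutoff^2)
  }, numeric(1))
  descriptor_series(paste0("coordination_", cutoff, "A"), traj$times, vals,
                    "count")
}

#' Default descriptor catalog
#'
#' The named geometric descriptors of the active site, as selector pairs.
#' Ion roles (K1, M1, M2) are crystallographic-file-specific and must be
#' supplied by the caller as atom serial numbers; [suggest_ion_roles()] can
#' propose candidates. Residue numbering follows the Oceanobacillus
#' iheyensis group II intron convention (J2/3 junction A287-G288-C289,
#' catalytic triad C358-G359-C360, Watson-Crick partner G385).
#'
#' @param ion_serials Named list/vector of atom serial numbers for roles
#'   `K1`, `M1`, `M2` (any subset; descriptors needing a missing role are
#'   marked unavailable).
#' @param d_pair Atom pair for the junction-triad distance, as
#'   `list(a = selector, b = selector)`; the default is O2 of residue 289 to
#'   N4 of residue 358 (wild-type C358 — substituted constructs should point
#'   this at the closest WC-face donor-acceptor pair of the mutant base).
#' @param alpha_residues Residue pair for the base-plane angle
#'   (default c(358, 385)).
#' @return A `descriptor_catalog` list.
#' @export
descriptor_catalog <- function(ion_serials = list(),
                               d_pair = list(a = "resnum 289 and name O2",
                                             b = "resnum 358 and name N4"),
                               alpha_residues = c(358, 385)) {
  structure(list(
    ion_serials = as.list(ion_serials),
    d_pair = d_pair,
    alpha_residues = alpha_residues,
    g288_n7 = "resnum 288 and name N7",
    g288_o6 = "resnum 288 and name O6"
  ), class = "descriptor_catalog")
}

ion_sel <- function(structure, serial) {
  idx <- which(structure$atoms$serial == serial)
  if (length(idx) != 1L) {
    stop("ion serial ", serial, " matches ", length(idx), " atoms")
  }
  idx
}

#' Evaluate every available catalog descriptor on a trajectory
#'
#' @param traj An `intron_trajectory`.
#' @param catalog A [descriptor_catalog()].
#' @param sp_serial Optional scissile-phosphate P atom serial (for d_SP-M2).
#' @return Named list of `descriptor_series`; descriptors whose ion roles are
#'   not assigned are omitted (with a warning naming them).
#' @export
evaluate_catalog <- function(traj, catalog, sp_serial = NULL) {
  out <- list()
  out$d_289_358 <- pair_distance(traj, catalog$d_pair$a, catalog$d_pair$b,
                                 name = "d_289-358")
  out$alpha <- base_plane_angle(traj, catalog$alpha_residues[1],
                                catalog$alpha_residues[2])
  ions <- catalog$ion_serials
  skipped <- character()
  if (!is.null(ions$K1)) {
    out$d_K1_N7 <- pair_distance(traj, ion_sel(traj$topology, ions$K1),
                                 catalog$g288_n7, name = "d_K1-N7G288")
  } else skipped <- c(skipped, "d_K1-N7G288")
  if (!is.null(ions$M1) && !is.null(ions$M2)) {
    out$d_M1_M2 <- pair_distance(traj, ion_sel(traj$topology, ions$M1),
                                 ion_sel(traj$topology, ions$M2),
                                 name = "d_M1-M2")
  } else skipped <- c(skipped, "d_M1-M2")
  if (!is.null(ions$M2)) {
    out$d_M2_O6 <- pair_distance(traj, ion_sel(traj$topology, ions$M2),
                                 catalog$g288_o6, name = "d_M2-O6")
    if (!is.null(sp_serial)) {
      out$d_SP_M2 <- pair_distance(traj, ion_sel(traj$topology, sp_serial),
                                   ion_sel(traj$topology, ions$M2),
                                   name = "d_SP-M2")
    }
  } else skipped <- c(skipped, "d_M2-O6", "d_SP-M2")
  if (length(skipped)) {
    warning("evaluate_catalog: no ion role assigned for: ",
            paste(unique(skipped), collapse = ", "))
  }
  out
}

#' Suggest K1/M1/M2 role assignments for a structure
#'
#' Advisory helper: proposes the potassium closest to O5' of residue 359 as
#' K1 and the two magnesiums closest to the catalytic-triad phosphates as
#' M1/M2 (M1 the one nearer the scissile position). Deposited files do not
#' label catalytic roles, so suggestions must be reviewed by the user.
#'
#' @param structure An `intron_structure`.
#' @return Named list of candidate atom serials (entries may be absent when
#'   no candidate ion exists).
#' @export
suggest_ion_roles <- function(structure) {
  at <- structure$atoms
  out <- list()
  anchor <- which(at$resno == 359 & at$name == "O5'")
  ks <- which(at$element == "K")
  if (length(anchor) == 1L && length(ks) > 0L) {
    p <- as.numeric(at[anchor, c("x", "y", "z")])
    d <- sqrt(colSums((t(as.matrix(at[ks, c("x", "y", "z")])) - p)^2))
    out$K1 <- at$serial[ks[which.min(d)]]
  }
  triad_p <- which(at$resno %in% 358:360 & at$name == "P")
  mgs <- which(at$element == "MG")
  if (length(triad_p) > 0L && length(mgs) > 0L) {
    pm <- as.matrix(at[triad_p, c("x", "y", "z")])
    dm <- vapply(mgs, function(i) {
      min(sqrt(rowSums(sweep(pm, 2L, as.numeric(at[i, c("x", "y", "z")]))^2)))
    }, numeric(1))
    ord <- mgs[order(dm)]
    out$M1 <- at$serial[ord[1L]]
    if (length(ord) > 1L) out$M2 <- at$serial[ord[2L]]
  }
  out
}

#' Reference crystal-structure descriptor values
#'
#' Literature descriptor values for the deposited wild-type and mutant
#' structures, for validating the descriptor layer against files the user
#' has downloaded (the coordinates themselves are not shipped). Distances in
#' Angstrom, angles in rad.
#'
#' @return Data frame with columns `pdb_id`, `descriptor`, `value`, `units`.
#' @export
crystal_reference_values <- function() {
  data.frame(
    pdb_id = c("4FAQ", "4FAQ", "4FAQ", "4FAQ", "4FAQ", "4FAR", "6T3K", "6T3R"),
    descriptor = c("d_289-358", "alpha", "d_K1-N7G288", "d_M1-M2", "d_M2-O6",
                   "d_K1-N7G288", "alpha", "alpha"),
    value = c(2.7, 0.17, 4.3, 4.3, 5.71, 4.4, 0.15, 0.31),
    units = c("A", "rad", "A", "A", "A", "A", "rad", "rad"),
    stringsAsFactors = FALSE
  )
}
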