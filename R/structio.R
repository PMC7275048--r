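#' @importFrom stats sd rnorm runif setNames aggregate approx optim quantile var rexp
#' @importFrom utils head tail read.table write.table modifyList
NULL

#' Read a structure from a PDB file
#'
#' Parses one model of a PDB file into an `intron_structure`: an atom table
#' with identities and Angstrom coordinates. HETATM ion records (K, NA, MG,
#' CA) are retained as ordinary atoms so that descriptor selections can reach
#' them. Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken in favour of altloc "A").
#'
#' @param path Path to a PDB-format text file.
#' @param model Integer model number to extract (default: first model).
#' @return An object of class `intron_structure`: a list with `model_id` and
#'   `atoms`, a data frame with columns `serial`, `name`, `resname`, `resno`,
#'   `chain`, `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, model = NULL) {
  if (!file.exists(path)) {
    stop("read_structure: file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                                     hex = TRUE)),
    error = function(e) stop("read_structure: cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- nrow(pdb$xyz)
  if (is.null(model)) model <- 1L
  model <- as.integer(model)
  if (model < 1L || model > n_models) {
    stop("read_structure: model ", model, " not found (file has ",
         n_models, " model", if (n_models > 1) "s", ")")
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at <- resolve_altloc(at)
  elem <- at$elesy
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_el)) elem[missing_el] <- guess_element(at$elety[missing_el])
  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    resname = trimws(at$resid),
    resno   = as.integer(at$resno),
    chain   = ifelse(is.na(at$chain) | !nzchar(trimws(at$chain)), " ",
                     trimws(at$chain)),
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, model_id = model)
}

resolve_altloc <- function(at) {
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (!any(nzchar(alt))) return(at)
  occ <- suppressWarnings(as.numeric(at$o)); occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[nzchar(alt)])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    # highest occupancy wins; on ties prefer altloc 'A' (then alphabetical)
    ord <- order(-occ[idx], alt[idx] != "A", alt[idx])
    keep[idx[-ord[1L]]] <- FALSE
  }
  at[keep, , drop = FALSE]
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1L, 2L)
  el <- substr(sub("^[0-9']*", "", nm), 1L, 1L)
  el[two %in% c("MG", "NA", "CA", "CL", "MN", "ZN", "BR")] <-
    two[two %in% c("MG", "NA", "CA", "CL", "MN", "ZN", "BR")]
  el[nm == "K"] <- "K"
  el
}

new_structure <- function(atoms, model_id = 1L) {
  stopifnot(nrow(atoms) > 0L)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("structure: non-finite coordinates")
  }
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "intron_structure")
}

#' @export
print.intron_structure <- function(x, ...) {
  cat("intron_structure: ", nrow(x$atoms), " atoms, model ", x$model_id,
      ", residues ", min(x$atoms$resno), "-", max(x$atoms$resno), "\n",
      sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `intron_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a structure as an n x 3 matrix
#' @param structure An `intron_structure`.
#' @return Numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(structure) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Write a structure (or list of coordinate sets) to a PDB file
#'
#' A single structure is written as a plain PDB; a list of structures sharing
#' one topology is written as a multi-model PDB (MODEL/ENDMDL records), the
#' serialization used for reference-path nodes and synthetic trajectories.
#'
#' @param x An `intron_structure`, or a list of them with identical atom
#'   tables (coordinates may differ).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  models <- if (inherits(x, "intron_structure")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    st <- models[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_atoms(st$atoms), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

format_pdb_atoms <- function(atoms) {
  ion_res <- c("K", "NA", "MG", "CA", "CL", "MN", "ZN")
  rec <- ifelse(atoms$resname %in% ion_res | atoms$resname == "HOH",
                "HETATM", "ATOM  ")
  nm <- atoms$name
  # PDB atom-name column convention: 1-letter elements start in column 14
  nm_fmt <- ifelse(nchar(nm) <= 3L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  sprintf("%s%5d %s %-3s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000L, nm_fmt, atoms$resname,
          substr(atoms$chain, 1, 1), atoms$resno,
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Read a trajectory
#'
#' Accepts either a multi-model PDB or the package's plain frame format
#' (one frame = a `t=<ns>` line followed by one `name x y z` line per atom).
#' Frames are returned in file order; when the plain format omits times they
#' default to `frame index * dt`.
#'
#' @param path File to read.
#' @param topology An `intron_structure` providing atom identities.
#' @param dt Frame interval in ns used when no times are present (default 1).
#' @return An `intron_trajectory`: list with `topology`, `coords`
#'   (n_frames x n_atoms x 3 array, Angstrom) and `times` (ns).
#' @export
read_trajectory <- function(path, topology, dt = 1) {
  if (!file.exists(path)) stop("read_trajectory: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^t\\s*=", first)) {
    read_plain_frames(path, topology, dt)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE, hex = TRUE))
    n_fr <- nrow(pdb$xyz)
    na <- n_atoms(topology)
    if (ncol(pdb$xyz) != 3L * na) {
      stop("read_trajectory: atom count ", ncol(pdb$xyz) / 3,
           " does not match topology (", na, " atoms)")
    }
    arr <- array(NA_real_, c(n_fr, na, 3L))
    for (i in seq_len(n_fr)) {
      arr[i, , ] <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    }
    new_trajectory(topology, arr, times = (seq_len(n_fr) - 1) * dt)
  }
}

read_plain_frames <- function(path, topology, dt) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  na <- n_atoms(topology)
  hdr <- grep("^t\\s*=", lines)
  n_fr <- length(hdr)
  if (n_fr == 0L) stop("read_trajectory: no 't=' frame headers found")
  bounds <- c(hdr, length(lines) + 1L)
  arr <- array(NA_real_, c(n_fr, na, 3L))
  times <- numeric(n_fr)
  for (i in seq_len(n_fr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != na) {
      stop("read_trajectory: frame ", i, " has ", length(block),
           " atoms, topology has ", na)
    }
    tval <- suppressWarnings(as.numeric(sub("^t\\s*=\\s*", "", lines[hdr[i]])))
    times[i] <- if (is.na(tval)) (i - 1) * dt else tval
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    arr[i, , ] <- matrix(as.numeric(parts[, 2:4]), ncol = 3L)
  }
  new_trajectory(topology, arr, times)
}

#' Write a trajectory in the plain frame format
#' @param traj An `intron_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- traj$topology$atoms$name
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("t=%.6f", traj$times[i]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", nm,
                       traj$coords[i, , 1], traj$coords[i, , 2],
                       traj$coords[i, , 3]), con)
  }
  invisible(path)
}

new_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "intron_structure"),
            length(dim(coords)) == 3L,
            dim(coords)[2] == n_atoms(topology),
            dim(coords)[1] == length(times))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("trajectory: times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "intron_trajectory")
}

#' Number of frames in a trajectory
#' @param traj An `intron_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Wrap a single structure as a 1-frame trajectory
#' @param structure An `intron_structure`.
#' @return An `intron_trajectory` with one frame at t = 0 ns.
#' @export
as_trajectory <- function(structure) {
  arr <- array(coords(structure), c(1L, n_atoms(structure), 3L))
  arr[1, , ] <- coords(structure)
  new_trajectory(structure, arr, times = 0)
}

#' @export
print.intron_trajectory <- function(x, ...) {
  cat("intron_trajectory: ", n_frames(x), " frames x ", n_atoms(x$topology),
      " atoms, t = ", min(x$times), "-", max(x$times), " ns\n", sep = "")
  invisible(x)
}

#' Select atoms by a small expression grammar
#'
#' Selections are conjunctions (`and`) of clauses; each clause may be negated
#' with a leading `not`. Clauses: `resnum <n>` or `resnum <a>-<b>`,
#' `resname <code>`, `name <atom-name>`, `elem <symbol>`, `chain <id>`,
#' `heavy` (non-hydrogen), `ion` (K/NA/MG/CA), `all`. Examples:
#' `"resnum 288 and name N7"`, `"resnum 285-290 and heavy"`, `"elem K"`.
#'
#' @param structure An `intron_structure`.
#' @param selector Selection string.
#' @return An `atom_index_set`: integer indices into the structure's atom
#'   order (possibly empty), with the selector attached as attribute
#'   `selector`.
#' @export
select_atoms <- function(structure, selector) {
  at <- structure$atoms
  clauses <- strsplit(trimws(selector), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0L || !nzchar(trimws(selector))) {
    stop("select_atoms: empty selector")
  }
  mask <- rep(TRUE, nrow(at))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    neg <- FALSE
    if (identical(tolower(toks[1]), "not")) {
      neg <- TRUE
      toks <- toks[-1]
      if (length(toks) == 0L) stop("select_atoms: dangling 'not' in '", cl, "'")
    }
    m <- clause_mask(at, toks, cl)
    if (neg) m <- !m
    mask <- mask & m
  }
  structure(which(mask), class = "atom_index_set", selector = selector)
}

clause_mask <- function(at, toks, cl) {
  key <- tolower(toks[1])
  val <- if (length(toks) > 1L) toks[2] else NA_character_
  if (key %in% c("resnum", "resname", "name", "elem", "element", "chain") &&
      is.na(val)) {
    stop("select_atoms: clause '", cl, "' is missing a value")
  }
  switch(key,
    "resnum" = {
      if (grepl("^[0-9]+-[0-9]+$", val)) {
        rng <- as.integer(strsplit(val, "-")[[1]])
        at$resno >= rng[1] & at$resno <= rng[2]
      } else if (grepl("^[0-9]+$", val)) {
        at$resno == as.integer(val)
      } else stop("select_atoms: bad resnum '", val, "'")
    },
    "resname" = at$resname == toupper(val),
    "name" = at$name == toupper(val),
    "elem" = ,
    "element" = at$element == toupper(val),
    "chain" = at$chain == val,
    "heavy" = at$element != "H",
    "hydrogen" = at$element == "H",
    "ion" = at$element %in% c("K", "NA", "MG", "CA"),
    "all" = rep(TRUE, nrow(at)),
    stop("select_atoms: cannot parse clause '", cl, "'")
  )
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, optionally weighted per atom.
#'
#' @param mobile n x 3 matrix to be moved.
#' @param reference n x 3 matrix held fixed.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd` (Angstrom, after applying the transform) and `transformed`
#'   (moved copy of `mobile`). Apply as `mobile %*% t(R) + translation`.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("superpose: coordinate sets must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superpose: need at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("superpose: invalid weights")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  a <- sweep(mobile, 2L, cm); b <- sweep(reference, 2L, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    warning("superpose: near-degenerate (collinear) configuration; ",
            "transform is best-effort")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  moved <- mobile %*% t(rot) + matrix(trans, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, transformed = moved)
}
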