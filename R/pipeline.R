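#' Build an analysis configuration
#'
#' Central declarative configuration for end-to-end runs. Defaults that come
#' from the study protocol (classification thresholds 3 A / 0.35 rad,
#' 25 ns equilibration discard, 0.3 kJ/mol hills at 1 ps stride with a 0.03
#' width floor, 16 path nodes, 310.15 K assay temperature) are tagged
#' `"protocol"` in reports; remaining defaults are tagged `"package"`.
#'
#' @param structures Named character vector/list of structure PDB paths.
#' @param trajectory Optional trajectory file path.
#' @param topology Optional topology PDB path for the trajectory.
#' @param kinetics Optional kinetic dataset path (see
#'   [read_kinetic_dataset()]).
#' @param ion_serials Named list of K1/M1/M2 atom serials.
#' @param d_max,alpha_max Triple-helix thresholds (A, rad).
#' @param discard Equilibration discard, ns.
#' @param bound_cutoff,released_cutoff,dwell Ion-release parameters (A, A, ns).
#' @param path_residues Residue range for reference paths.
#' @param n_nodes Path node count.
#' @param lambda Optional lambda override (A^-2).
#' @param temperature Eyring temperature, K.
#' @param bootstrap Bootstrap resamples for rate fits (0 = covariance).
#' @param seed RNG seed recorded in all outputs.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(structures = NULL, trajectory = NULL,
                            topology = NULL, kinetics = NULL,
                            ion_serials = list(), d_max = 3.0,
                            alpha_max = 0.35, discard = 25,
                            bound_cutoff = 3.5, released_cutoff = 6.0,
                            dwell = 1, path_residues = c(285, 290),
                            n_nodes = 16L, lambda = NULL,
                            temperature = NULL, bootstrap = 0L, seed = 1L) {
  stopifnot(d_max > 0, alpha_max > 0, discard >= 0)
  temp_warn <- is.null(temperature)
  if (temp_warn) temperature <- 310
  structure(list(structures = structures, trajectory = trajectory,
                 topology = topology, kinetics = kinetics,
                 ion_serials = ion_serials, d_max = d_max,
                 alpha_max = alpha_max, discard = discard,
                 bound_cutoff = bound_cutoff,
                 released_cutoff = released_cutoff, dwell = dwell,
                 path_residues = path_residues, n_nodes = n_nodes,
                 lambda = lambda, temperature = temperature,
                 temperature_defaulted = temp_warn,
                 bootstrap = bootstrap, seed = as.integer(seed),
                 provenance = c(d_max = "protocol", alpha_max = "protocol",
                                discard = "protocol", n_nodes = "protocol",
                                temperature = "protocol",
                                bound_cutoff = "package",
                                released_cutoff = "package",
                                dwell = "package")),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#' @param path YAML file whose keys match [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_analysis_config: unknown key(s): ",
                        paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

new_report <- function(stage, config, body, warnings = character()) {
  structure(list(stage = stage, config = config, body = body,
                 warnings = warnings,
                 package_version = as.character(utils::packageVersion("introntoggle")),
                 seed = config$seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report [", x$stage, "] (seed ", x$seed, ", introntoggle ",
      x$package_version, ")\n", sep = "")
  print(x$body)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Per-structure descriptor report
#'
#' Evaluates every available catalog descriptor on each configured structure
#' and classifies each as triple-helix or disrupted. Descriptors that fail
#' on a given structure (e.g. a missing residue) are reported as named
#' errors in their own rows; the remaining rows are kept. Ion descriptors
#' with no configured role raise a configuration error.
#'
#' @param config An `analysis_config` with `structures` set.
#' @param require_ions If `TRUE` (default) an unassigned K1 role is a
#'   configuration error rather than a skipped descriptor.
#' @return A `run_report` whose body is a data frame `structure`,
#'   `descriptor`, `value`, `units`, `status`, `state`.
#' @export
run_structure_report <- function(config, require_ions = TRUE) {
  if (is.null(config$structures) || length(config$structures) == 0L) {
    stop("run_structure_report: no structures configured")
  }
  if (require_ions && is.null(config$ion_serials$K1)) {
    stop("run_structure_report: ion role K1 is not assigned in the config ",
         "(set ion_serials or pass require_ions = FALSE)")
  }
  cat_ <- descriptor_catalog(ion_serials = config$ion_serials)
  rows <- list(); warns <- character()
  for (nm in names(config$structures)) {
    st <- if (inherits(config$structures[[nm]], "intron_structure")) {
      config$structures[[nm]]
    } else read_structure(config$structures[[nm]])
    traj <- as_trajectory(st)
    vals <- withCallingHandlers(
      tryCatch(evaluate_catalog(traj, cat_), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    per <- list()
    # evaluate each descriptor independently so one failure cannot mask others
    try_desc <- function(label, fn) {
      r <- tryCatch(fn(), error = function(e) e)
      if (inherits(r, "error")) {
        data.frame(structure = nm, descriptor = label, value = NA_real_,
                   units = NA_character_,
                   status = paste("error:", conditionMessage(r)),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(structure = nm, descriptor = label, value = r$values[1],
                   units = r$units, status = "ok", stringsAsFactors = FALSE)
      }
    }
    per$d <- try_desc("d_289-358", function()
      pair_distance(traj, cat_$d_pair$a, cat_$d_pair$b, "d_289-358"))
    per$alpha <- try_desc("alpha", function()
      base_plane_angle(traj, cat_$alpha_residues[1], cat_$alpha_residues[2]))
    if (!is.null(config$ion_serials$K1)) {
      per$k1 <- try_desc("d_K1-N7G288", function()
        pair_distance(traj, ion_sel(st, config$ion_serials$K1), cat_$g288_n7,
                      "d_K1-N7G288"))
    }
    if (!is.null(config$ion_serials$M1) && !is.null(config$ion_serials$M2)) {
      per$m1m2 <- try_desc("d_M1-M2", function()
        pair_distance(traj, ion_sel(st, config$ion_serials$M1),
                      ion_sel(st, config$ion_serials$M2), "d_M1-M2"))
    }
    if (!is.null(config$ion_serials$M2)) {
      per$m2o6 <- try_desc("d_M2-O6", function()
        pair_distance(traj, ion_sel(st, config$ion_serials$M2), cat_$g288_o6,
                      "d_M2-O6"))
    }
    tab <- do.call(rbind, per)
    dv <- tab$value[tab$descriptor == "d_289-358"]
    av <- tab$value[tab$descriptor == "alpha"]
    tab$state <- if (length(dv) == 1L && length(av) == 1L &&
                     !is.na(dv) && !is.na(av)) {
      ifelse(dv <= config$d_max & av <= config$alpha_max,
             "TRIPLE_HELIX", "DISRUPTED")
    } else NA_character_
    rows[[nm]] <- tab
  }
  new_report("structure", config, do.call(rbind, c(rows, make.row.names = FALSE)),
             warnings = unique(warns))
}

#' Trajectory descriptor/state/release report
#'
#' Computes the core descriptor series on the configured trajectory,
#' summarizes them after the equilibration discard, classifies frames and
#' detects ion-release events. Series may also be supplied directly (as
#' produced by [gen_toggling_series()]) instead of a trajectory file.
#'
#' @param config An `analysis_config` with either `trajectory` + `topology`
#'   set, or `series` passed here.
#' @param series Optional list with `d`, `alpha`, `d_k1` descriptor series.
#' @return A `run_report` whose body has `summaries` (data frame),
#'   `states` (`state_series`), `release` (events data frame) and `series`.
#' @export
run_trajectory_report <- function(config, series = NULL) {
  if (is.null(series)) {
    if (is.null(config$trajectory) || is.null(config$topology)) {
      stop("run_trajectory_report: no trajectory configured")
    }
    topo <- if (inherits(config$topology, "intron_structure")) config$topology
            else read_structure(config$topology)
    traj <- read_trajectory(config$trajectory, topo)
    cat_ <- descriptor_catalog(ion_serials = config$ion_serials)
    series <- evaluate_catalog(traj, cat_)
    names(series)[names(series) == "d_289_358"] <- "d"
    names(series)[names(series) == "d_K1_N7"] <- "d_k1"
  }
  if (is.null(series$d) || is.null(series$alpha)) {
    stop("run_trajectory_report: need at least d and alpha series")
  }
  summ <- lapply(series[!vapply(series, is.null, logical(1))], function(s) {
    if (!inherits(s, "descriptor_series")) return(NULL)
    r <- tryCatch(summarize_series(s, discard = config$discard),
                  error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(series = s$name, mean = NA_real_, sd = NA_real_,
                 n_frames = 0L, status = paste("error:", conditionMessage(r)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(series = s$name, mean = r$mean, sd = r$sd,
                 n_frames = r$n_frames, status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  summ <- do.call(rbind, c(summ[!vapply(summ, is.null, logical(1))],
                           make.row.names = FALSE))
  states <- classify_triple_helix(series$d, series$alpha,
                                  d_max = config$d_max,
                                  alpha_max = config$alpha_max)
  release <- if (!is.null(series$d_k1)) {
    detect_ion_release(series$d_k1, bound_cutoff = config$bound_cutoff,
                       released_cutoff = config$released_cutoff,
                       dwell = config$dwell)
  } else NULL
  new_report("trajectory", config,
             list(summaries = summ, states = states, release = release,
                  series = series))
}

#' Kinetics report: rate fit, Eyring barriers and optional fold changes
#'
#' @param config An `analysis_config`; `kinetics` may be a file path or a
#'   `kinetic_dataset`.
#' @param reference_fit Optional `rate_fit` of a reference construct; when
#'   given, fold changes `k_ref / k` are reported for both steps.
#' @return A `run_report` whose body has `fit` (`rate_fit`), `barriers`
#'   (data frame step/k/delta_g), and optionally `fold_changes`.
#' @export
run_kinetics_report <- function(config, reference_fit = NULL) {
  if (is.null(config$kinetics)) {
    stop("run_kinetics_report: no kinetic dataset configured")
  }
  ds <- if (inherits(config$kinetics, "kinetic_dataset")) config$kinetics
        else read_kinetic_dataset(config$kinetics)
  warns <- character()
  if (isTRUE(config$temperature_defaulted)) {
    warns <- c(warns, "temperature not configured; using 310 K (37 C assay)")
  }
  fit <- fit_rates(ds, bootstrap = config$bootstrap, seed = config$seed)
  barriers <- data.frame(
    step = c("step1", "step2"), k = c(fit$k1, fit$k2),
    delta_g = c(eyring_barrier(fit$k1, config$temperature)$delta_g,
                eyring_barrier(fit$k2, config$temperature)$delta_g),
    temperature = config$temperature)
  body <- list(fit = fit, barriers = barriers)
  if (!is.null(reference_fit)) {
    body$fold_changes <- data.frame(
      step = c("step1", "step2"),
      fold = c(fold_change(reference_fit$k1, fit$k1),
               fold_change(reference_fit$k2, fit$k2)))
  }
  new_report("kinetics", config, body, warnings = warns)
}
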