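# Readers and writers: extended-XYZ trajectories (with a Lattice comment
# line), xyz-dialect Wannier-center files (centers carry a dummy element
# symbol), and the CSV tables used for polarizations, dipole trajectories and
# spectra. Coordinates are Cartesian Å throughout; cells are written row-major
# (lattice vectors as rows) and converted to the column convention of the
# quantum matrix internally. Truncated files are rejected, never silently
# shortened.

#' Read a multi-frame extended-XYZ file
#'
#' @param path file path.
#' @return list of [frame()]s.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i]) && i == length(lines)) break
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0) {
      stop(sprintf("parse error at line %d: expected an atom count, got '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (i + 1 + na > length(lines)) {
      stop(sprintf("truncated file: frame starting at line %d declares %d atoms", i, na),
           call. = FALSE)
    }
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 0) {
      stop(sprintf("frame at line %d has no Lattice=\"...\" entry in its comment line", i),
           call. = FALSE)
    }
    nums <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", lat)), "\\s+")[[1]])
    if (length(nums) != 9 || any(is.na(nums))) {
      stop(sprintf("malformed lattice at line %d", i + 1), call. = FALSE)
    }
    cl <- cell(matrix(nums, 3, 3, byrow = TRUE))
    atoms <- lines[(i + 2):(i + 1 + na)]
    parts <- strsplit(trimws(atoms), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0) {
      stop(sprintf("parse error at line %d: need 'symbol x y z'", i + 1 + bad[1]),
           call. = FALSE)
    }
    species <- vapply(parts, `[[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(pos))) stop(sprintf("non-numeric coordinates in frame at line %d", i),
                              call. = FALSE)
    frames[[length(frames) + 1]] <- frame(species, pos, cl)
    i <- i + 2 + na
    while (i <= length(lines) && grepl("^\\s*$", lines[i])) i <- i + 1
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)
  frames
}

#' Write frames to an extended-XYZ file
#'
#' @param frames a [frame()] or list of frames.
#' @param path output path.
#' @export
write_extxyz <- function(frames, path) {
  if (inherits(frames, "frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    L <- unclass(fr$cell)
    writeLines(as.character(n_atoms(fr)), con)
    writeLines(sprintf('Lattice="%s" Properties=species:S:1:pos:R:3',
                       paste(sprintf("%.10g", t(L)), collapse = " ")), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       fr$species, fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read Wannier centers from an xyz-dialect file
#'
#' Centers are the rows whose element symbol equals `dummy_symbol`
#' (CP2K-style output writes them as `X`); any other rows are ignored with a
#' note on standard error. Multi-frame files return a list of sets.
#'
#' @param path file path.
#' @param dummy_symbol symbol marking center rows.
#' @return a [wannier_set()] (single frame) or list of them.
#' @export
read_wannier_xyz <- function(path, dummy_symbol = "X") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  sets <- list(); n_ignored <- 0
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i]) && i == length(lines)) break
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0) {
      stop(sprintf("parse error at line %d: expected an atom count", i), call. = FALSE)
    }
    if (i + 1 + na > length(lines)) {
      stop(sprintf("truncated file: frame at line %d declares %d rows", i, na), call. = FALSE)
    }
    parts <- strsplit(trimws(lines[(i + 2):(i + 1 + na)]), "\\s+")
    sym <- vapply(parts, `[[`, character(1), 1)
    keep <- sym == dummy_symbol
    n_ignored <- n_ignored + sum(!keep)
    if (any(keep)) {
      pos <- t(vapply(parts[keep], function(p) as.numeric(p[2:4]), numeric(3)))
      sets[[length(sets) + 1]] <- wannier_set(pos)
    } else {
      stop(sprintf("no centers with dummy symbol '%s' in frame at line %d", dummy_symbol, i),
           call. = FALSE)
    }
    i <- i + 2 + na
    while (i <= length(lines) && grepl("^\\s*$", lines[i])) i <- i + 1
  }
  if (length(sets) == 0) {
    stop(sprintf("no centers with dummy symbol '%s' found", dummy_symbol), call. = FALSE)
  }
  if (n_ignored > 0) message(n_ignored, " non-center rows ignored")
  if (length(sets) == 1) sets[[1]] else sets
}

#' Write Wannier centers (xyz dialect)
#' @param centers a [wannier_set()] or list of them.
#' @param path output path.
#' @param dummy_symbol symbol to write.
#' @export
write_wannier_xyz <- function(centers, path, dummy_symbol = "X") {
  if (inherits(centers, "wannier_set")) centers <- list(centers)
  con <- file(path, "w")
  on.exit(close(con))
  for (ws in centers) {
    writeLines(as.character(nrow(ws$positions)), con)
    writeLines("Wannier centers", con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", dummy_symbol,
                       ws$positions[, 1], ws$positions[, 2], ws$positions[, 3]), con)
  }
  invisible(path)
}

#' Read/write polarization tables
#'
#' CSV with columns `frame_id, Px, Py, Pz`; the unit (`e.A` or `Debye`) is
#' declared in a `# units:` header line and values are converted to e·Å on
#' read.
#'
#' @param x tibble with columns `frame_id, Px, Py, Pz` (e·Å).
#' @param path file path.
#' @param units `"e.A"` or `"Debye"` (written values converted accordingly).
#' @export
write_polarization_csv <- function(x, path, units = c("e.A", "Debye")) {
  units <- match.arg(units)
  out <- x[, c("frame_id", "Px", "Py", "Pz")]
  if (units == "Debye") out[, 2:4] <- out[, 2:4] * EA_TO_DEBYE
  con <- file(path, "w")
  writeLines(paste0("# units: ", units), con)
  close(con)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_polarization_csv
#' @export
read_polarization_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  units <- "e.A"
  if (grepl("^#\\s*units:", first)) {
    units <- trimws(sub("^#\\s*units:", "", first))
  }
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("frame_id", "Px", "Py", "Pz")
  if (!all(need %in% names(x))) {
    stop("polarization table must have columns frame_id, Px, Py, Pz", call. = FALSE)
  }
  x <- x[, need]
  if (tolower(units) %in% c("debye", "d")) {
    x[, 2:4] <- x[, 2:4] / EA_TO_DEBYE
  } else if (!tolower(units) %in% c("e.a", "ea", "e*a", "e.angstrom")) {
    stop("unknown units declaration: ", units, call. = FALSE)
  }
  x
}

#' Write a spectrum as CSV
#' @param spectrum an `ir_spectrum`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

#' Read a dipole trajectory CSV
#'
#' Expects columns `time, Px, Py, Pz` (optionally `P1x..P2z` for shell
#' components).
#' @param path file path.
#' @export
read_dipole_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("time", "Px", "Py", "Pz")
  if (!all(need %in% names(x))) {
    stop("dipole trajectory must have columns time, Px, Py, Pz", call. = FALSE)
  }
  P1 <- P2 <- NULL
  if (all(c("P1x", "P1y", "P1z") %in% names(x))) P1 <- as.matrix(x[, c("P1x", "P1y", "P1z")])
  if (all(c("P2x", "P2y", "P2z") %in% names(x))) P2 <- as.matrix(x[, c("P2x", "P2y", "P2z")])
  dipole_trajectory(x$time, as.matrix(x[, c("Px", "Py", "Pz")]), P1 = P1, P2 = P2)
}

#' Write a dipole trajectory as CSV
#' @param traj a [dipole_trajectory()].
#' @param path output path.
#' @export
write_dipole_csv <- function(traj, path) {
  out <- tibble::tibble(time = traj$times,
                        Px = traj$P[, 1], Py = traj$P[, 2], Pz = traj$P[, 3])
  if (!is.null(traj$P1)) {
    out$P1x <- traj$P1[, 1]; out$P1y <- traj$P1[, 2]; out$P1z <- traj$P1[, 3]
  }
  if (!is.null(traj$P2)) {
    out$P2x <- traj$P2[, 1]; out$P2y <- traj$P2[, 2]; out$P2z <- traj$P2[, 3]
  }
  readr::write_csv(out, path)
  invisible(path)
}

# --- run configuration -------------------------------------------------------

.config_keys <- c("radial_cutoff", "n_radial", "l_max", "gaussian_width",
                  "species_list", "zeta", "regularization",
                  "probe_fraction", "max_restarts", "dip_threshold", "n_boot",
                  "max_OO_distance", "max_angle", "shell_cutoff",
                  "label_cutoff", "valence", "units", "seed", "paths")

#' Run configuration
#'
#' A validated bag of the tunable settings (descriptor hyperparameters, unwrap
#' settings, H-bond criterion, shell-cutoff policy, units, paths) that
#' round-trips losslessly through JSON. Unknown keys are rejected.
#'
#' @param ... named settings drawn from the known keys.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  vals <- list(...)
  if (length(vals) > 0 && (is.null(names(vals)) || any(names(vals) == ""))) {
    stop("all configuration entries must be named", call. = FALSE)
  }
  unknown <- setdiff(names(vals), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- list(radial_cutoff = 4.0, n_radial = 6L, l_max = 4L,
                   gaussian_width = 0.3, species_list = NULL, zeta = 2,
                   regularization = 1e-8, probe_fraction = 0.05,
                   max_restarts = 20L, dip_threshold = 0.05, n_boot = 1000L,
                   max_OO_distance = 3.5, max_angle = 30, shell_cutoff = NULL,
                   label_cutoff = 1.8, valence = as.list(.default_valence),
                   units = "e.A", seed = 1L, paths = list())
  cfg <- utils::modifyList(defaults, vals)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$paths <- as.list(obj$paths)
  obj$valence <- as.list(obj$valence)
  do.call(run_config, obj)
}
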