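# Rotationally covariant kernel ridge regression for 3-vector targets.
#
# Two flavours share one machinery:
#   * global polarization models: the target is the cell polarization P of a
#     frame, represented as a sum of atom-centered 3-vectors (the kernel
#     between frames is the sum of atomic kernels, so per-atom contributions
#     are defined -- the decomposition the shell-resolved spectra need);
#   * Wannier displacement models: one sub-model per species, the target is
#     the per-atom displacement sum Delta_i.
# Covariance (predictions rotate exactly with the input) is inherited from the
# covariant features, not learned.

MODEL_VERSION <- "polwann-model-1"

# 3x3-blocked kernel between two featurized sets, optionally aggregating rows/
# columns by group (frame). Returns 3x3 list of matrices.
kernel_blocks <- function(fa, fb, zeta, group_a = NULL, group_b = NULL) {
  k0 <- tcrossprod(fa$Phi, fb$Phi)
  if (zeta != 1) k0 <- k0^(zeta - 1)
  comp <- list(fa$Fx, fa$Fy, fa$Fz)
  compb <- list(fb$Fx, fb$Fy, fb$Fz)
  out <- vector("list", 9)
  for (a in 1:3) for (b in 1:3) {
    B <- tcrossprod(comp[[a]], compb[[b]]) * k0
    if (!is.null(group_a)) B <- rowsum(B, group_a, reorder = TRUE)
    if (!is.null(group_b)) B <- t(rowsum(t(B), group_b, reorder = TRUE))
    out[[(a - 1) * 3 + b]] <- B
  }
  out
}

# assemble the blocked kernel into a (3 Fa) x (3 Fb) matrix, component-major
assemble_blocks <- function(blocks) {
  rows <- lapply(1:3, function(a) do.call(cbind, blocks[(a - 1) * 3 + 1:3]))
  do.call(rbind, rows)
}

solve_ridge <- function(K, y, regularization) {
  lam <- regularization * mean(diag(K))
  if (lam > 0) K <- K + diag(lam, nrow(K))
  w <- tryCatch(solve(K, y), error = function(e) {
    stop("kernel system is singular or ill-conditioned; set regularization > 0",
         call. = FALSE)
  })
  w
}

#' Train a global polarization model
#'
#' Fits covariant kernel ridge regression of smooth-branch polarizations on
#' whole frames, using the summed-environment kernel so that every prediction
#' decomposes into atom-centered 3-vectors.
#'
#' @param frames list of [frame()]s (>= 2).
#' @param targets N x 3 matrix of polarizations on a single smooth branch,
#'   e·Å.
#' @param config a [descriptor_config()].
#' @param regularization ridge parameter, relative to the mean kernel
#'   diagonal.
#' @param zeta scalar-kernel exponent.
#' @return a `vector_kernel_model`.
#' @export
train_polarization_model <- function(frames, targets, config = descriptor_config(),
                                     regularization = 1e-8, zeta = 2) {
  targets <- rbind_vec3(targets, "targets")
  if (length(frames) < 2) stop("need at least 2 training frames", call. = FALSE)
  if (nrow(targets) != length(frames)) {
    stop("one target polarization per frame required", call. = FALSE)
  }
  feat <- featurize_frames(frames, config)
  blocks <- kernel_blocks(feat, feat, zeta, feat$frame_id, feat$frame_id)
  K <- assemble_blocks(blocks)
  nf <- length(frames)
  y <- c(targets[, 1], targets[, 2], targets[, 3])
  w <- solve_ridge(K, y, regularization)
  structure(list(target_kind = "global_polarization",
                 config = feat$config, zeta = zeta,
                 regularization = regularization,
                 feat = feat, n_frames = nf,
                 weights = matrix(w, nf, 3),
                 fitted = matrix(K %*% w, nf, 3),
                 targets = targets,
                 version = MODEL_VERSION),
            class = "vector_kernel_model")
}

#' @export
print.vector_kernel_model <- function(x, ...) {
  cat(sprintf("<vector_kernel_model [%s]: %s, zeta=%g, lambda=%g>\n",
              x$target_kind,
              if (x$target_kind == "global_polarization")
                sprintf("%d frames", x$n_frames)
              else sprintf("species %s", paste(names(x$sub), collapse = ",")),
              x$zeta, x$regularization))
  invisible(x)
}

#' Predict the polarization of a frame, atom by atom
#'
#' @param model a `vector_kernel_model` with `target_kind`
#'   `"global_polarization"`.
#' @param frame a [frame()] (or list of frames).
#' @return for a single frame, an `atomic_dipole_decomposition`: list with
#'   `per_atom` (N x 3, e·Å) and `total` (3-vector). For a list of frames, a
#'   list of such objects.
#' @export
predict_polarization <- function(model, frame) {
  stopifnot(inherits(model, "vector_kernel_model"),
            model$target_kind == "global_polarization")
  single <- inherits(frame, "frame")
  frames <- if (single) list(frame) else frame
  feat <- featurize_frames(frames, model$config)
  # aggregate only over training frames; rows stay per test atom
  blocks <- kernel_blocks(feat, model$feat, model$zeta,
                          group_a = NULL, group_b = model$feat$frame_id)
  n <- length(feat$frame_id)
  per_atom <- matrix(0, n, 3)
  for (a in 1:3) for (b in 1:3) {
    per_atom[, a] <- per_atom[, a] + blocks[[(a - 1) * 3 + b]] %*% model$weights[, b]
  }
  res <- lapply(seq_along(frames), function(fi) {
    pa <- per_atom[feat$frame_id == fi, , drop = FALSE]
    atomic_dipole_decomposition(pa)
  })
  if (single) res[[1]] else res
}

#' Atomic dipole decomposition
#'
#' @param per_atom N x 3 matrix of atom-centered dipole vectors, e·Å.
#' @return list with `per_atom` and `total` (the column sum).
#' @export
atomic_dipole_decomposition <- function(per_atom) {
  per_atom <- rbind_vec3(per_atom, "per_atom")
  structure(list(per_atom = per_atom, total = colSums(per_atom)),
            class = "atomic_dipole_decomposition")
}

#' @export
print.atomic_dipole_decomposition <- function(x, ...) {
  cat(sprintf("<atomic_dipole_decomposition: %d atoms, total P = (%.4f, %.4f, %.4f) e.A>\n",
              nrow(x$per_atom), x$total[1], x$total[2], x$total[3]))
  invisible(x)
}

#' Train per-species Wannier displacement models
#'
#' One covariant kernel model per species, regressing the per-atom
#' displacement sum Delta_i on the atomic environment.
#'
#' @param frames list of [frame()]s.
#' @param displacement_targets list (per frame) of N_atoms x 3 matrices of
#'   Delta_i, e·Å; a single stacked matrix over all atoms is also accepted.
#' @param config a [descriptor_config()].
#' @param regularization,zeta as in [train_polarization_model()].
#' @return a `vector_kernel_model` with per-species sub-models.
#' @export
train_wannier_model <- function(frames, displacement_targets,
                                config = descriptor_config(),
                                regularization = 1e-8, zeta = 2) {
  if (inherits(frames, "frame")) frames <- list(frames)
  if (is.list(displacement_targets) && !is.data.frame(displacement_targets)) {
    displacement_targets <- do.call(rbind, displacement_targets)
  }
  displacement_targets <- rbind_vec3(displacement_targets, "displacement_targets")
  feat <- featurize_frames(frames, config)
  if (nrow(displacement_targets) != length(feat$species)) {
    stop("need one Delta_i 3-vector per atom across all frames", call. = FALSE)
  }
  sub <- list()
  for (s in unique(feat$species)) {
    rows <- which(feat$species == s)
    if (length(rows) < 2) {
      stop(sprintf("species %s has only %d training environment(s); need >= 2",
                   s, length(rows)), call. = FALSE)
    }
    fs <- list(Fx = feat$Fx[rows, , drop = FALSE], Fy = feat$Fy[rows, , drop = FALSE],
               Fz = feat$Fz[rows, , drop = FALSE], Phi = feat$Phi[rows, , drop = FALSE])
    K <- assemble_blocks(kernel_blocks(fs, fs, zeta))
    y <- c(displacement_targets[rows, 1], displacement_targets[rows, 2],
           displacement_targets[rows, 3])
    w <- solve_ridge(K, y, regularization)
    sub[[s]] <- list(feat = fs, weights = matrix(w, length(rows), 3),
                     targets = displacement_targets[rows, , drop = FALSE])
  }
  structure(list(target_kind = "wannier_displacement",
                 config = feat$config, zeta = zeta,
                 regularization = regularization, sub = sub,
                 version = MODEL_VERSION),
            class = "vector_kernel_model")
}

#' Predict per-atom Wannier displacement sums
#'
#' @param model a `vector_kernel_model` with `target_kind`
#'   `"wannier_displacement"`.
#' @param frame a [frame()].
#' @return N_atoms x 3 matrix of predicted Delta_i, e·Å.
#' @export
predict_wannier_displacements <- function(model, frame) {
  stopifnot(inherits(model, "vector_kernel_model"),
            model$target_kind == "wannier_displacement")
  feat <- featurize_frames(list(frame), model$config)
  out <- matrix(0, n_atoms(frame), 3)
  for (s in unique(feat$species)) {
    if (is.null(model$sub[[s]])) {
      stop(sprintf("model has no sub-model for species %s", s), call. = FALSE)
    }
    rows <- which(feat$species == s)
    fs <- list(Fx = feat$Fx[rows, , drop = FALSE], Fy = feat$Fy[rows, , drop = FALSE],
               Fz = feat$Fz[rows, , drop = FALSE], Phi = feat$Phi[rows, , drop = FALSE])
    blocks <- kernel_blocks(fs, model$sub[[s]]$feat, model$zeta)
    for (a in 1:3) for (b in 1:3) {
      out[rows, a] <- out[rows, a] +
        blocks[[(a - 1) * 3 + b]] %*% model$sub[[s]]$weights[, b]
    }
  }
  out
}

#' Reconstruct a polarization from predicted displacement sums
#'
#' Combines predicted Delta_i with the expected center counts per atom label
#' (the other half of a Wannier model) into the per-atom form of the
#' polarization.
#'
#' @param frame a [frame()].
#' @param deltas N x 3 matrix of (predicted) Delta_i, e·Å.
#' @param expected named integer vector from [most_probable_counts()].
#' @param labels per-atom labels (default recomputed with the default cutoff).
#' @param valence named valence charges.
#' @return 3-vector, e·Å.
#' @export
polarization_from_deltas <- function(frame, deltas, expected, labels = NULL,
                                     valence = .default_valence) {
  if (is.null(labels)) labels <- atom_labels(frame)
  deltas <- rbind_vec3(deltas, "deltas")
  counts <- unname(expected[labels])
  if (any(is.na(counts))) {
    stop("no expected count for label(s): ",
         paste(unique(labels[is.na(counts)]), collapse = ", "), call. = FALSE)
  }
  Z <- valence[frame$species]
  eff <- Z - 2 * counts
  unname(colSums(frame$positions * eff) - colSums(deltas))
}

#' Leave-one-out predictions of a global polarization model
#'
#' Closed-form ridge leave-one-out: with hat matrix `H = K (K + lambda I)^-1`,
#' the LOO residual of coordinate i is `(y_i - yhat_i) / (1 - H_ii)`. Each
#' frame's polarization is thus predicted by a model that never saw it --
#' which is what makes these predictions usable for outlier-proof branch
#' re-assignment.
#'
#' @param model a `vector_kernel_model` with global targets.
#' @return n_frames x 3 matrix of LOO-predicted polarizations.
#' @export
loo_predictions <- function(model) {
  stopifnot(inherits(model, "vector_kernel_model"),
            model$target_kind == "global_polarization")
  feat <- model$feat
  K <- assemble_blocks(kernel_blocks(feat, feat, model$zeta,
                                     feat$frame_id, feat$frame_id))
  lam <- model$regularization * mean(diag(K))
  M <- K + diag(lam, nrow(K))
  Hd <- diag(K %*% solve(M))
  y <- c(model$targets[, 1], model$targets[, 2], model$targets[, 3])
  yhat <- c(model$fitted[, 1], model$fitted[, 2], model$fitted[, 3])
  denom <- pmax(1 - Hd, 0.05)
  loo <- y - (y - yhat) / denom
  matrix(loo, model$n_frames, 3)
}

# --- serialization -----------------------------------------------------------

#' Write / read a model archive
#'
#' Models are stored as a single self-describing JSON archive (version field,
#' descriptor configuration, species, reference features and weights).
#'
#' @param model a `vector_kernel_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  ser_feat <- function(f) list(Fx = f$Fx, Fy = f$Fy, Fz = f$Fz, Phi = f$Phi,
                               frame_id = f$frame_id, species = f$species)
  obj <- list(version = model$version, target_kind = model$target_kind,
              zeta = model$zeta, regularization = model$regularization,
              config = model$config[c("radial_cutoff", "n_radial", "l_max",
                                      "gaussian_width", "species_list")])
  if (model$target_kind == "global_polarization") {
    obj$feat <- ser_feat(model$feat)
    obj$weights <- model$weights
    obj$n_frames <- model$n_frames
  } else {
    obj$sub <- lapply(model$sub, function(s) list(feat = ser_feat(s$feat), weights = s$weights))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != MODEL_VERSION) {
    stop("not a recognised model archive (missing/unknown version field)", call. = FALSE)
  }
  des_feat <- function(f) list(Fx = as.matrix(f$Fx), Fy = as.matrix(f$Fy),
                               Fz = as.matrix(f$Fz), Phi = as.matrix(f$Phi),
                               frame_id = f$frame_id, species = f$species)
  cfg <- descriptor_config(obj$config$radial_cutoff, obj$config$n_radial,
                           obj$config$l_max, obj$config$gaussian_width,
                           obj$config$species_list)
  m <- list(target_kind = obj$target_kind, config = cfg, zeta = obj$zeta,
            regularization = obj$regularization, version = obj$version)
  if (obj$target_kind == "global_polarization") {
    m$feat <- des_feat(obj$feat)
    m$feat$config <- cfg
    m$weights <- as.matrix(obj$weights)
    m$n_frames <- obj$n_frames
  } else {
    m$sub <- lapply(obj$sub, function(s) list(feat = des_feat(s$feat), weights = as.matrix(s$weights)))
  }
  structure(m, class = "vector_kernel_model")
}
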