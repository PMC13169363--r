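# Wannier-center assignment and the Wannier route to the polarization.
#
# Each maximally localized Wannier center is a doubly occupied orbital. With
# valence nuclear charges Z_i the cell dipole is
#   P = e * sum_i Z_i R_i - 2 e * sum_j r_j^W.
# Assigning every center to an atom rewrites this as a sum of per-atom terms
#   P = e * sum_i [ (Z_i - 2 N_i^W) R_i - Delta_i ],
# with N_i^W the number of centers owned by atom i and
# Delta_i = sum_{j in i} 2 (r_j^W - R_i) the (doubly weighted) displacement
# sum -- the per-atom quantity the regression module learns. The assignment is
# pure bookkeeping: the two forms agree for *any* ownership, modulo the
# quantum of polarization when minimum-image displacements wrap a center
# across the cell boundary.

#' Default valence (pseudopotential) charges
#' @keywords internal
.default_valence <- c(O = 6, C = 4, H = 1)

#' Construct a set of Wannier centers
#'
#' @param positions N x 3 matrix of Cartesian center coordinates, Å. Every
#'   center carries 2 electrons.
#' @return object of class `wannier_set`.
#' @export
wannier_set <- function(positions) {
  positions <- rbind_vec3(positions, "positions")
  if (any(!is.finite(positions))) stop("center positions must be finite", call. = FALSE)
  structure(list(positions = positions, occupancy = 2), class = "wannier_set")
}

#' @export
print.wannier_set <- function(x, ...) {
  cat(sprintf("<wannier_set: %d doubly occupied centers>\n", nrow(x$positions)))
  invisible(x)
}

#' Assign each Wannier center to its nearest atom
#'
#' Ownership minimizes the minimum-image distance. An exact tie (within
#' `tie_tol` Å) is an error: assignment would be arbitrary.
#'
#' @param frame a [frame()].
#' @param centers a [wannier_set()].
#' @param tie_tol tie tolerance, Å.
#' @return a `wannier_assignment`: list with `owner` (per-center atom index),
#'   `counts` (per-atom N_i^W), `delta_sums` (N_atoms x 3 matrix of
#'   Delta_i = sum_j 2 delta_ij, e·Å with unit charge), and `displacements`
#'   (per-center minimum-image delta_ij rows).
#' @export
assign_nearest <- function(frame, centers, tie_tol = 1e-9) {
  stopifnot(inherits(centers, "wannier_set"))
  if (nrow(centers$positions) == 0) stop("empty Wannier set", call. = FALSE)
  d <- pair_distances(centers$positions, frame$positions, frame$cell)
  owner <- integer(nrow(d))
  for (j in seq_len(nrow(d))) {
    ord <- order(d[j, ])
    if (ncol(d) > 1 && d[j, ord[2]] - d[j, ord[1]] < tie_tol) {
      stop(sprintf("center %d is equidistant (within %g A) from atoms %d and %d",
                   j, tie_tol, ord[1], ord[2]), call. = FALSE)
    }
    owner[j] <- ord[1]
  }
  build_assignment(frame, centers, owner)
}

# assemble counts / displacement sums for a given ownership vector
build_assignment <- function(frame, centers, owner) {
  n <- n_atoms(frame)
  counts <- tabulate(owner, nbins = n)
  disp <- min_image(frame$positions[owner, , drop = FALSE], centers$positions, frame$cell)
  delta <- matrix(0, n, 3)
  for (k in 1:3) delta[, k] <- unname(2 * tapply(disp[, k], factor(owner, levels = seq_len(n)), sum, default = 0))
  delta[is.na(delta)] <- 0
  structure(list(owner = owner, counts = counts, displacements = disp,
                 delta_sums = delta, frame = frame, centers = centers),
            class = "wannier_assignment")
}

#' @export
print.wannier_assignment <- function(x, ...) {
  cat(sprintf("<wannier_assignment: %d centers on %d atoms (counts %s)>\n",
              length(x$owner), length(x$counts),
              paste(sort(unique(x$counts)), collapse = "/")))
  invisible(x)
}

#' Chemical-environment labels for atoms
#'
#' Each atom is labeled by its species plus the sorted multiset of species
#' found within `label_cutoff` (minimum image). Atoms in identical chemical
#' environments receive identical labels, which is what lets the expected
#' Wannier-center count be tabulated per environment.
#'
#' @param frame a [frame()].
#' @param label_cutoff Å; the default 1.8 Å covers covalent bonds but excludes
#'   hydrogen-bond partners.
#' @return character vector of labels, e.g. `"C(C,H,H,H)"`.
#' @export
atom_labels <- function(frame, label_cutoff = 1.8) {
  stopifnot(label_cutoff > 0)
  d <- pair_distances(frame$positions, frame$positions, frame$cell)
  diag(d) <- Inf
  vapply(seq_len(n_atoms(frame)), function(i) {
    nb <- sort(frame$species[d[i, ] <= label_cutoff])
    paste0(frame$species[i], "(", paste(nb, collapse = ","), ")")
  }, character(1))
}

#' Most probable Wannier-center count per atom label
#'
#' Tabulates the modal N_i^W over all atoms and frames for each label; an
#' exact tie is broken toward the larger count with a warning.
#'
#' @param assignments list of `wannier_assignment`s (or a single one).
#' @param labels list of per-frame label vectors matching `assignments`.
#' @return named integer vector: expected count per label.
#' @export
most_probable_counts <- function(assignments, labels) {
  if (inherits(assignments, "wannier_assignment")) assignments <- list(assignments)
  if (!is.list(labels) || !is.null(dim(labels))) labels <- list(labels)
  if (is.character(labels[[1]]) && length(labels) != length(assignments) && length(labels) == 1) {
    labels <- rep(labels, length(assignments))
  }
  stopifnot(length(labels) == length(assignments))
  lab <- unlist(labels)
  cnt <- unlist(lapply(assignments, `[[`, "counts"))
  out <- integer(0)
  for (lv in unique(lab)) {
    tb <- table(cnt[lab == lv])
    best <- as.integer(names(tb)[tb == max(tb)])
    if (length(best) > 1) {
      warning(sprintf("tie for label %s between counts {%s}; taking the larger",
                      lv, paste(best, collapse = ",")), call. = FALSE)
    }
    out[lv] <- max(best)
  }
  out
}

#' Repair Wannier-center miscounts by bonded-pair transfer
#'
#' Wherever an atom owns one center fewer than its label's expected count and
#' a bonded neighbour owns one more, the surplus atom's center closest to the
#' deficit atom is reassigned. The total center count is conserved exactly and
#' the operation is idempotent. If any atom still deviates from its expected
#' count after all resolvable transfers, a repair-failure error lists the
#' offending atoms.
#'
#' @param raw a `wannier_assignment`.
#' @param expected named integer vector from [most_probable_counts()].
#' @param labels per-atom labels of the frame (default recomputed).
#' @param bonds optional bond matrix (default: frame bonds).
#' @return repaired `wannier_assignment`.
#' @export
repair_assignment <- function(raw, expected, labels = NULL, bonds = NULL) {
  stopifnot(inherits(raw, "wannier_assignment"))
  frame <- raw$frame
  if (is.null(labels)) labels <- atom_labels(frame)
  if (is.null(bonds)) bonds <- frame_bonds(frame)
  if (any(!labels %in% names(expected))) {
    stop("no expected count for label(s): ",
         paste(setdiff(unique(labels), names(expected)), collapse = ", "), call. = FALSE)
  }
  want <- unname(expected[labels])
  owner <- raw$owner
  counts <- raw$counts
  adj <- lapply(seq_len(n_atoms(frame)), function(i) {
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  })
  d_center_atom <- pair_distances(raw$centers$positions, frame$positions, frame$cell)
  repeat {
    deficit <- which(counts < want)
    moved <- FALSE
    for (i in deficit) {
      donors <- adj[[i]][counts[adj[[i]]] > want[adj[[i]]]]
      if (length(donors) == 0) next
      # donor whose transferable center is closest to the deficit atom
      best <- NULL
      for (dn in donors) {
        cen <- which(owner == dn)
        if (length(cen) == 0) next
        j <- cen[which.min(d_center_atom[cen, i])]
        if (is.null(best) || d_center_atom[j, i] < best$d) best <- list(center = j, d = d_center_atom[j, i], donor = dn)
      }
      if (is.null(best)) next
      owner[best$center] <- i
      counts[i] <- counts[i] + 1
      counts[best$donor] <- counts[best$donor] - 1
      moved <- TRUE
    }
    if (!moved) break
  }
  if (any(counts != want)) {
    bad <- which(counts != want)
    stop(sprintf(
      "repair failed: atoms %s have counts (%s) != expected (%s) and no bonded surplus/deficit pair resolves them",
      paste(bad, collapse = ","), paste(counts[bad], collapse = ","),
      paste(want[bad], collapse = ",")), call. = FALSE)
  }
  build_assignment(frame, raw$centers, owner)
}

#' Polarization from Wannier centers
#'
#' @param frame a [frame()].
#' @param assignment a `wannier_assignment` (for `method = "assignment"`) or a
#'   [wannier_set()] (allowed for `method = "direct"`).
#' @param valence named vector of valence charges (defaults O:6, C:4, H:1).
#' @param method `"assignment"` evaluates the per-atom form
#'   `e * sum_i [(Z_i - 2 N_i^W) R_i - Delta_i]`; `"direct"` evaluates
#'   `e * sum_i Z_i R_i - 2 e * sum_j r_j^W` from raw center positions.
#' @return 3-vector, e·Å.
#' @export
polarization_from_wannier <- function(frame, assignment,
                                      valence = .default_valence,
                                      method = c("assignment", "direct")) {
  method <- match.arg(method)
  Z <- valence[frame$species]
  if (any(is.na(Z))) stop("no valence charge for some species", call. = FALSE)
  centers <- if (inherits(assignment, "wannier_assignment")) assignment$centers else assignment
  nw <- nrow(centers$positions)
  if (abs(sum(Z) - 2 * nw) > 1e-9) {
    stop(sprintf("charge imbalance: sum(Z) = %g but centers carry %g electrons",
                 sum(Z), 2 * nw), call. = FALSE)
  }
  if (method == "direct") {
    return(unname(colSums(frame$positions * Z) - 2 * colSums(centers$positions)))
  }
  stopifnot(inherits(assignment, "wannier_assignment"))
  eff <- Z - 2 * assignment$counts
  unname(colSums(frame$positions * eff) - colSums(assignment$delta_sums))
}
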