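# Atomic frames with periodic boundary conditions and the geometry helpers
# (minimum image, covalent bond perception, molecule identification) shared by
# the Wannier-assignment and hydrogen-bond machinery.

# covalent radii (Å) for the species handled by the fixture generator and the
# bond-perception rule; values are the standard Cordero radii
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

#' Construct an atomic frame
#'
#' @param species character vector of element symbols.
#' @param positions N x 3 matrix of Cartesian coordinates, Å.
#' @param cell a [cell()] or 3x3 matrix of lattice-vector rows.
#' @param bonds optional two-column integer matrix of bonded atom pairs
#'   (1-based). When absent, [frame_bonds()] perceives them from covalent radii.
#' @return object of class `frame`.
#' @export
frame <- function(species, positions, cell, bonds = NULL) {
  positions <- rbind_vec3(positions, "positions")
  species <- as.character(species)
  if (length(species) != nrow(positions)) {
    stop("length(species) must equal nrow(positions)", call. = FALSE)
  }
  if (any(!is.finite(positions))) stop("positions must be finite", call. = FALSE)
  if (!inherits(cell, "cell")) cell <- polwann::cell(cell)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1 | bonds > length(species))) stop("bond indices out of range", call. = FALSE)
  }
  structure(list(species = species, positions = positions, cell = cell, bonds = bonds),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame: %d atoms (%s), cell volume %.1f A^3>\n",
              length(x$species),
              paste(sprintf("%s:%d", names(table(x$species)), table(x$species)), collapse = " "),
              cell_volume(x$cell)))
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame a [frame()]
#' @export
n_atoms <- function(frame) length(frame$species)

#' Minimum-image displacement vectors
#'
#' Displacements `to - from` wrapped into the cell's first image. `from` may be
#' a single point or a matrix matching `to` row-for-row.
#'
#' @param from,to points (3-vector or N x 3), Å.
#' @param cell a [cell()].
#' @return N x 3 matrix of displacements.
#' @export
min_image <- function(from, to, cell) {
  to <- rbind_vec3(to, "to")
  from <- rbind_vec3(from, "from")
  if (nrow(from) == 1 && nrow(to) > 1) from <- from[rep(1, nrow(to)), , drop = FALSE]
  d <- to - from
  L <- unclass(cell)
  f <- d %*% solve(L)          # fractional displacement (rows)
  f <- f - round(f)
  f %*% L
}

#' Pairwise minimum-image distances between two point sets
#' @param a,b matrices (Na x 3, Nb x 3), Å.
#' @param cell a [cell()].
#' @return Na x Nb distance matrix.
#' @export
pair_distances <- function(a, b, cell) {
  a <- rbind_vec3(a, "a"); b <- rbind_vec3(b, "b")
  L <- unclass(cell); Linv <- solve(L)
  fa <- a %*% Linv; fb <- b %*% Linv
  c1 <- c2 <- c3 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    df <- outer(fa[, k], fb[, k], "-")
    df <- df - round(df)
    c1 <- c1 + df * L[k, 1]; c2 <- c2 + df * L[k, 2]; c3 <- c3 + df * L[k, 3]
  }
  sqrt(c1^2 + c2^2 + c3^2)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their minimum-image distance is below
#' `scale` times the sum of their covalent radii. Returns stored bonds if the
#' frame already carries them.
#'
#' @param frame a [frame()].
#' @param scale multiplier on the covalent-radius sum (default 1.2).
#' @return two-column integer matrix of atom index pairs (i < j).
#' @export
frame_bonds <- function(frame, scale = 1.2) {
  if (!is.null(frame$bonds)) return(frame$bonds)
  sp <- frame$species
  radii <- .covalent_radii[sp]
  if (any(is.na(radii))) {
    stop("no covalent radius for species: ",
         paste(unique(sp[is.na(radii)]), collapse = ", "), call. = FALSE)
  }
  d <- pair_distances(frame$positions, frame$positions, frame$cell)
  cutoff <- outer(radii, radii, "+") * scale
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2, dimnames = NULL)
}

#' Identify molecules as connected components of the bond graph
#'
#' @param frame a [frame()].
#' @return integer vector: molecule id per atom (1-based, in order of first atom).
#' @export
molecule_ids <- function(frame) {
  n <- n_atoms(frame)
  bonds <- frame_bonds(frame)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      ri <- find(bonds[k, 1]); rj <- find(bonds[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify molecules of a water/ethanol frame
#'
#' Recognises molecules by composition: `H2O` becomes `"water"`, `C2H6O`
#' becomes `"ethanol"`, anything else `"other"`.
#'
#' @param frame a [frame()].
#' @return tibble with one row per molecule: `molecule`, `kind`, `o_index`
#'   (oxygen atom index, NA if none), `beta_carbon` (the ethanol carbon not
#'   bonded to oxygen, NA otherwise).
#' @export
classify_molecules <- function(frame) {
  mids <- molecule_ids(frame)
  bonds <- frame_bonds(frame)
  sp <- frame$species
  purrr::map_dfr(seq_len(max(mids)), function(m) {
    idx <- which(mids == m)
    comp <- table(sp[idx])
    kind <- "other"
    o_index <- NA_integer_
    beta <- NA_integer_
    if (setequal(names(comp), c("H", "O")) && comp["O"] == 1 && comp["H"] == 2) {
      kind <- "water"; o_index <- idx[sp[idx] == "O"]
    } else if (setequal(names(comp), c("C", "H", "O")) &&
               comp["C"] == 2 && comp["O"] == 1 && comp["H"] == 6) {
      kind <- "ethanol"; o_index <- idx[sp[idx] == "O"]
      carbons <- idx[sp[idx] == "C"]
      bonded_to_o <- unique(c(bonds[bonds[, 1] == o_index, 2], bonds[bonds[, 2] == o_index, 1]))
      beta_c <- setdiff(carbons, bonded_to_o)
      if (length(beta_c) == 1) beta <- beta_c else kind <- "other"
    }
    tibble::tibble(molecule = m, kind = kind, o_index = o_index, beta_carbon = beta)
  })
}

#' Rigidly rotate a frame (positions and cell)
#' @param frame a [frame()].
#' @param R 3x3 rotation matrix.
#' @export
rotate_frame <- function(frame, R) {
  stopifnot(all(dim(R) == c(3, 3)))
  frame$positions <- frame$positions %*% t(R)
  frame$cell <- cell(unclass(frame$cell) %*% t(R))
  frame
}

#' Rigidly translate a frame (periodic wrap applied)
#' @param frame a [frame()].
#' @param shift 3-vector, Å.
#' @export
translate_frame <- function(frame, shift) {
  frame$positions <- sweep(frame$positions, 2, as.numeric(shift), "+")
  frame$positions <- wrap_positions(frame$positions, frame$cell)
  frame
}

#' Wrap Cartesian positions into the home cell
#' @param positions N x 3, Å.
#' @param cell a [cell()].
#' @export
wrap_positions <- function(positions, cell) {
  L <- unclass(cell)
  f <- positions %*% solve(L)
  (f - floor(f)) %*% L
}

# Uniform random rotation matrix (quaternion method), deterministic under the
# caller's RNG state.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
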