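# Polarization algebra for periodic systems.
#
# In the modern theory of polarization the total cell dipole P of a periodic
# system is only defined modulo a "quantum of polarization": adding an integer
# multiple of e times any lattice vector to P leaves the physics unchanged.
# Everything downstream (branch unwrapping, circular error metrics) is built on
# the reduced polarization p = Q^-1 P, whose components live on the unit circle.

#' Conversion factor from e·Ångström to Debye
#'
#' One elementary charge displaced by one Ångström corresponds to
#' 4.803205 Debye (CODATA). Charges are carried internally in units of e, so
#' this factor is applied only when reading or writing Debye-valued tables.
#' @keywords internal
EA_TO_DEBYE <- 4.803205

#' Construct a periodic cell
#'
#' @param vectors 3x3 numeric matrix of lattice vectors, one per row
#'   (`a1`, `a2`, `a3`), in Ångström.
#' @return An object of class `cell`: the validated matrix.
#' @examples
#' cell(diag(3) * 12.4)
#' @export
cell <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (!is.numeric(vectors) || !identical(dim(vectors), c(3L, 3L))) {
    stop("`vectors` must be a numeric 3x3 matrix of lattice vectors (rows)", call. = FALSE)
  }
  if (any(!is.finite(vectors))) stop("lattice vectors must be finite", call. = FALSE)
  d <- det(vectors)
  if (abs(d) < 1e-10 * max(1, max(abs(vectors)))^3) {
    stop("degenerate cell: lattice vectors are linearly dependent (zero volume)", call. = FALSE)
  }
  structure(vectors, class = "cell")
}

#' Cell volume in cubic Angstrom
#' @param x a [cell()]
#' @export
cell_volume <- function(x) abs(det(unclass(x)))

#' Quantum-of-polarization matrix
#'
#' The polarization of a periodic system is defined modulo the matrix `Q` whose
#' columns are `e` times the lattice vectors: `P` and `P + Q n` are physically
#' equivalent for any integer vector `n`. With charges in units of `e` and the
#' cell in Å, `Q` has units e·Å.
#'
#' @param cell a [cell()] (or a 3x3 matrix of lattice-vector rows).
#' @return 3x3 invertible matrix with class `quantum_matrix`.
#' @export
quantum_matrix <- function(cell) {
  if (!inherits(cell, "cell")) cell <- polwann::cell(cell)
  # lattice vectors are stored as rows; the quantum matrix carries them as columns
  structure(t(unclass(cell)), class = "quantum_matrix")
}

#' Reduce a polarization onto the first branch
#'
#' Computes the reduced polarization `p = Q^-1 P` wrapped component-wise into
#' `[-1/2, 1/2)` and the integer branch offsets `n` such that `P = Q (p + n)`.
#' The wrap convention is half-open: a component landing exactly on `+1/2` maps
#' to `-1/2`.
#'
#' @param P numeric 3-vector (or N x 3 matrix) of polarizations, e·Å.
#' @param Q a [quantum_matrix()].
#' @param frame_id optional identifier(s) carried through to the output.
#' @return A tibble with one row per polarization: `frame_id`, the raw
#'   components `Px, Py, Pz`, the reduced components `px, py, pz` and integer
#'   offsets `nx, ny, nz`.
#' @export
reduce_polarization <- function(P, Q, frame_id = NULL) {
  P <- rbind_vec3(P, "P")
  if (any(!is.finite(P))) stop("non-finite polarization components", call. = FALSE)
  stopifnot(inherits(Q, "quantum_matrix"))
  praw <- P %*% t(solve(unclass(Q)))     # rows: Q^-1 P
  p <- wrap_half(praw)
  n <- praw - p
  if (max(abs(n - round(n))) > 1e-9) stop("internal error: offsets not integral")
  n <- round(n)
  if (is.null(frame_id)) frame_id <- seq_len(nrow(P))
  tibble::tibble(
    frame_id = frame_id,
    Px = P[, 1], Py = P[, 2], Pz = P[, 3],
    px = p[, 1], py = p[, 2], pz = p[, 3],
    nx = n[, 1], ny = n[, 2], nz = n[, 3]
  )
}

#' Wrap values into the half-open interval [-1/2, 1/2)
#'
#' Deterministic wrap used throughout: `wrap_half(x) = x - round(x)`, with the
#' tie at exactly `+1/2` mapped to `-1/2`.
#' @param x numeric vector or matrix.
#' @export
wrap_half <- function(x) {
  w <- x - floor(x + 0.5)
  # floor(x + 0.5) rounds half-up, so +0.5 already maps to -0.5; guard roundoff
  w[w >= 0.5] <- w[w >= 0.5] - 1
  w
}

#' Von Mises error between reduced polarizations
#'
#' Circular error metric for period-1 data:
#' `vME = 1 - (1/3N) sum_i sum_alpha cos(2 pi (p_pred - p_calc))`.
#' It is zero for perfect prediction, two when every residual component is half
#' a quantum, and invariant under adding integers to any component of either
#' argument, which makes it the appropriate loss for branch-ambiguous
#' polarization data.
#'
#' @param p_pred,p_calc N x 3 matrices (or length-3 vectors) of reduced
#'   polarizations.
#' @return scalar in `[0, 2]`.
#' @export
von_mises_error <- function(p_pred, p_calc) {
  p_pred <- rbind_vec3(p_pred, "p_pred")
  p_calc <- rbind_vec3(p_calc, "p_calc")
  if (nrow(p_pred) != nrow(p_calc)) {
    stop("p_pred and p_calc must have the same number of points", call. = FALSE)
  }
  if (nrow(p_pred) < 1) stop("need at least one point", call. = FALSE)
  1 - mean(cos(2 * pi * (p_pred - p_calc)))
}

#' Convert e-Angstrom to Debye (and back)
#'
#' @param x numeric, e·Å (or Debye for the inverse).
#' @return numeric in Debye (respectively e·Å).
#' @export
ea_to_debye <- function(x) {
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  x * EA_TO_DEBYE
}

#' @rdname ea_to_debye
#' @export
debye_to_ea <- function(x) {
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  x / EA_TO_DEBYE
}

# Coerce a length-3 vector or N x 3 matrix-like to an N x 3 matrix.
rbind_vec3 <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3) stop(sprintf("`%s` must be a 3-vector or N x 3 matrix", what), call. = FALSE)
    x <- matrix(x, 1, 3)
  }
  if (ncol(x) != 3) stop(sprintf("`%s` must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  x
}
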