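# Infrared spectra from polarization dynamics.
#
# The IR absorption of a classical trajectory is proportional to
# omega^2 times the Fourier transform of the polarization autocorrelation
# <P(t).P(0)>. It is evaluated here in the Wiener-Khinchin form -- omega^2
# times the squared modulus of the Fourier transform of the windowed,
# mean-removed signal -- which is the same estimator but guarantees
# nonnegative auto-spectra and makes the two-component decomposition
#   I = I1 + I2 + Ic   (auto, auto, symmetrized cross term)
# close exactly. No quantum correction is applied: the input dynamics is
# classical.

# speed of light in cm/fs: converts wavenumber (cm^-1) to cycles/fs
.c_cm_fs <- 2.99792458e-5

#' Dipole (polarization) trajectory
#'
#' @param times numeric vector, fs, uniformly spaced, length >= 8.
#' @param P T x 3 matrix of polarizations, e·Å.
#' @param P1,P2 optional component trajectories (same shape); when present
#'   they must sum to `P` within `1e-8` relative.
#' @return object of class `dipole_trajectory`.
#' @export
dipole_trajectory <- function(times, P, P1 = NULL, P2 = NULL) {
  P <- rbind_vec3(P, "P")
  times <- as.numeric(times)
  if (length(times) != nrow(P)) stop("times and P disagree in length", call. = FALSE)
  if (length(times) < 8) stop("need at least 8 samples", call. = FALSE)
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1))) {
    stop("time grid must be uniform", call. = FALSE)
  }
  if (dt[1] <= 0) stop("time step must be positive", call. = FALSE)
  if (!is.null(P1)) P1 <- rbind_vec3(P1, "P1")
  if (!is.null(P2)) P2 <- rbind_vec3(P2, "P2")
  if (!is.null(P1) && !is.null(P2)) {
    scale <- max(abs(P), 1e-300)
    if (max(abs(P1 + P2 - P)) > 1e-8 * scale) {
      stop("P1 + P2 does not reproduce the stored total polarization", call. = FALSE)
    }
  }
  structure(list(times = times, dt = dt[1], P = P, P1 = P1, P2 = P2),
            class = "dipole_trajectory")
}

#' @export
print.dipole_trajectory <- function(x, ...) {
  cat(sprintf("<dipole_trajectory: %d steps, dt = %g fs%s>\n",
              length(x$times), x$dt,
              if (!is.null(x$P1)) ", with shell components" else ""))
  invisible(x)
}

window_vector <- function(n, window = c("hann", "bartlett", "none")) {
  window <- match.arg(window)
  k <- seq_len(n) - 1
  switch(window,
         hann = 0.5 * (1 - cos(2 * pi * k / (n - 1))),
         bartlett = 1 - abs((k - (n - 1) / 2) / ((n - 1) / 2)),
         none = rep(1, n))
}

# windowed, zero-padded FFT of the mean-removed components of a T x 3 signal
spectral_transform <- function(X, w, n_pad) {
  X <- sweep(X, 2, colMeans(X))
  out <- matrix(0i, n_pad, 3)
  for (a in 1:3) out[, a] <- stats::fft(c(X[, a] * w, rep(0, n_pad - nrow(X))))
  out
}

#' Infrared spectrum of a dipole trajectory
#'
#' @param traj a [dipole_trajectory()].
#' @param window apodization window (`"hann"` default).
#' @param max_wavenumber upper edge of the reported grid, cm^-1.
#' @param pad zero-padding factor for grid refinement.
#' @return an `ir_spectrum` tibble: `wavenumber` (cm^-1, ascending) and
#'   `intensity` (arbitrary units, >= 0); shell components `I1`, `I2`, `Ic`
#'   are attached by [decomposed_spectra()].
#' @export
ir_spectrum <- function(traj, window = "hann", max_wavenumber = 4000, pad = 2) {
  stopifnot(inherits(traj, "dipole_trajectory"))
  T_ <- nrow(traj$P)
  w <- window_vector(T_, window)
  n_pad <- pad * T_
  Fv <- spectral_transform(traj$P, w, n_pad)
  grid <- spectrum_grid(n_pad, traj$dt, max_wavenumber)
  intensity <- grid$wavenumber^2 * rowSums(abs(Fv[grid$bins, , drop = FALSE])^2)
  new_spectrum(tibble::tibble(wavenumber = grid$wavenumber, intensity = intensity))
}

spectrum_grid <- function(n_pad, dt, max_wavenumber) {
  nyq_bin <- floor(n_pad / 2)
  wn <- (0:nyq_bin) / (n_pad * dt * .c_cm_fs)
  keep <- wn <= max_wavenumber
  list(bins = which(keep), wavenumber = wn[keep])
}

new_spectrum <- function(df) {
  class(df) <- c("ir_spectrum", class(df))
  df
}

#' Shell-resolved spectra
#'
#' Computes the auto-spectra of the two stored polarization components and the
#' symmetrized cross term; `I1 + I2 + Ic` equals the spectrum of the total
#' polarization pointwise to machine precision.
#'
#' @inheritParams ir_spectrum
#' @return an `ir_spectrum` with columns `I1`, `I2`, `Ic`.
#' @export
decomposed_spectra <- function(traj, window = "hann", max_wavenumber = 4000, pad = 2) {
  stopifnot(inherits(traj, "dipole_trajectory"))
  if (is.null(traj$P1) || is.null(traj$P2)) {
    stop("trajectory carries no shell components P1/P2", call. = FALSE)
  }
  T_ <- nrow(traj$P)
  w <- window_vector(T_, window)
  n_pad <- pad * T_
  F1 <- spectral_transform(traj$P1, w, n_pad)
  F2 <- spectral_transform(traj$P2, w, n_pad)
  grid <- spectrum_grid(n_pad, traj$dt, max_wavenumber)
  w2 <- grid$wavenumber^2
  I1 <- w2 * rowSums(abs(F1[grid$bins, , drop = FALSE])^2)
  I2 <- w2 * rowSums(abs(F2[grid$bins, , drop = FALSE])^2)
  Ic <- w2 * rowSums(2 * Re(F1[grid$bins, , drop = FALSE] *
                              Conj(F2[grid$bins, , drop = FALSE])))
  new_spectrum(tibble::tibble(wavenumber = grid$wavenumber,
                              intensity = I1 + I2 + Ic,
                              I1 = I1, I2 = I2, Ic = Ic))
}

#' Split per-atom dipoles into first-shell and outer-shell water parts
#'
#' @param decomp an [atomic_dipole_decomposition()] (or N x 3 matrix of
#'   per-atom vectors, e·Å).
#' @param frame the [frame()] the decomposition belongs to.
#' @param first_shell logical vector, one entry per molecule (in
#'   [molecule_ids()] order); every water molecule must be flagged TRUE/FALSE.
#' @return list with `P1` (first-shell water sum), `P2` (other water sum),
#'   `P_other` (non-water molecules) and the per-molecule tibble.
#' @export
decompose_polarization <- function(decomp, frame, first_shell) {
  per_atom <- if (inherits(decomp, "atomic_dipole_decomposition")) decomp$per_atom else rbind_vec3(decomp, "decomp")
  mids <- molecule_ids(frame)
  info <- classify_molecules(frame)
  if (length(first_shell) != nrow(info)) {
    stop("need one first_shell flag per molecule", call. = FALSE)
  }
  wat <- info$kind == "water"
  if (any(is.na(first_shell[wat]))) {
    stop("unflagged water molecule(s): ",
         paste(info$molecule[wat & is.na(first_shell)], collapse = ", "), call. = FALSE)
  }
  mol_dip <- rowsum(per_atom, mids)
  tab <- tibble::tibble(molecule = info$molecule, kind = info$kind,
                        first_shell = first_shell,
                        mux = mol_dip[, 1], muy = mol_dip[, 2], muz = mol_dip[, 3])
  sum_rows <- function(rows) {
    if (!any(rows)) c(0, 0, 0) else colSums(mol_dip[rows, , drop = FALSE])
  }
  list(P1 = sum_rows(wat & first_shell %in% TRUE),
       P2 = sum_rows(wat & first_shell %in% FALSE),
       P_other = sum_rows(!wat),
       molecules = tab)
}

#' Locate a spectral peak
#'
#' Argmax inside the search window refined by three-point quadratic
#' interpolation. A window in which the intensity has no interior maximum
#' (flat, or curvature >= 0 at the argmax) raises a no-peak error.
#'
#' @param spectrum an `ir_spectrum`.
#' @param search_window length-2 numeric, cm^-1.
#' @param component column to search (default `"intensity"`).
#' @return peak position, cm^-1.
#' @export
peak_position <- function(spectrum, search_window, component = "intensity") {
  stopifnot(length(search_window) == 2)
  rows <- which(spectrum$wavenumber >= search_window[1] &
                  spectrum$wavenumber <= search_window[2])
  if (length(rows) < 3) stop("search window contains fewer than 3 grid points", call. = FALSE)
  y <- spectrum[[component]][rows]
  x <- spectrum$wavenumber[rows]
  i <- which.max(y)
  if (i == 1 || i == length(y)) {
    if (diff(range(y)) <= 1e-12 * max(abs(y), 1e-300)) {
      stop("no peak in window: spectrum is flat", call. = FALSE)
    }
    return(x[i])    # maximum at the window edge: no refinement possible
  }
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) stop("no peak in window: curvature is not negative", call. = FALSE)
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[i + 1] - x[i])
}

#' Peak positions and shifts across concentrations
#'
#' @param spectra named list of `ir_spectrum` objects; names are numeric
#'   concentrations (volume or mole fractions).
#' @param search_window length-2 numeric, cm^-1.
#' @param reference concentration whose peak defines shift zero.
#' @param component column to search.
#' @return tibble: `concentration`, `peak` (cm^-1), `shift` (cm^-1; exactly 0
#'   at the reference).
#' @export
peak_shift_series <- function(spectra, search_window, reference,
                              component = "intensity") {
  conc <- as.numeric(names(spectra))
  if (any(is.na(conc))) stop("spectra must be named by numeric concentration", call. = FALSE)
  ref_i <- which(abs(conc - reference) < 1e-12)
  if (length(ref_i) != 1) stop("reference concentration not present", call. = FALSE)
  peaks <- vapply(spectra, peak_position, numeric(1),
                  search_window = search_window, component = component)
  shift <- peaks - peaks[ref_i]
  shift[ref_i] <- 0
  tibble::tibble(concentration = conc, peak = unname(peaks), shift = unname(shift))
}
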