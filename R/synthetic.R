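# Synthetic fixture generation.
#
# Everything the learning, unwrapping, spectroscopy and structure code needs as
# input can be generated here with known ground truth: idealized rigid
# water/ethanol mixtures, Wannier centers at bond and lone-pair sites, a smooth
# point-charge + bond-dipole polarization oracle, polarization data scattered
# onto random branches, and dipole time series with known spectral lines.
# Generators are pure functions of their seed.

# --- idealized molecular geometries -----------------------------------------

.tet <- acos(-1 / 3)  # tetrahedral angle, rad

unitv <- function(v) v / sqrt(sum(v^2))

# water: O at origin, O-H 0.96 A, H-O-H 104.5 deg; species O,H,H
.water_template <- function() {
  half <- 104.5 / 2 * pi / 180
  pos <- rbind(c(0, 0, 0),
               0.96 * c(cos(half), sin(half), 0),
               0.96 * c(cos(half), -sin(half), 0))
  list(species = c("O", "H", "H"), positions = pos,
       bonds = rbind(c(1L, 2L), c(1L, 3L)))
}

# ethanol CH3-CH2-OH with standard bond geometry;
# species order: C(beta) C(alpha) O H H H (methyl) H H (alpha) H (hydroxyl)
.ethanol_template <- function() {
  cb <- c(0, 0, 0)
  ca <- c(1.54, 0, 0)
  d_o <- c(cos(pi - .tet), sin(pi - .tet), 0)   # 109.47 deg from the C-C axis
  o <- ca + 1.43 * d_o
  # hydroxyl H: 108.5 deg from the O->Ca direction, kept in the xy plane
  b_oc <- unitv(ca - o)
  ang <- 108.5 * pi / 180
  perp <- unitv(c(-b_oc[2], b_oc[1], 0))
  h_oh <- o + 0.96 * (cos(ang) * b_oc + sin(ang) * perp)
  # methyl hydrogens: tetrahedral cone opposite the C-C bond
  hm <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    cb + 1.09 * c(cos(.tet), sin(.tet) * cos(phi), sin(.tet) * sin(phi))
  }, numeric(3)))
  # the two alpha hydrogens: bisector construction out of the C-C / C-O plane
  b1 <- unitv(cb - ca); b2 <- unitv(o - ca)
  u <- unitv(-(b1 + b2)); w <- unitv(pracma_cross(b1, b2))
  halftet <- .tet / 2
  ha1 <- ca + 1.09 * unitv(cos(halftet) * u + sin(halftet) * w)
  ha2 <- ca + 1.09 * unitv(cos(halftet) * u - sin(halftet) * w)
  pos <- rbind(cb, ca, o, hm, ha1, ha2, h_oh)
  rownames(pos) <- NULL
  list(species = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
       positions = pos,
       bonds = rbind(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(1L, 5L), c(1L, 6L),
                     c(2L, 7L), c(2L, 8L), c(3L, 9L)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Describe a synthetic mixture fixture
#'
#' @param n_water,n_ethanol molecule counts.
#' @param box cubic box edge, Å. Default allots 110 Å³ per molecule, a density
#'   at which rejection packing of rigid molecules succeeds reliably while
#'   keeping neighbours inside a 4 Å descriptor cutoff.
#' @param seed integer RNG seed.
#' @param noise_scale Gaussian jitter applied to Wannier-center sites, Å.
#' @param branch_offset_range bound of the random integer branch offsets.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_water = 4, n_ethanol = 0, box = NULL, seed = 1,
                         noise_scale = 0, branch_offset_range = 2) {
  stopifnot(n_water >= 0, n_ethanol >= 0, n_water + n_ethanol >= 1)
  if (is.null(box)) box <- (110 * (n_water + n_ethanol))^(1 / 3)
  structure(list(n_water = n_water, n_ethanol = n_ethanol, box = box,
                 seed = seed, noise_scale = noise_scale,
                 branch_offset_range = branch_offset_range),
            class = "fixture_spec")
}

#' Generate a packed water/ethanol frame
#'
#' Rigid idealized molecules are placed at random positions and orientations by
#' rejection sampling: a placement is accepted when every heavy-atom pair
#' across molecules is at least 2.2 Å apart (minimum image). Molecules are kept
#' whole (not wrapped), so the point-charge polarization of the frame is a
#' smooth function of the coordinates.
#'
#' @param spec a [fixture_spec()].
#' @param max_attempts total placement attempts before giving up.
#' @return a [frame()] with bonds set.
#' @export
make_mixture_frame <- function(spec, max_attempts = 10000) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    cl <- cell(diag(3) * spec$box)
    templates <- c(replicate(spec$n_water, .water_template(), simplify = FALSE),
                   replicate(spec$n_ethanol, .ethanol_template(), simplify = FALSE))
    species <- character(0); positions <- NULL; bonds <- NULL
    heavy <- NULL
    attempts <- 0
    for (tpl in templates) {
      placed <- FALSE
      while (!placed) {
        attempts <- attempts + 1
        if (attempts > max_attempts) {
          stop("packing failed after ", max_attempts,
               " attempts; increase `box`", call. = FALSE)
        }
        R <- random_rotation()
        center <- stats::runif(3, 0, spec$box)
        pos <- sweep(tpl$positions %*% t(R), 2, center, "+")
        hv <- pos[tpl$species != "H", , drop = FALSE]
        ok <- is.null(heavy) || min(pair_distances(hv, heavy, cl)) >= 2.2
        if (ok) {
          offset <- length(species)
          species <- c(species, tpl$species)
          positions <- rbind(positions, pos)
          bonds <- rbind(bonds, tpl$bonds + offset)
          heavy <- rbind(heavy, hv)
          placed <- TRUE
        }
      }
    }
    frame(species, positions, cl, bonds = bonds)
  })
}

# --- Wannier-center construction sites --------------------------------------

# noiseless construction sites for one frame: 4 centers per O (2 bond, 2 lone
# pair), 4 per methyl C (3 C-H + the C-C center), 2 per CH2 carbon.
# Bond centers sit nearer the heavy atom than the bond midpoint so that
# nearest-atom assignment reproduces the expected counts at zero noise.
.wannier_sites <- function(frame) {
  bonds <- frame_bonds(frame)
  sp <- frame$species
  pos <- frame$positions
  neigh <- function(i) {
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  }
  sites <- NULL
  for (i in which(sp == "O")) {
    nb <- neigh(i)
    bvec <- lapply(nb, function(j) unitv(pos[j, ] - pos[i, ]))
    # two bond centers, 0.4 A (O-H) / 0.45 A (O-C) from the oxygen
    for (k in seq_along(nb)) {
      d0 <- if (sp[nb[k]] == "C") 0.45 else 0.40
      sites <- rbind(sites, pos[i, ] + d0 * bvec[[k]])
    }
    # two lone pairs on the opposite side, out of the bond plane
    u <- unitv(-(bvec[[1]] + bvec[[2]]))
    w <- unitv(pracma_cross(bvec[[1]], bvec[[2]]))
    half <- .tet / 2
    sites <- rbind(sites,
                   pos[i, ] + 0.30 * unitv(cos(half) * u + sin(half) * w),
                   pos[i, ] + 0.30 * unitv(cos(half) * u - sin(half) * w))
  }
  for (i in which(sp == "C")) {
    nb <- neigh(i)
    hyd <- nb[sp[nb] == "H"]
    for (j in hyd) sites <- rbind(sites, pos[i, ] + 0.45 * unitv(pos[j, ] - pos[i, ]))
    if (length(hyd) == 3) {       # methyl carbon also owns the C-C center
      cc <- nb[sp[nb] == "C"]
      sites <- rbind(sites, pos[i, ] + 0.60 * unitv(pos[cc, ] - pos[i, ]))
    }
  }
  sites
}

#' Place synthetic Wannier centers on a frame
#'
#' Centers are placed at idealized bond and lone-pair sites (4 per oxygen, 4
#' per methyl carbon, 2 per CH2 carbon), optionally jittered with isotropic
#' Gaussian noise. The default is noiseless: like their first-principles
#' counterparts, the centers are then a deterministic function of the
#' geometry; jitter exists to provoke assignment flips for miscount-repair
#' studies. The total number of centers equals half the valence-charge sum,
#' so the frame is charge-neutral with the default valences (O:6, C:4, H:1).
#'
#' @param frame a [frame()].
#' @param noise_scale Gaussian jitter, Å.
#' @param seed integer.
#' @return a [wannier_set()].
#' @export
make_wannier_centers <- function(frame, noise_scale = 0, seed = 1) {
  sites <- .wannier_sites(frame)
  withr::with_seed(seed, {
    jitter <- matrix(stats::rnorm(length(sites), sd = noise_scale), nrow(sites), 3)
    wannier_set(sites + jitter)
  })
}

# --- smooth polarization oracle ---------------------------------------------

# fixed oracle charges (units of e); arbitrary but smooth and molecule-neutral
.oracle_charges <- function(frame) {
  sp <- frame$species
  bonds <- frame_bonds(frame)
  mids <- molecule_ids(frame)
  q <- numeric(length(sp))
  info <- classify_molecules(frame)
  for (m in seq_len(nrow(info))) {
    idx <- which(mids == info$molecule[m])
    if (info$kind[m] == "water") {
      q[idx[sp[idx] == "O"]] <- -0.8
      q[idx[sp[idx] == "H"]] <- 0.4
    } else if (info$kind[m] == "ethanol") {
      o <- info$o_index[m]
      q[o] <- -0.70
      hydroxyl <- intersect(c(bonds[bonds[, 1] == o, 2], bonds[bonds[, 2] == o, 1]),
                            idx[sp[idx] == "H"])
      q[hydroxyl] <- 0.42
      q[info$beta_carbon[m]] <- -0.30
      alpha <- setdiff(idx[sp[idx] == "C"], info$beta_carbon[m])
      q[alpha] <- 0.28
      other_h <- setdiff(idx[sp[idx] == "H"], hydroxyl)
      q[other_h] <- 0.06
    } else {
      stop("oracle charges defined only for water and ethanol molecules", call. = FALSE)
    }
  }
  q
}

# smooth bond-dipole amplitudes by bonded pair (e.A at unit exp factor)
.bond_dipole_amp <- c(`O-H` = 0.15, `C-H` = 0.08, `C-C` = 0.05, `C-O` = 0.12, `O-C` = 0.12, `H-O` = 0.15, `H-C` = 0.08)

#' Smooth point-charge polarization oracle
#'
#' Ground-truth polarization for synthetic frames: a fixed point-charge sum
#' (each molecule neutral) plus a smooth exponential bond-dipole term. The
#' result is an infinitely differentiable, deterministic function of the
#' coordinates -- exactly the kind of single-branch data the learning and
#' unwrapping machinery assumes.
#'
#' @param frame a [frame()].
#' @param charge_scale multiplier on the oracle charges (controls how many
#'   quanta the polarization spans).
#' @return 3-vector, e·Å.
#' @export
smooth_polarization_oracle <- function(frame, charge_scale = 1) {
  q <- .oracle_charges(frame) * charge_scale
  P <- colSums(frame$positions * q)
  bonds <- frame_bonds(frame)
  rank <- c(O = 1, C = 2, H = 3)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (rank[frame$species[i]] > rank[frame$species[j]]) { tmp <- i; i <- j; j <- tmp }
    b <- frame$positions[j, ] - frame$positions[i, ]
    key <- paste0(frame$species[i], "-", frame$species[j])
    P <- P + charge_scale * .bond_dipole_amp[[key]] * exp(-sqrt(sum(b^2))) * b
  }
  unname(P)
}

#' Scatter smooth polarizations onto random branches
#'
#' Emulates raw periodic polarization data whose points are recorded on
#' arbitrary branches: each smooth polarization is reduced to the first branch
#' and then shifted by a uniform random integer 3-vector in
#' `[-offset_range, offset_range]`. The returned ground-truth offsets are the
#' integer corrections that bring each point back onto the original smooth
#' branch; a branch-unwrapping run can recover them only up to a common
#' integer (the global branch gauge).
#'
#' @param P N x 3 matrix of smooth polarizations, e·Å.
#' @param Q a [quantum_matrix()].
#' @param seed integer.
#' @param offset_range integer >= 1.
#' @return list with `p` (N x 3 matrix of branch-scattered reduced
#'   polarizations), `true_offsets` (N x 3 integer matrix), and `p_smooth`
#'   (N x 3, the smooth-branch reduced polarizations `Q^-1 P`).
#' @export
wrap_with_random_branches <- function(P, Q, seed = 1, offset_range = 2) {
  stopifnot(offset_range >= 1)
  P <- rbind_vec3(P, "P")
  red <- reduce_polarization(P, Q)
  p0 <- as.matrix(red[, c("px", "py", "pz")])
  n0 <- as.matrix(red[, c("nx", "ny", "nz")])
  withr::with_seed(seed, {
    m <- matrix(sample(seq(-offset_range, offset_range), 3 * nrow(P), replace = TRUE),
                nrow(P), 3)
  })
  list(p = unname(p0 + m),
       true_offsets = unname(n0 - m),
       p_smooth = unname(p0 + n0))
}

#' Harmonic dipole trajectory with known lines
#'
#' Sum of cosines at the requested wavenumbers with random phases per line and
#' Cartesian component, plus optional white noise; the analytic line positions
#' make this the reference fixture for spectrum tests.
#'
#' @param lines data frame (or 2-column matrix) with columns
#'   `wavenumber` (cm^-1) and `amplitude`.
#' @param dt time step, fs.
#' @param n_steps number of samples.
#' @param noise white-noise standard deviation.
#' @param seed integer.
#' @return a [dipole_trajectory()].
#' @export
harmonic_dipole_trajectory <- function(lines, dt = 0.5, n_steps = 4096,
                                       noise = 0, seed = 1) {
  lines <- as.data.frame(lines)
  if (!all(c("wavenumber", "amplitude") %in% names(lines))) {
    names(lines)[1:2] <- c("wavenumber", "amplitude")
  }
  nyq <- 1 / (2 * dt * .c_cm_fs)
  if (any(lines$wavenumber >= nyq)) {
    stop(sprintf("line above the Nyquist wavenumber (%.0f cm^-1) for dt = %g fs", nyq, dt),
         call. = FALSE)
  }
  t <- (seq_len(n_steps) - 1) * dt
  withr::with_seed(seed, {
    P <- matrix(0, n_steps, 3)
    for (k in seq_len(nrow(lines))) {
      phases <- stats::runif(3, 0, 2 * pi)
      for (a in 1:3) {
        P[, a] <- P[, a] + lines$amplitude[k] *
          cos(2 * pi * .c_cm_fs * lines$wavenumber[k] * t + phases[a])
      }
    }
    if (noise > 0) P <- P + matrix(stats::rnorm(3 * n_steps, sd = noise), n_steps, 3)
  })
  dipole_trajectory(times = t, P = P)
}
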