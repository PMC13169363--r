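# Atom-centered descriptors for covariant kernel regression.
#
# Each atomic environment is expanded on a Gaussian radial basis per neighbour
# species. Two channels are built:
#   * an invariant channel: the rotationally invariant power spectrum
#     p_{s,n,l} = sum_m |c_{s,n,l,m}|^2 of real-spherical-harmonic
#     coefficients up to l_max -- this feeds the scalar part of the kernel
#     (raised to zeta);
#   * a covariant (lambda = 1) channel: the l = 1 vector coefficients
#     v_{s,n} = sum_j g_n(d_j) r_hat_j, augmented with products
#     v_{s,n} (x) c_{s',n'} against the l = 0 coefficients (power-spectrum
#     order). These transform exactly like vectors under rotation, which is
#     what makes kernel predictions of 3-vectors exactly equivariant.

#' Descriptor configuration
#'
#' @param radial_cutoff environment cutoff, Å.
#' @param n_radial number of Gaussian radial basis functions.
#' @param l_max maximum angular channel of the invariant power spectrum
#'   (0--4).
#' @param gaussian_width width of the radial Gaussians, Å.
#' @param species_list element symbols the model accepts; inferred from the
#'   training frames when NULL.
#' @return a `descriptor_config`.
#' @export
descriptor_config <- function(radial_cutoff = 4.0, n_radial = 6, l_max = 4,
                              gaussian_width = 0.3, species_list = NULL) {
  stopifnot(radial_cutoff > 0, n_radial >= 1, l_max >= 1, l_max <= 4,
            gaussian_width > 0)
  structure(list(radial_cutoff = radial_cutoff, n_radial = as.integer(n_radial),
                 l_max = as.integer(l_max), gaussian_width = gaussian_width,
                 species_list = species_list),
            class = "descriptor_config")
}

# real spherical harmonics (orthonormal) evaluated on unit vectors; rows of
# `u` are unit vectors; returns matrix with sum_l (2l+1) columns up to l_max
real_sph_harm <- function(u, l_max) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  out <- matrix(0.5 / sqrt(pi), nrow(u), 1)                     # l = 0
  if (l_max >= 1) {
    c1 <- sqrt(3 / (4 * pi))
    out <- cbind(out, c1 * y, c1 * z, c1 * x)
  }
  if (l_max >= 2) {
    out <- cbind(out,
      0.5 * sqrt(15 / pi) * x * y,
      0.5 * sqrt(15 / pi) * y * z,
      0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
      0.5 * sqrt(15 / pi) * x * z,
      0.25 * sqrt(15 / pi) * (x^2 - y^2))
  }
  if (l_max >= 3) {
    out <- cbind(out,
      0.25 * sqrt(35 / (2 * pi)) * y * (3 * x^2 - y^2),
      0.5 * sqrt(105 / pi) * x * y * z,
      0.25 * sqrt(21 / (2 * pi)) * y * (5 * z^2 - 1),
      0.25 * sqrt(7 / pi) * (5 * z^3 - 3 * z),
      0.25 * sqrt(21 / (2 * pi)) * x * (5 * z^2 - 1),
      0.25 * sqrt(105 / pi) * z * (x^2 - y^2),
      0.25 * sqrt(35 / (2 * pi)) * x * (x^2 - 3 * y^2))
  }
  if (l_max >= 4) {
    out <- cbind(out,
      0.75 * sqrt(35 / pi) * x * y * (x^2 - y^2),
      0.75 * sqrt(35 / (2 * pi)) * y * z * (3 * x^2 - y^2),
      0.75 * sqrt(5 / pi) * x * y * (7 * z^2 - 1),
      0.75 * sqrt(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
      (3 / 16) / sqrt(pi) * (35 * z^4 - 30 * z^2 + 3),
      0.75 * sqrt(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
      (3 / 8) * sqrt(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
      0.75 * sqrt(35 / (2 * pi)) * x * z * (x^2 - 3 * y^2),
      (3 / 16) * sqrt(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4))
  }
  out
}

# featurize all atoms of a list of frames.
# Returns list(Fx, Fy, Fz: N x M covariant features; Phi: N x K normalized
# invariants; frame_id, species, config)
featurize_frames <- function(frames, config) {
  if (inherits(frames, "frame")) frames <- list(frames)
  if (is.null(config$species_list)) {
    config$species_list <- sort(unique(unlist(lapply(frames, `[[`, "species"))))
  }
  sp_list <- config$species_list
  nr <- config$n_radial
  rc <- config$radial_cutoff
  mu <- seq(0.5, rc, length.out = nr)
  sig <- config$gaussian_width
  nch <- length(sp_list) * nr                  # (species, radial) channels
  n_lm <- sum(2 * (0:config$l_max) + 1)
  l_index <- rep(0:config$l_max, times = 2 * (0:config$l_max) + 1)

  n_tot <- sum(vapply(frames, n_atoms, integer(1)))
  M <- nch + nch * nch                          # v plus v (x) c products
  Fx <- matrix(0, n_tot, M); Fy <- matrix(0, n_tot, M); Fz <- matrix(0, n_tot, M)
  Phi <- matrix(0, n_tot, nch * (config$l_max + 1))
  frame_id <- integer(n_tot); species <- character(n_tot)

  row <- 0L
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    bad <- setdiff(unique(fr$species), sp_list)
    if (length(bad) > 0) {
      stop("species outside the model's species list: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (rc > min_half_width(fr$cell) + 1e-9) {
      stop(sprintf(
        "radial_cutoff %.2f exceeds half the smallest cell width (%.2f A)",
        rc, min_half_width(fr$cell)), call. = FALSE)
    }
    na <- n_atoms(fr)
    # all minimum-image displacements and distances at once
    L <- unclass(fr$cell); Linv <- solve(L)
    fpos <- fr$positions %*% Linv
    for (i in seq_len(na)) {
      row <- row + 1L
      frame_id[row] <- fi; species[row] <- fr$species[i]
      df <- fpos[-i, , drop = FALSE]
      df <- sweep(df, 2, fpos[i, ], "-")
      df <- df - round(df)
      dvec <- df %*% L
      d <- sqrt(rowSums(dvec^2))
      keep <- d <= rc & d > 1e-8
      if (!any(keep)) next
      dvec <- dvec[keep, , drop = FALSE]; d <- d[keep]
      spn <- fr$species[-i][keep]
      u <- dvec / d
      fcut <- 0.5 * (cos(pi * d / rc) + 1)
      g <- exp(-outer(d, mu, "-")^2 / (2 * sig^2)) * fcut   # nb x nr
      # channel matrix: nb x nch, species-blocked radial functions
      ch <- matrix(0, length(d), nch)
      for (s in seq_along(sp_list)) {
        rows_s <- spn == sp_list[s]
        if (any(rows_s)) ch[rows_s, ((s - 1) * nr + 1):(s * nr)] <- g[rows_s, , drop = FALSE]
      }
      Y <- real_sph_harm(u, config$l_max)
      coef <- crossprod(ch, Y)                  # nch x n_lm
      # invariant power spectrum p_{ch, l}
      p <- vapply(0:config$l_max, function(l) {
        rowSums(coef[, l_index == l, drop = FALSE]^2)
      }, numeric(nch))
      Phi[row, ] <- as.numeric(p)
      # covariant l = 1 vectors per channel (m ordering: y, z, x)
      vx <- coef[, 4]; vy <- coef[, 2]; vz <- coef[, 3]
      c0 <- coef[, 1]
      Fx[row, ] <- c(vx, as.numeric(outer(vx, c0)))
      Fy[row, ] <- c(vy, as.numeric(outer(vy, c0)))
      Fz[row, ] <- c(vz, as.numeric(outer(vz, c0)))
    }
  }
  nrm <- sqrt(rowSums(Phi^2))
  nrm[nrm == 0] <- 1
  list(Fx = Fx, Fy = Fy, Fz = Fz, Phi = Phi / nrm,
       frame_id = frame_id, species = species, config = config)
}

min_half_width <- function(cl) {
  L <- unclass(cl)
  v <- abs(det(L))
  # perpendicular widths of the cell
  widths <- vapply(1:3, function(k) {
    others <- L[-k, , drop = FALSE]
    cr <- pracma_cross(others[1, ], others[2, ])
    v / sqrt(sum(cr^2))
  }, numeric(1))
  min(widths) / 2
}

#' Covariant kernel between two atomic environments
#'
#' Evaluates the 3x3 lambda = 1 kernel block
#' `K(a, b) = (phi_a . phi_b)^(zeta - 1) * F_a F_b^T` between the environments
#' of single atoms. Rotating environment `a` by `R` maps the kernel to
#' `R K(a, b)` exactly; `K(a, a)` is symmetric positive semidefinite.
#'
#' @param env_a,env_b lists `list(frame, atom)` selecting one atom each.
#' @param config a [descriptor_config()]; its `species_list` must cover both
#'   frames.
#' @param zeta scalar kernel exponent (>= 1).
#' @return 3x3 matrix.
#' @export
covariant_kernel <- function(env_a, env_b, config = descriptor_config(), zeta = 2) {
  if (is.null(config$species_list)) {
    config$species_list <- sort(unique(c(env_a$frame$species, env_b$frame$species)))
  }
  fa <- featurize_frames(list(env_a$frame), config)
  fb <- featurize_frames(list(env_b$frame), config)
  ia <- env_a$atom; ib <- env_b$atom
  k0 <- sum(fa$Phi[ia, ] * fb$Phi[ib, ])^(zeta - 1)
  Fa <- rbind(fa$Fx[ia, ], fa$Fy[ia, ], fa$Fz[ia, ])
  Fb <- rbind(fb$Fx[ib, ], fb$Fy[ib, ], fb$Fz[ib, ])
  k0 * (Fa %*% t(Fb))
}
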