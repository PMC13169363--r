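# Hydrogen-bond structure of water-alcohol mixtures.
#
# Water-water and water-ethanol hydrogen bonds are counted with a geometric
# donor-H...acceptor criterion; the measured per-water participation is
# compared against an ideal-mixing baseline (linear in the ethanol mole
# fraction between the pure-water and equimolar endpoints), both globally and
# resolved by distance from the nearest ethanol methyl (beta) carbon. The
# latter profile is what distinguishes "first-shell structuring" (clathrate
# pictures) from structuring further out.

#' Geometric hydrogen-bond criterion
#'
#' @param max_OO_distance donor-acceptor oxygen distance cutoff, Å.
#' @param max_angle H-donor-O...acceptor-O angle cutoff, degrees.
#'   Defaults are the standard liquid-water convention (3.5 Å, 30 deg).
#' @export
hbond_criterion <- function(max_OO_distance = 3.5, max_angle = 30) {
  stopifnot(max_OO_distance > 0, max_angle > 0)
  structure(list(max_OO_distance = max_OO_distance, max_angle = max_angle),
            class = "hbond_criterion")
}

#' Find hydrogen bonds in a frame
#'
#' A donor O-H donates to an acceptor O when the O...O minimum-image distance
#' and the H-O(donor)...O(acceptor) angle satisfy the criterion. Each bond is
#' counted once.
#'
#' @param frame a [frame()].
#' @param criterion a [hbond_criterion()].
#' @return tibble: `donor_o`, `h`, `acceptor_o` atom indices plus geometry
#'   columns `d_oo` (Å) and `angle` (degrees).
#' @export
find_hydrogen_bonds <- function(frame, criterion = hbond_criterion()) {
  bonds <- frame_bonds(frame)
  sp <- frame$species
  o_idx <- which(sp == "O")
  if (length(o_idx) < 2) {
    return(tibble::tibble(donor_o = integer(), h = integer(),
                          acceptor_o = integer(), d_oo = numeric(), angle = numeric()))
  }
  # covalently bound O-H pairs are donor candidates
  oh <- rbind(bonds[sp[bonds[, 1]] == "O" & sp[bonds[, 2]] == "H", , drop = FALSE],
              bonds[sp[bonds[, 2]] == "O" & sp[bonds[, 1]] == "H", c(2, 1), drop = FALSE])
  d_oo <- pair_distances(frame$positions[o_idx, , drop = FALSE],
                         frame$positions[o_idx, , drop = FALSE], frame$cell)
  out <- list()
  for (k in seq_len(nrow(oh))) {
    don <- oh[k, 1]; h <- oh[k, 2]
    di <- match(don, o_idx)
    acc_cand <- o_idx[d_oo[di, ] <= criterion$max_OO_distance & o_idx != don]
    if (length(acc_cand) == 0) next
    v_oh <- min_image(frame$positions[don, ], frame$positions[h, ], frame$cell)
    v_oa <- min_image(frame$positions[don, , drop = FALSE][rep(1, length(acc_cand)), ],
                      frame$positions[acc_cand, , drop = FALSE], frame$cell)
    cosang <- (v_oa %*% t(v_oh)) /
      (sqrt(rowSums(v_oa^2)) * sqrt(sum(v_oh^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang <= criterion$max_angle
    if (any(ok)) {
      out[[length(out) + 1]] <- tibble::tibble(
        donor_o = don, h = h, acceptor_o = acc_cand[ok],
        d_oo = d_oo[di, match(acc_cand[ok], o_idx)], angle = ang[ok])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(donor_o = integer(), h = integer(),
                          acceptor_o = integer(), d_oo = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Per-water hydrogen-bond participation
#'
#' @param frame a [frame()].
#' @param criterion a [hbond_criterion()].
#' @return tibble with one row per water molecule: `molecule`, `o_index`,
#'   `n_donor`, `n_acceptor`, `n_HB` (participation = donor + acceptor
#'   count).
#' @export
water_hbond_counts <- function(frame, criterion = hbond_criterion()) {
  hb <- find_hydrogen_bonds(frame, criterion)
  info <- classify_molecules(frame)
  wat <- info[info$kind == "water", ]
  tibble::tibble(
    molecule = wat$molecule,
    o_index = wat$o_index,
    n_donor = vapply(wat$o_index, function(o) sum(hb$donor_o == o), integer(1)),
    n_acceptor = vapply(wat$o_index, function(o) sum(hb$acceptor_o == o), integer(1))
  ) |> dplyr::mutate(n_HB = .data$n_donor + .data$n_acceptor)
}

#' Ideal-mixing hydrogen-bond baseline
#'
#' Linear interpolation of the mean per-water hydrogen-bond count between two
#' endpoint mole fractions; the excess is `delta = n_HB - n_HB_ideal`, exactly
#' zero at the endpoints by construction.
#'
#' @param n_HB measured mean H-bond participation at `x_e`.
#' @param x_e ethanol mole fraction(s).
#' @param endpoints list with `x` (length 2) and `n_HB` (length 2): the
#'   baseline anchor points.
#' @return tibble: `x_e`, `n_HB`, `n_HB_ideal`, `delta`.
#' @export
ideal_hbond_baseline <- function(n_HB, x_e,
                                 endpoints = list(x = c(0, 0.5), n_HB = c(3.430, 3.23))) {
  stopifnot(length(endpoints$x) == 2, length(endpoints$n_HB) == 2,
            endpoints$x[1] != endpoints$x[2], length(n_HB) == length(x_e))
  if (any(x_e < min(endpoints$x) | x_e > max(endpoints$x))) {
    warning("x_e outside the baseline endpoints: extrapolating", call. = FALSE)
  }
  slope <- diff(endpoints$n_HB) / diff(endpoints$x)
  ideal <- endpoints$n_HB[1] + slope * (x_e - endpoints$x[1])
  tibble::tibble(x_e = x_e, n_HB = n_HB, n_HB_ideal = ideal, delta = n_HB - ideal)
}

#' Radial distribution function
#'
#' Standard normalized pair distribution between two species over one or more
#' frames, with the first maximum and following first minimum located on a
#' moving-average smoothed curve.
#'
#' @param frames a [frame()] or list of frames.
#' @param species_pair length-2 character, e.g. `c("C", "O")`. For
#'   identical species, self-pairs are excluded.
#' @param r_max histogram range, Å; must not exceed half the smallest cell
#'   width.
#' @param n_bins number of bins.
#' @param smooth moving-average half-width (bins) used for extrema location.
#' @param indices optional list `list(a =, b =)` restricting each side to
#'   specific atom indices (applied per frame).
#' @return a `rdf` tibble (`r`, `g`) with attributes `first_max`/`first_min`
#'   (Å, NA when not identifiable).
#' @export
radial_distribution <- function(frames, species_pair, r_max = NULL, n_bins = 100,
                                smooth = 2, indices = NULL) {
  if (inherits(frames, "frame")) frames <- list(frames)
  half <- min(vapply(frames, function(f) min_half_width(f$cell), numeric(1)))
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    stop(sprintf("r_max %.2f exceeds half the smallest cell width (%.2f A)", r_max, half),
         call. = FALSE)
  }
  edges <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  norm <- 0
  for (fr in frames) {
    ia <- which(fr$species == species_pair[1])
    ib <- which(fr$species == species_pair[2])
    if (!is.null(indices)) {
      if (!is.null(indices$a)) ia <- intersect(ia, indices$a)
      if (!is.null(indices$b)) ib <- intersect(ib, indices$b)
    }
    if (length(ia) == 0 || length(ib) == 0) next
    d <- pair_distances(fr$positions[ia, , drop = FALSE],
                        fr$positions[ib, , drop = FALSE], fr$cell)
    same <- identical(species_pair[1], species_pair[2]) && is.null(indices)
    dv <- as.numeric(d)
    if (same) dv <- dv[as.numeric(d) > 1e-9]   # drop self pairs
    dv <- dv[dv <= r_max & dv > 0]
    counts <- counts + graphics::hist(dv, breaks = edges, plot = FALSE)$counts
    # ideal-gas normalization: pairs per shell volume at the frame's density
    rho_pairs <- length(ia) * length(ib) / cell_volume(fr$cell)
    if (same) rho_pairs <- length(ia) * (length(ib) - 1) / cell_volume(fr$cell)
    norm <- norm + rho_pairs
  }
  vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (vol * norm)
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  gs <- stats::filter(g, rep(1 / (2 * smooth + 1), 2 * smooth + 1), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  ext <- locate_first_extrema(r_mid, as.numeric(gs))
  out <- tibble::tibble(r = r_mid, g = g)
  attr(out, "first_max") <- ext$first_max
  attr(out, "first_min") <- ext$first_min
  class(out) <- c("rdf", class(out))
  out
}

locate_first_extrema <- function(r, g) {
  n <- length(g)
  first_max <- NA_real_; first_min <- NA_real_
  i <- 2
  while (i < n) {
    if (g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] > 0.5) { first_max <- r[i]; break }
    i <- i + 1
  }
  if (!is.na(first_max)) {
    while (i < n) {
      if (g[i] < g[i - 1] && g[i] <= g[i + 1]) { first_min <- r[i]; break }
      i <- i + 1
    }
  }
  list(first_max = first_max, first_min = first_min)
}

#' First-hydration-shell membership of water molecules
#'
#' A water belongs to the first shell when its oxygen lies within
#' `shell_cutoff` (minimum image) of the nearest ethanol beta-carbon (the
#' methyl carbon, i.e. the ethanol carbon not bonded to oxygen).
#'
#' @param frame a [frame()].
#' @param shell_cutoff Å; typically the first minimum of the beta-C--O(water)
#'   radial distribution function.
#' @return tibble: one row per molecule with `molecule`, `kind`,
#'   `dist_beta` (Å, NA for non-water) and `first_shell` (logical; FALSE with
#'   a warning for every water when the frame has no ethanol).
#' @export
first_shell_membership <- function(frame, shell_cutoff) {
  info <- classify_molecules(frame)
  beta <- info$beta_carbon[info$kind == "ethanol"]
  wat <- info$kind == "water"
  dist_beta <- rep(NA_real_, nrow(info))
  if (length(beta) == 0) {
    if (any(wat)) warning("frame contains no ethanol; all waters marked outside the first shell",
                          call. = FALSE)
    fs <- rep(NA, nrow(info)); fs[wat] <- FALSE
  } else {
    d <- pair_distances(frame$positions[info$o_index[wat], , drop = FALSE],
                        frame$positions[beta, , drop = FALSE], frame$cell)
    dist_beta[wat] <- apply(d, 1, min)
    fs <- rep(NA, nrow(info))
    fs[wat] <- dist_beta[wat] <= shell_cutoff
  }
  dplyr::mutate(info, dist_beta = dist_beta, first_shell = fs)
}

#' Excess hydrogen-bond density versus distance from ethanol
#'
#' For each water molecule the H-bond participation excess over the ideal
#' baseline is accumulated in bins of the distance from its oxygen to the
#' nearest ethanol beta-carbon, normalized per shell volume and per frame.
#'
#' @param frames a [frame()] or list of frames.
#' @param bins numeric vector of bin edges, Å (within half the cell width).
#' @param baseline_n_HB ideal per-water H-bond count at this composition
#'   (from [ideal_hbond_baseline()]).
#' @param criterion a [hbond_criterion()].
#' @return tibble: `r_lo`, `r_hi`, `r_mid`, `n_waters`, `delta_rho`
#'   (excess H-bonds per Å^3; NA for empty bins).
#' @export
excess_hbond_density <- function(frames, bins, baseline_n_HB,
                                 criterion = hbond_criterion()) {
  if (inherits(frames, "frame")) frames <- list(frames)
  half <- min(vapply(frames, function(f) min_half_width(f$cell), numeric(1)))
  if (max(bins) > half + 1e-9) {
    stop("bins extend beyond half the smallest cell width", call. = FALSE)
  }
  nb <- length(bins) - 1
  excess <- numeric(nb); nwat <- integer(nb)
  for (fr in frames) {
    cnt <- water_hbond_counts(fr, criterion)
    shells <- first_shell_membership(fr, shell_cutoff = Inf)
    d <- shells$dist_beta[match(cnt$molecule, shells$molecule)]
    if (all(is.na(d))) stop("frames contain no ethanol: no reference carbon", call. = FALSE)
    bin <- findInterval(d, bins, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb & !is.na(bin)
    for (k in which(ok)) {
      excess[bin[k]] <- excess[bin[k]] + (cnt$n_HB[k] - baseline_n_HB)
      nwat[bin[k]] <- nwat[bin[k]] + 1L
    }
  }
  vol <- 4 / 3 * pi * diff(bins^3)
  delta_rho <- excess / (vol * length(frames))
  delta_rho[nwat == 0] <- NA_real_
  tibble::tibble(r_lo = bins[-length(bins)], r_hi = bins[-1],
                 r_mid = (bins[-1] + bins[-length(bins)]) / 2,
                 n_waters = nwat, delta_rho = delta_rho)
}
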