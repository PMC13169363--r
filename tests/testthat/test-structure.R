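# Hydrogen-bond counting, ideal-mixing baseline, RDF, shells.

make_dimer <- function(d_oo = 2.9, tilt_deg = 5) {
  # donor water with one O-H pointing along +x toward the acceptor oxygen
  cl <- cell(diag(3) * 25)
  tilt <- tilt_deg * pi / 180
  donor <- rbind(c(0, 0, 0),
                 0.96 * c(cos(tilt), sin(tilt), 0),
                 0.96 * c(cos(104.5 * pi / 180), -sin(104.5 * pi / 180), 0))
  half <- 104.5 / 2 * pi / 180
  acceptor <- sweep(rbind(c(0, 0, 0),
                          0.96 * c(cos(half), sin(half), 0),
                          0.96 * c(cos(half), -sin(half), 0)),
                    2, c(d_oo, 0, 3), "+")
  acceptor[, 3] <- acceptor[, 3] - 3
  frame(rep(c("O", "H", "H"), 2), rbind(donor, acceptor) + 10, cl)
}

test_that("the geometric criterion accepts and rejects dimers correctly", {
  hb <- find_hydrogen_bonds(make_dimer(2.9, 5))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_o, 1); expect_equal(hb$acceptor_o, 4)
  expect_equal(nrow(find_hydrogen_bonds(make_dimer(4.0, 5))), 0)
  expect_equal(nrow(find_hydrogen_bonds(make_dimer(2.9, 40))), 0)
  # participation: both waters count the one shared bond
  cnt <- water_hbond_counts(make_dimer(2.9, 5))
  expect_equal(cnt$n_HB, c(1L, 1L))
})

test_that("total bond count equals half the summed participations", {
  frames <- lapply(1:4, function(k) make_mixture_frame(fixture_spec(10, 0, box = 10.3, seed = 700 + k)))
  for (fr in frames) {
    hb <- find_hydrogen_bonds(fr)
    cnt <- water_hbond_counts(fr)
    expect_equal(sum(cnt$n_HB), 2 * nrow(hb))
  }
})

test_that("the ideal-mixing baseline reproduces the excess H-bond numbers", {
  # endpoints: pure water 3.430, equimolar 3.23
  tab <- ideal_hbond_baseline(c(3.430, 3.421, 3.37, 3.23),
                              c(0, 0.125, 0.250, 0.5))
  expect_equal(tab$delta[1], 0)
  expect_equal(tab$delta[4], 0)
  expect_equal(round(tab$delta[2], 3), 0.041)
  expect_equal(round(tab$delta[3], 2), 0.04)
  expect_warning(ideal_hbond_baseline(3.4, 0.7), "extrapolating")
})

test_that("radial distributions are normalized with located extrema", {
  set.seed(3)
  frames <- lapply(1:30, function(k)
    frame(rep("O", 25), matrix(runif(75, 0, 14), 25, 3), cell(diag(3) * 14)))
  g <- radial_distribution(frames, c("O", "O"), r_max = 6.5, n_bins = 40)
  expect_lt(abs(mean(g$g[g$r > 3.5]) - 1), 0.1)
  # a single fixed pair in a dilute box: one sharp peak at the pair distance
  fr <- frame(c("C", "O"), rbind(c(6, 10, 10), c(9, 10, 10)), cell(diag(3) * 20))
  g2 <- radial_distribution(fr, c("C", "O"), r_max = 9, n_bins = 60)
  expect_equal(g2$r[which.max(g2$g)], 3.0, tolerance = 0.1)
  # synthetic two-shell arrangement around a central atom
  set.seed(9)
  shell_pts <- function(r, n) {
    u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
    sweep(r * u, 2, rep(10, 3), "+")
  }
  fr3 <- frame(c("C", rep("O", 60)),
               rbind(c(10, 10, 10), shell_pts(2.8, 30), shell_pts(5.2, 30)),
               cell(diag(3) * 20))
  g3 <- radial_distribution(fr3, c("C", "O"), r_max = 7, n_bins = 56)
  expect_lt(abs(attr(g3, "first_max") - 2.8), 0.4)
  expect_gt(attr(g3, "first_min"), 3.0)
  expect_lt(attr(g3, "first_min"), 5.0)
  expect_error(radial_distribution(fr3, c("C", "O"), r_max = 12), "half the smallest")
})

test_that("first-shell membership partitions the waters", {
  fr <- make_mixture_frame(fixture_spec(6, 1, seed = 9))
  fs <- first_shell_membership(fr, shell_cutoff = 5)
  wat <- fs$kind == "water"
  expect_true(all(!is.na(fs$first_shell[wat])))
  expect_equal(sum(fs$first_shell[wat]) + sum(!fs$first_shell[wat]), sum(wat))
  expect_true(all((fs$dist_beta[wat] <= 5) == fs$first_shell[wat]))
  # explicit distances: 3 A is inside a 5 A shell, 6 A is not
  cl <- cell(diag(3) * 30)
  eth <- make_mixture_frame(fixture_spec(0, 1, box = 30, seed = 1))
  beta <- classify_molecules(eth)$beta_carbon[1]
  w <- water_frame(30)
  near <- sweep(w$positions, 2, eth$positions[beta, ] + c(3, 0, 0) - w$positions[1, ], "+")
  far <- sweep(w$positions, 2, eth$positions[beta, ] + c(0, 6, 0) - w$positions[1, ], "+")
  fr2 <- frame(c(eth$species, rep(c("O", "H", "H"), 2)),
               rbind(eth$positions, near, far), cl)
  fs2 <- first_shell_membership(fr2, shell_cutoff = 5)
  expect_equal(fs2$first_shell[fs2$kind == "water"], c(TRUE, FALSE))
  # a pure-water frame has no shell at all
  wonly <- make_mixture_frame(fixture_spec(4, 0, seed = 2))
  expect_warning(fs3 <- first_shell_membership(wonly, 5), "no ethanol")
  expect_true(all(fs3$first_shell[fs3$kind == "water"] == FALSE))
})

test_that("excess H-bond density resolves depletion near ethanol", {
  # hand-built frame: ethanol with two isolated waters at ~3 A from the
  # beta-carbon and a hydrogen-bonded water pair ~7.5 A away, all placed on
  # the methyl side so nothing fuses with the ethanol
  cl <- cell(diag(3) * 26)
  eth <- make_mixture_frame(fixture_spec(0, 1, box = 26, seed = 5))
  info_e <- classify_molecules(eth)
  beta <- info_e$beta_carbon[1]
  alpha <- setdiff(which(eth$species == "C"), beta)
  b <- eth$positions[beta, ]
  away <- (b - eth$positions[alpha, ]) / sqrt(sum((b - eth$positions[alpha, ])^2))
  perp <- c(-away[2], away[1], 0); perp <- perp / sqrt(sum(perp^2))
  half <- 104.5 / 2 * pi / 180
  w <- rbind(c(0, 0, 0), 0.96 * c(cos(half), sin(half), 0),
             0.96 * c(cos(half), -sin(half), 0))
  place <- function(offset) sweep(w, 2, b + offset, "+")
  dimer <- make_dimer(2.9, 5)
  dimer_pos <- sweep(dimer$positions, 2, dimer$positions[1, ], "-")
  species <- c(eth$species, c("O", "H", "H"), dimer$species)
  pos <- rbind(eth$positions, place(3 * away),
               sweep(dimer_pos, 2, b + 7.5 * away, "+"))
  fr <- frame(species, pos, cl)
  expect_equal(sum(classify_molecules(fr)$kind == "water"), 3)
  # against a baseline of 0.5 bonds per water: the lone first-shell water
  # (0 bonds) is depleted, the far dimer (1 bond each) enhanced
  prof <- excess_hbond_density(list(fr), bins = c(0, 2, 4, 6, 9),
                               baseline_n_HB = 0.5)
  expect_lt(prof$delta_rho[prof$r_lo == 2], 0)
  expect_gt(prof$delta_rho[prof$r_lo == 6], 0)
  # empty bins are missing values, not zeros
  expect_true(is.na(prof$delta_rho[1]))
  expect_equal(sum(prof$n_waters), 3)
})
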