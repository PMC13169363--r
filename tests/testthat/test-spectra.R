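# IR spectra: line recovery, omega^2 weighting, decomposition closure, peaks.

test_that("constant polarization gives a dark spectrum", {
  tr <- dipole_trajectory((0:63) * 0.5, matrix(1.3, 64, 3))
  sp <- ir_spectrum(tr)
  expect_lt(max(sp$intensity), 1e-20)
  expect_true(all(diff(sp$wavenumber) > 0))
  expect_error(dipole_trajectory(c(0, 1, 2, 3.5, 4:7) , matrix(0, 8, 3)), "uniform")
})

test_that("single lines are recovered within one grid spacing", {
  tr <- harmonic_dipole_trajectory(data.frame(wavenumber = 1500, amplitude = 1),
                                   dt = 0.5, n_steps = 2^14, seed = 2)
  sp <- ir_spectrum(tr)
  dg <- diff(sp$wavenumber[1:2])
  expect_lt(abs(peak_position(sp, c(1200, 1800)) - 1500), dg)
  expect_true(all(sp$intensity >= 0))
  # intensity scales quadratically with the signal amplitude
  tr2 <- tr; tr2$P <- 3 * tr$P
  expect_equal(ir_spectrum(tr2)$intensity, 9 * sp$intensity, tolerance = 1e-10)
})

test_that("the omega^2 factor enhances the higher-frequency line", {
  tr <- harmonic_dipole_trajectory(data.frame(wavenumber = c(1650, 3060),
                                              amplitude = c(1, 1)),
                                   dt = 0.5, n_steps = 2^14, seed = 3)
  sp <- ir_spectrum(tr)
  dg <- diff(sp$wavenumber[1:2])
  expect_lt(abs(peak_position(sp, c(1400, 1900)) - 1650), dg)
  expect_lt(abs(peak_position(sp, c(2800, 3300)) - 3060), dg)
  h_low <- max(sp$intensity[sp$wavenumber > 1400 & sp$wavenumber < 1900])
  h_high <- max(sp$intensity[sp$wavenumber > 2800 & sp$wavenumber < 3300])
  expect_equal(h_high / h_low, (3060 / 1650)^2, tolerance = 0.1)
})

test_that("shell decomposition closes exactly and behaves symmetrically", {
  t_ <- (0:2047) * 0.5
  P1 <- harmonic_dipole_trajectory(data.frame(wavenumber = 1650, amplitude = 1),
                                   n_steps = 2048, seed = 4)$P
  P2 <- harmonic_dipole_trajectory(data.frame(wavenumber = 3060, amplitude = 1),
                                   n_steps = 2048, seed = 5)$P
  tr <- dipole_trajectory(t_, P1 + P2, P1 = P1, P2 = P2)
  d <- decomposed_spectra(tr)
  expect_lt(max(abs(d$I1 + d$I2 + d$Ic - d$intensity)) / max(d$intensity), 1e-8)
  expect_equal(d$intensity, ir_spectrum(tr)$intensity, tolerance = 1e-12)
  # independent lines: the cross term is dark away from both lines
  mid <- d$wavenumber > 2100 & d$wavenumber < 2700
  expect_lt(max(abs(d$Ic[mid])) / max(d$intensity), 1e-6)
  # P2 = 0: everything is I1
  tr0 <- dipole_trajectory(t_, P1, P1 = P1, P2 = 0 * P1)
  d0 <- decomposed_spectra(tr0)
  expect_equal(d0$I1, d0$intensity, tolerance = 1e-12)
  expect_lt(max(abs(d0$Ic)), 1e-20)
  # P1 = P2: equal halves plus a doubled cross term
  tr_eq <- dipole_trajectory(t_, 2 * P1, P1 = P1, P2 = P1)
  deq <- decomposed_spectra(tr_eq)
  expect_equal(deq$I1, deq$I2, tolerance = 1e-12)
  expect_equal(deq$Ic, 2 * deq$I1, tolerance = 1e-10)
  # component trajectories must reproduce the stored total
  expect_error(dipole_trajectory(t_, P1, P1 = P1, P2 = P1), "reproduce")
})

test_that("per-atom dipoles split by shell membership", {
  fr <- make_mixture_frame(fixture_spec(3, 1, seed = 61))
  set.seed(8)
  per_atom <- matrix(rnorm(n_atoms(fr) * 3, sd = 0.2), n_atoms(fr), 3)
  decomp <- atomic_dipole_decomposition(per_atom)
  info <- classify_molecules(fr)
  all_first <- ifelse(info$kind == "water", TRUE, NA)
  d_all <- decompose_polarization(decomp, fr, all_first)
  expect_equal(d_all$P2, c(0, 0, 0))
  d_none <- decompose_polarization(decomp, fr, ifelse(info$kind == "water", FALSE, NA))
  expect_equal(d_none$P1, c(0, 0, 0))
  expect_equal(d_all$P1, d_none$P2, tolerance = 1e-12)
  expect_equal(d_all$P1 + d_all$P_other, decomp$total - d_all$P2, tolerance = 1e-12)
  expect_error(decompose_polarization(decomp, fr, rep(NA, nrow(info))), "unflagged")
})

test_that("peak location is refined, windowed and guarded", {
  tr <- harmonic_dipole_trajectory(data.frame(wavenumber = 1660, amplitude = 1),
                                   dt = 0.5, n_steps = 2^13, seed = 6)
  sp <- ir_spectrum(tr)
  dg <- diff(sp$wavenumber[1:2])
  expect_lt(abs(peak_position(sp, c(1400, 1900)) - 1660), dg / 2 + 1e-9)
  tr2 <- harmonic_dipole_trajectory(data.frame(wavenumber = c(1660, 3000),
                                               amplitude = c(1, 1)),
                                    dt = 0.5, n_steps = 2^13, seed = 7)
  sp2 <- ir_spectrum(tr2)
  expect_lt(abs(peak_position(sp2, c(1400, 1900)) - 1660), dg)
  flat <- sp; flat$intensity <- rep(1, nrow(flat))
  expect_error(peak_position(flat, c(1400, 1900)), "no peak")
  expect_error(peak_position(sp, c(1500, 1500.1)), "fewer than 3")
})

test_that("peak shifts are reported relative to the reference concentration", {
  mk <- function(nu) ir_spectrum(harmonic_dipole_trajectory(
    data.frame(wavenumber = nu, amplitude = 1), dt = 0.5, n_steps = 2^13, seed = 8))
  ve <- c(0, 0.2, 0.4, 0.8)
  shifts_true <- 5 * ve / 0.8
  spectra <- stats::setNames(lapply(1660 + 3.4 * shifts_true, mk), ve)
  out <- peak_shift_series(spectra, c(1500, 1900), reference = 0)
  expect_equal(out$shift[1], 0)
  fit <- stats::coef(stats::lm(out$shift ~ shifts_true))
  expect_equal(unname(fit[2]), 3.4, tolerance = 0.05)
  out8 <- peak_shift_series(spectra, c(1500, 1900), reference = 0.8)
  expect_equal(out8$shift[out8$concentration == 0.8], 0)
  same <- stats::setNames(lapply(c(1660, 1660), function(x) mk(x)), c(0, 0.5))
  expect_true(all(peak_shift_series(same, c(1500, 1900), 0)$shift == 0))
  expect_error(peak_shift_series(spectra, c(1500, 1900), reference = 0.3),
               "reference")
})
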