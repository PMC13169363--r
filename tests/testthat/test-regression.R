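# Covariant kernel regression: kernel contracts, model quality, symmetries.

test_that("covariant kernel is Gram-like and rotates covariantly", {
  fr <- make_mixture_frame(fixture_spec(3, 0, box = 9, seed = 21))
  cfg <- descriptor_config(species_list = c("H", "O"))
  K_aa <- covariant_kernel(list(frame = fr, atom = 1), list(frame = fr, atom = 1), cfg)
  expect_equal(K_aa, t(K_aa), tolerance = 1e-12)
  expect_true(all(eigen(K_aa, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  R <- rotation_z(pi / 2)
  fr_rot <- rotate_frame(fr, R)
  K_ab <- covariant_kernel(list(frame = fr, atom = 1), list(frame = fr, atom = 5), cfg)
  K_rot <- covariant_kernel(list(frame = fr_rot, atom = 1), list(frame = fr, atom = 5), cfg)
  expect_lt(max(abs(K_rot - R %*% K_ab)) / max(abs(K_ab)), 1e-8)
  expect_error(covariant_kernel(list(frame = fr, atom = 1), list(frame = fr, atom = 2),
                                descriptor_config(species_list = "O")),
               "species")
})

test_that("kernel between far-apart environments uses only local information", {
  # two identical waters, far beyond 2 x cutoff: moving one does not change
  # the kernel between their oxygens' environments
  half <- 104.5 / 2 * pi / 180
  w <- rbind(c(0, 0, 0), 0.96 * c(cos(half), sin(half), 0),
             0.96 * c(cos(half), -sin(half), 0))
  cl <- cell(diag(3) * 40)
  fr1 <- frame(rep(c("O", "H", "H"), 2), rbind(w + 5, w + 25), cl)
  fr2 <- frame(rep(c("O", "H", "H"), 2), rbind(w + 5, w + 30), cl)
  cfg <- descriptor_config(species_list = c("H", "O"))
  K1 <- covariant_kernel(list(frame = fr1, atom = 1), list(frame = fr1, atom = 4), cfg)
  K2 <- covariant_kernel(list(frame = fr2, atom = 1), list(frame = fr2, atom = 4), cfg)
  expect_equal(K1, K2, tolerance = 1e-10)
})

test_that("global polarization model interpolates, shrinks, and learns", {
  frames <- mix_frames(70)
  P <- oracle_P(frames)
  # two identical frames, identical targets: exact interpolation
  m0 <- train_polarization_model(frames[c(1, 1)], P[c(1, 1), ], regularization = 1e-12)
  expect_equal(predict_polarization(m0, frames[[1]])$total, P[1, ], tolerance = 1e-4)
  # all-zero targets: predictions vanish
  mz <- train_polarization_model(frames[1:10], matrix(0, 10, 3))
  expect_lt(max(abs(predict_polarization(mz, frames[[11]])$total)), 1e-8)
  # held-out accuracy: 50 training frames, 20 test frames, circular error
  m <- train_polarization_model(frames[1:50], P[1:50, ])
  Qi <- solve(unclass(quantum_matrix(frames[[1]]$cell)))
  pred <- predict_polarization(m, frames[51:70])
  ppred <- do.call(rbind, lapply(pred, `[[`, "total")) %*% t(Qi)
  expect_lt(von_mises_error(ppred, P[51:70, ] %*% t(Qi)), 0.01)
  # per-atom decomposition sums to the total
  expect_equal(colSums(pred[[1]]$per_atom), pred[[1]]$total, tolerance = 1e-12)
  expect_error(train_polarization_model(frames[1], P[1, , drop = FALSE]), "at least 2")
})

test_that("training error is monotone in the regularization", {
  frames <- mix_frames(70)[1:20]
  P <- oracle_P(frames)
  errs <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(reg) {
    m <- train_polarization_model(frames, P, regularization = reg)
    von_mises_error(m$fitted, m$targets)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("predictions are equivariant, translation and permutation invariant", {
  frames <- mix_frames(70)
  P <- oracle_P(frames)
  m <- train_polarization_model(frames[1:10], P[1:10, ])
  fr <- frames[[12]]
  pr <- predict_polarization(m, fr)
  scale <- max(abs(pr$per_atom))
  set.seed(31)
  for (k in 1:3) {
    R <- random_rotation_matrix()
    pr_rot <- predict_polarization(m, rotate_frame(fr, R))
    expect_lt(max(abs(pr_rot$per_atom - pr$per_atom %*% t(R))) / scale, 1e-6)
  }
  pr_tr <- predict_polarization(m, translate_frame(fr, c(1.7, -0.4, 3.3)))
  expect_lt(max(abs(pr_tr$per_atom - pr$per_atom)) / scale, 1e-8)
  perm <- c(7:9, 4:6, 1:3, 10:21)       # swap two waters, keep species pattern
  fr_p <- frame(fr$species[perm], fr$positions[perm, ], fr$cell)
  expect_equal(predict_polarization(m, fr_p)$total, pr$total, tolerance = 1e-10)
})

test_that("learning curves do not degrade as training data doubles", {
  Qi <- solve(unclass(quantum_matrix(mix_frames(70)[[1]]$cell)))
  med <- sapply(c(10, 20, 40), function(ntr) {
    vapply(1:5, function(s) {
      frames <- mix_frames(55, base_seed = 2000 + 71 * s)
      P <- oracle_P(frames)
      m <- train_polarization_model(frames[seq_len(ntr)], P[seq_len(ntr), ])
      pred <- predict_polarization(m, frames[41:55])
      ppred <- do.call(rbind, lapply(pred, `[[`, "total")) %*% t(Qi)
      von_mises_error(ppred, P[41:55, ] %*% t(Qi))
    }, numeric(1))
  })
  medians <- apply(med, 2, stats::median)
  expect_true(all(diff(medians) <= 0))
})

test_that("wannier displacement models recover per-atom targets", {
  frames <- mix_frames(70)[1:60]
  centers <- lapply(seq_along(frames), function(k) make_wannier_centers(frames[[k]]))
  deltas <- lapply(seq_along(frames), function(k)
    assign_nearest(frames[[k]], centers[[k]])$delta_sums)
  wm <- train_wannier_model(frames[1:50], deltas[1:50])
  dpred <- do.call(rbind, lapply(51:60, function(k)
    predict_wannier_displacements(wm, frames[[k]])))
  dtrue <- do.call(rbind, deltas[51:60])
  err <- mean(sqrt(rowSums((dpred - dtrue)^2)))
  expect_lt(err, 0.05 * mean(sqrt(rowSums(dtrue^2))))
  # hydrogens own no centers: their sub-model predicts (approximately) zero
  sp <- unlist(lapply(frames[51:60], `[[`, "species"))
  expect_lt(max(abs(dpred[sp == "H", ])), 1e-6)
  # a species with a single training environment is rejected
  one_w <- make_mixture_frame(fixture_spec(1, 0, box = 12, seed = 77))
  expect_error(train_wannier_model(list(one_w), list(matrix(0, 3, 3))), "environment")
})

test_that("models survive a serialization round trip", {
  frames <- mix_frames(70)[1:10]
  P <- oracle_P(frames)
  m <- train_polarization_model(frames[1:8], P[1:8, ])
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict_polarization(m2, frames[[9]])$total,
               predict_polarization(m, frames[[9]])$total, tolerance = 1e-10)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), bad)
  expect_error(read_model(bad), "version")
})
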