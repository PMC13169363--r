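# Data-driven branch unwrapping of periodic polarization data.
#
# Raw periodic polarizations come on arbitrary branches: two physically
# equivalent values may differ by an integer vector in reduced coordinates,
# which makes the dataset a multivalued (and unlearnable) function of the
# atomic positions. The cure is data driven and needs no auxiliary charge
# model:
#   1. train a rough probe model on a small random fraction of the data;
#   2. predict the remainder and look at the residual distribution per
#      Cartesian component: residuals of a usable probe cluster at integers
#      (multimodal -- the probe's training subset was branch-consistent),
#      while a probe poisoned by mixed branches produces a featureless smear
#      (unimodal -> resample and retry);
#   3. round the signed residuals to the nearest integer and shift each point
#      by that offset, which brings the whole dataset onto the probe's branch.
# Unimodality is judged with the Hartigan dip test.

#' Train a probe model and diagnose branch structure
#'
#' @param frames list of [frame()]s.
#' @param p_calc N x 3 matrix of reduced polarizations as recorded (arbitrary
#'   branches).
#' @param probe_fraction fraction of points used to train the probe model.
#' @param seed RNG seed (probe subset choice and dip bootstrap).
#' @param config descriptor configuration for the probe model.
#' @param regularization probe ridge parameter; deliberately heavy, the probe
#'   only has to resolve relative branches, not be accurate.
#' @param dip_threshold per-component p-value below which the residual
#'   distribution counts as multimodal.
#' @param n_boot dip bootstrap size.
#' @param zeta kernel exponent of the probe.
#' @return a `residual_diagnostics` list: `residuals` (N x 3 signed, probe
#'   rows included), `dip` tibble (component, dip, p_value), `verdict`
#'   (`"multimodal"`/`"unimodal"`), `probe_indices`, `max_abs_residual`.
#' @export
probe_and_diagnose <- function(frames, p_calc, probe_fraction = 0.05, seed = 1,
                               config = descriptor_config(),
                               regularization = 10, dip_threshold = 0.05,
                               n_boot = 1000, zeta = 2) {
  p_calc <- rbind_vec3(p_calc, "p_calc")
  n <- length(frames)
  stopifnot(nrow(p_calc) == n)
  if (probe_fraction <= 0 || probe_fraction >= 1) {
    stop("probe_fraction must be in (0, 1)", call. = FALSE)
  }
  n_probe <- max(2L, as.integer(round(probe_fraction * n)))
  if (n_probe >= n) stop("not enough frames for a probe split", call. = FALSE)
  probe_idx <- withr::with_seed(seed, sample.int(n, n_probe))
  model <- train_polarization_model(frames[probe_idx],
                                    p_calc[probe_idx, , drop = FALSE],
                                    config = config,
                                    regularization = regularization, zeta = zeta)
  preds <- predict_polarization(model, frames)
  p_pred <- do.call(rbind, lapply(preds, `[[`, "total"))
  residuals <- p_pred - p_calc
  rest <- setdiff(seq_len(n), probe_idx)
  dip <- purrr::map_dfr(1:3, function(a) {
    h <- hartigan_dip(residuals[rest, a], n_boot = n_boot, seed = seed)
    tibble::tibble(component = c("x", "y", "z")[a], dip = h$dip, p_value = h$p_value)
  })
  verdict <- if (any(dip$p_value < dip_threshold)) "multimodal" else "unimodal"
  structure(list(residuals = residuals, dip = dip, verdict = verdict,
                 probe_indices = probe_idx,
                 max_abs_residual = max(abs(residuals)),
                 p_pred = p_pred, seed = seed),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("<residual_diagnostics: verdict %s (min p = %.3g), max |residual| = %.3f>\n",
              x$verdict, min(x$dip$p_value), x$max_abs_residual))
  invisible(x)
}

#' Assign branch offsets from probe predictions
#'
#' Component-wise: a point with `|p_pred - p_calc| < 1/2` is already on the
#' main branch (offset 0); otherwise the offset is the nearest integer to the
#' signed residual. A residual within `tol` of a half-integer makes the branch
#' genuinely ambiguous and raises an error naming the points.
#'
#' @param p_pred,p_calc N x 3 matrices of reduced polarizations.
#' @param tol half-integer ambiguity tolerance.
#' @return N x 3 integer matrix of offsets; `p_calc + offsets` is on the
#'   predicted branch.
#' @export
assign_branches <- function(p_pred, p_calc, tol = 1e-6) {
  p_pred <- rbind_vec3(p_pred, "p_pred")
  p_calc <- rbind_vec3(p_calc, "p_calc")
  if (!all(dim(p_pred) == dim(p_calc))) stop("shape mismatch", call. = FALSE)
  d <- p_pred - p_calc
  frac_dist <- abs(abs(d - floor(d)) - 0.5)       # distance to nearest half-integer
  if (any(frac_dist < tol)) {
    bad <- unique(which(frac_dist < tol, arr.ind = TRUE)[, 1])
    stop("ambiguous branch (residual within ", tol, " of a half-integer) for point(s): ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  offsets <- floor(d + 0.5)
  storage.mode(offsets) <- "integer"
  offsets
}

#' Unwrap a polarization dataset onto a single branch
#'
#' Runs the probe-and-diagnose loop with fresh random probe subsets until a
#' subset yields a multimodal residual distribution (or until the data is
#' verified to already sit on a single branch: unimodal residuals that never
#' leave `(-1/2, 1/2)`), then assigns branch offsets to every point.
#' Deterministic for a given seed.
#'
#' @inheritParams probe_and_diagnose
#' @param max_restarts maximum number of probe subsets tried.
#' @param refine_passes after the probe assignment, rebuild the model from
#'   the points whose residuals sit close to an integer (the confidently
#'   branched ones) and re-assign every offset with it, up to this many times
#'   (stops early once the offsets are stable). Points inside the confident
#'   subset are re-assigned from their leave-one-out predictions so a
#'   mis-branched point can never confirm its own assignment.
#' @param refine_regularization ridge parameter of the refinement model; kept
#'   moderate so no single frame reaches leverage one in the refit.
#' @param confident_residual maximum distance of a residual from the nearest
#'   integer for a point to join the refinement training set.
#' @return an `unwrap_result`: `offsets` (N x 3 integer), `unwrapped_p`
#'   (N x 3), `n_restarts`, `probe_indices`, `diagnostics` (last
#'   `residual_diagnostics`), `seed`.
#' @export
unwrap_dataset <- function(frames, p_calc, probe_fraction = 0.05, seed = 1,
                           max_restarts = 20, config = descriptor_config(),
                           regularization = 10, dip_threshold = 0.05,
                           n_boot = 1000, zeta = 2, refine_passes = 4,
                           refine_regularization = 1e-2,
                           confident_residual = 0.35) {
  p_calc <- rbind_vec3(p_calc, "p_calc")
  last <- NULL
  for (attempt in seq_len(max_restarts)) {
    diag <- probe_and_diagnose(frames, p_calc, probe_fraction,
                               seed = seed + 1000 * (attempt - 1),
                               config = config, regularization = regularization,
                               dip_threshold = dip_threshold, n_boot = n_boot,
                               zeta = zeta)
    last <- diag
    if (diag$verdict == "multimodal") {
      offsets <- tryCatch(assign_branches(diag$p_pred, p_calc),
                          error = function(e) NULL)
      if (is.null(offsets)) next     # half-integer ambiguity: resample probe
      resid <- diag$p_pred - p_calc
      confdist <- apply(abs(resid - round(resid)), 1, max)
      n <- nrow(p_calc)
      for (pass in seq_len(refine_passes)) {
        conf <- which(confdist < confident_residual)
        if (length(conf) < 2) break
        refit <- train_polarization_model(frames[conf],
                                          (p_calc + offsets)[conf, , drop = FALSE],
                                          config = config,
                                          regularization = refine_regularization,
                                          zeta = zeta)
        p_fit <- matrix(NA_real_, n, 3)
        p_fit[conf, ] <- loo_predictions(refit)
        rest <- setdiff(seq_len(n), conf)
        if (length(rest) > 0) {
          p_fit[rest, ] <- do.call(rbind, lapply(
            predict_polarization(refit, frames[rest]), `[[`, "total"))
        }
        new_offsets <- tryCatch(assign_branches(p_fit, p_calc),
                                error = function(e) NULL)
        if (is.null(new_offsets)) break
        resid <- p_fit - p_calc
        confdist <- apply(abs(resid - round(resid)), 1, max)
        if (identical(new_offsets, offsets)) break
        offsets <- new_offsets
      }
      return(structure(list(offsets = offsets,
                            unwrapped_p = p_calc + offsets,
                            n_restarts = attempt - 1L,
                            probe_indices = diag$probe_indices,
                            diagnostics = diag, seed = seed),
                       class = "unwrap_result"))
    }
    if (diag$max_abs_residual < 0.5) {
      # unimodal residuals that never reach half a quantum: the dataset is
      # already on one branch, nothing to unwrap
      offsets <- matrix(0L, nrow(p_calc), 3)
      return(structure(list(offsets = offsets, unwrapped_p = p_calc,
                            n_restarts = attempt - 1L,
                            probe_indices = diag$probe_indices,
                            diagnostics = diag, seed = seed),
                       class = "unwrap_result"))
    }
  }
  stop(sprintf(
    paste0("unwrapping failed after %d restarts: every probe produced unimodal ",
           "residuals spanning more than half a quantum (last max |residual| = %.2f, ",
           "min dip p-value = %.3g); the data may mix branches too finely for a ",
           "probe of this size"),
    max_restarts, last$max_abs_residual, min(last$dip$p_value)), call. = FALSE)
}

#' @export
print.unwrap_result <- function(x, ...) {
  cat(sprintf("<unwrap_result: %d points, %d off-branch, %d restart(s)>\n",
              nrow(x$offsets), sum(rowSums(x$offsets != 0) > 0), x$n_restarts))
  invisible(x)
}
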