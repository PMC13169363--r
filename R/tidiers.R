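# Broom-style tidiers and ggplot2 methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an unwrap result
#'
#' @param x an `unwrap_result`.
#' @param ... unused.
#' @return tibble with one row per point: offsets, unwrapped components and an
#'   `off_branch` flag.
#' @export
tidy.unwrap_result <- function(x, ...) {
  tibble::tibble(
    point = seq_len(nrow(x$offsets)),
    nx = x$offsets[, 1], ny = x$offsets[, 2], nz = x$offsets[, 3],
    upx = x$unwrapped_p[, 1], upy = x$unwrapped_p[, 2], upz = x$unwrapped_p[, 3],
    off_branch = rowSums(x$offsets != 0) > 0)
}

#' @rdname tidy.unwrap_result
#' @export
glance.unwrap_result <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$offsets),
    n_off_branch = sum(rowSums(x$offsets != 0) > 0),
    n_restarts = x$n_restarts,
    verdict = x$diagnostics$verdict,
    min_dip_p = min(x$diagnostics$dip$p_value),
    seed = x$seed)
}

#' Tidy a residual diagnostics object
#' @param x a `residual_diagnostics`.
#' @param ... unused.
#' @export
tidy.residual_diagnostics <- function(x, ...) {
  tibble::tibble(
    point = rep(seq_len(nrow(x$residuals)), 3),
    component = rep(c("x", "y", "z"), each = nrow(x$residuals)),
    residual = as.numeric(x$residuals))
}

#' @rdname tidy.residual_diagnostics
#' @export
glance.residual_diagnostics <- function(x, ...) {
  dplyr::mutate(tidyr::pivot_wider(x$dip, names_from = "component",
                                   values_from = c("dip", "p_value")),
                verdict = x$verdict,
                max_abs_residual = x$max_abs_residual)
}

#' Summarize a fitted vector kernel model
#' @param x a `vector_kernel_model`.
#' @param ... unused.
#' @export
glance.vector_kernel_model <- function(x, ...) {
  if (x$target_kind == "global_polarization") {
    p_res <- x$fitted - x$targets
    tibble::tibble(target_kind = x$target_kind, n_references = x$n_frames,
                   zeta = x$zeta, regularization = x$regularization,
                   train_rmse = sqrt(mean(p_res^2)))
  } else {
    tibble::tibble(target_kind = x$target_kind,
                   n_references = sum(vapply(x$sub, function(s) nrow(s$weights), integer(1))),
                   zeta = x$zeta, regularization = x$regularization,
                   train_rmse = NA_real_)
  }
}

#' Tidy a spectrum into long format
#' @param x an `ir_spectrum`.
#' @param ... unused.
#' @export
tidy.ir_spectrum <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"wavenumber",
                      names_to = "channel", values_to = "intensity")
}

#' Plot an IR spectrum (components included when present)
#' @param object an `ir_spectrum`.
#' @param ... unused.
#' @export
autoplot.ir_spectrum <- function(object, ...) {
  long <- tidy.ir_spectrum(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavenumber, y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "intensity (arb. units)") +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function with its first extrema
#' @param object an `rdf`.
#' @param ... unused.
#' @export
autoplot.rdf <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "r (Å)", y = "g(r)") +
    ggplot2::theme_minimal()
  fm <- attr(object, "first_max"); fn <- attr(object, "first_min")
  if (!is.na(fm)) p <- p + ggplot2::geom_vline(xintercept = fm, linetype = 2)
  if (!is.na(fn)) p <- p + ggplot2::geom_vline(xintercept = fn, linetype = 2)
  p
}

#' Histogram of probe residuals per component
#' @param object a `residual_diagnostics`.
#' @param bins histogram bins.
#' @param ... unused.
#' @export
autoplot.residual_diagnostics <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy.residual_diagnostics(object),
                  ggplot2::aes(x = .data$residual)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = expression(Delta * p), y = "count") +
    ggplot2::theme_minimal()
}
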