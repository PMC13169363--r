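# Hartigan dip test for unimodality.
#
# The dip statistic is the smallest sup-norm distance between the empirical
# CDF and any unimodal CDF; it is computed exactly in compiled code (see
# src/dip.cpp). Significance is assessed by a seeded bootstrap against the
# uniform null, the asymptotically least-favourable unimodal distribution, so
# the resulting p-values are conservative for other unimodal nulls.

# cache of bootstrap null tables, keyed by "n/n_boot/seed"
.dip_cache <- new.env(parent = emptyenv())

#' Hartigan dip test
#'
#' @param sample numeric vector (n >= 4).
#' @param n_boot bootstrap resamples for the p-value.
#' @param seed RNG seed for the bootstrap (the null table for a given
#'   `(n, n_boot, seed)` is cached within the session).
#' @return list with `dip` (in `[0, 1/4]`) and `p_value` (share of uniform
#'   null samples with a dip at least as large).
#' @export
hartigan_dip <- function(sample, n_boot = 1000, seed = 1) {
  sample <- as.numeric(sample)
  if (length(sample) < 4) stop("dip test needs at least 4 observations", call. = FALSE)
  if (any(!is.finite(sample))) stop("sample must be finite", call. = FALSE)
  dip <- dip_stat_cpp(sort(sample))
  null <- dip_null_table(length(sample), n_boot, seed)
  p <- (1 + sum(null >= dip - 1e-12)) / (n_boot + 1)
  list(dip = dip, p_value = p)
}

#' Dip statistic only
#' @param sample numeric vector.
#' @export
dip_statistic <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2) stop("need at least 2 observations", call. = FALSE)
  dip_stat_cpp(sort(sample))
}

dip_null_table <- function(n, n_boot, seed) {
  key <- paste(n, n_boot, seed, sep = "/")
  if (!is.null(.dip_cache[[key]])) return(.dip_cache[[key]])
  tab <- withr::with_seed(seed, {
    dip_boot_cpp(matrix(stats::runif(n * n_boot), n, n_boot))
  })
  .dip_cache[[key]] <- tab
  tab
}
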