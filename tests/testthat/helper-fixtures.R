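# Shared fixtures, memoised so expensive frame sets are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# standard mixture frames: 4 water + 1 ethanol in a cubic 8.19 A box
mix_frames <- function(n, base_seed = 100) {
  memo(paste0("mix", n, "_", base_seed), {
    lapply(seq_len(n), function(k) make_mixture_frame(fixture_spec(4, 1, seed = base_seed + k)))
  })
}

oracle_P <- function(frames, charge_scale = 1) {
  t(vapply(frames, smooth_polarization_oracle, numeric(3), charge_scale = charge_scale))
}

# a lone ideal water frame in a large box (O at origin)
water_frame <- function(box = 20) {
  half <- 104.5 / 2 * pi / 180
  pos <- rbind(c(0, 0, 0),
               0.96 * c(cos(half), sin(half), 0),
               0.96 * c(cos(half), -sin(half), 0)) + box / 2
  frame(c("O", "H", "H"), pos, cell(diag(3) * box))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# fraction of points whose recovered offsets match the truth modulo the
# common integer gauge
offset_recovery <- function(recovered, truth) {
  tot <- recovered - truth
  gauge <- apply(tot, 2, function(v) as.integer(names(which.max(table(v)))))
  mean(rowSums(sweep(tot, 2, gauge) != 0) == 0)
}
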