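# Internal helpers shared across modules.

# Deterministic child seeds derived from one user-facing seed. Keeps every
# stage on its own stream so adding draws to one stage cannot shift another.
# Values stay below .Machine$integer.max (R seeds are 32-bit).
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1299709 + 7919 * as.double(index)) %% 2147483629)
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must be finite (got non-finite values).", name))
  }
  invisible(x)
}

# Pearson correlation between the rows of two matrices: out[i, j] =
# cor(x1[i, ], x2[j, ]). Rows with zero variance give NA columns/rows.
row_cor <- function(x1, x2) {
  suppressWarnings(stats::cor(t(x1), t(x2)))
}

is_count <- function(x) {
  length(x) == 1 && is.finite(x) && x == round(x) && x >= 0
}
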