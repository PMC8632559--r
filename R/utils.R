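# internal helpers shared across modules

geom_mean <- function(x) {
  # a zero subunit zeroes the whole complex (multi-subunit requirement)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

frobenius <- function(m) sqrt(sum(m^2))

# deterministic sign convention for embedding axes: largest-|loading|
# coordinate on each axis is made positive
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (all(v == 0)) next
    if (v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  coords
}

split_subunits <- function(x) strsplit(x, "&", fixed = TRUE)

join_subunits <- function(x) vapply(x, paste, "", collapse = "&")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
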