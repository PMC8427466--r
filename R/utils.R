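# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Wrap phase angles into (-pi, pi]
#'
#' Velocity-encoded phase accumulates beyond the principal interval when the
#' velocity exceeds the encoding velocity; this maps any angle back onto the
#' half-open interval used by the phase-contrast decoder.
#'
#' @param x numeric vector or array of angles, radians.
#' @return angles in (-pi, pi], same shape as `x`.
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
# All simulators route their randomness through this so they are pure
# functions of (inputs, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stage index, staying well
# below .Machine$integer.max (double arithmetic: products stay exact far
# below 2^53).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2147480009)
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# circular disc mask on a pixel grid; centre in pixel coordinates (row, col)
disc_mask <- function(grid_shape, centre, radius) {
  r <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  c <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  (r - centre[1])^2 + (c - centre[2])^2 <= radius^2
}
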