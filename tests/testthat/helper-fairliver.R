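# Shared fixtures: small phantoms and protocols keep the suite fast while
# exercising the same code paths as the full-size acquisition.

tiny_phantom <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(32L, 32L), seed = seed, ...)
}

tiny_protocol <- function(matrix_size = 32L, n_readouts = 12L) {
  fair_protocol(matrix_size = matrix_size, n_readouts = n_readouts,
                fov_mm = 60)
}

# independent forward model for single-pixel recovery curves
ir_curve <- function(m0, alpha, t1_star, tis) {
  m0 * (1 - alpha * exp(-tis / t1_star))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
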