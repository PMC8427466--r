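#' Slice-selective T1 implied by a perfusion level
#'
#' In FAIR ASL, inflow of non-inverted blood after a slice-selective
#' inversion shortens the apparent tissue T1. Inverting the perfusion
#' equation P = (lambda / T1_blood) * (T1_global / T1_ss - 1) gives the
#' slice-selective T1 that a tissue with global T1 `t1_global` and perfusion
#' `perfusion` must exhibit:
#' `T1_ss = T1_global / (1 + P * T1_blood / (lambda * 6e6))`,
#' where the 6e6 converts ml/g/ms to ml/min/100 g (60000 ms/min x 100 g).
#' At the defaults (lambda = 0.95 ml/g, T1_blood = 1900 ms) the denominator
#' is `1 + P/3000`.
#'
#' @param t1_global global-inversion (tissue) T1, ms.
#' @param perfusion perfusion, ml/min/100 g; vectorised.
#' @param lambda_ blood-tissue partition coefficient, ml/g.
#' @param t1_blood blood T1, ms.
#' @return slice-selective T1, ms.
#' @seealso [perfusion_map()] which applies the forward equation; the two
#'   compose to the identity.
#' @export
t1_slice_selective_from_perfusion <- function(t1_global, perfusion,
                                              lambda_ = 0.95,
                                              t1_blood = 1900) {
  if (any(t1_global <= 0)) stop("t1_global must be positive", call. = FALSE)
  if (any(perfusion < 0)) stop("perfusion must be >= 0", call. = FALSE)
  stop_if_not_scalar_positive(lambda_, "lambda_")
  stop_if_not_scalar_positive(t1_blood, "t1_blood")
  scale <- lambda_ / t1_blood * 6e6   # ml/min/100 g per unit T1 ratio
  t1_global / (1 + perfusion / scale)
}

#' Inversion-recovery image series container
#'
#' @param images array rows x cols x n_TI, arbitrary signal units.
#' @param tis inversion times, ms, strictly increasing, one per image.
#' @param inversion_mode `"global"` or `"slice_selective"`.
#' @param protocol a [fair_protocol()].
#' @return object of class `ir_series`.
#' @export
ir_series <- function(images, tis,
                      inversion_mode = c("global", "slice_selective"),
                      protocol = fair_protocol()) {
  inversion_mode <- match.arg(inversion_mode)
  stopifnot(length(dim(images)) == 3L)
  if (is.unsorted(tis, strictly = TRUE)) {
    stop("TIs must be strictly increasing", call. = FALSE)
  }
  if (dim(images)[3] != length(tis)) {
    stop("image count must equal the number of TIs", call. = FALSE)
  }
  if (length(tis) != protocol$n_readouts) {
    stop("length(tis) must equal protocol$n_readouts", call. = FALSE)
  }
  structure(list(images = images, tis = tis, inversion_mode = inversion_mode,
                 protocol = protocol), class = "ir_series")
}

#' @export
print.ir_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Inversion-recovery series (%s): %d x %d, %d TIs (%g..%g ms)\n",
              x$inversion_mode, d[1], d[2], d[3], min(x$tis), max(x$tis)))
  invisible(x)
}

# noiseless per-pixel recovery signal Mz(TI) = M0 (1 - alpha exp(-TI/T1*)),
# with T1* = T1_effective / (alpha - 1) so that the Look-Locker correction
# chain is exactly invertible.
fair_signal_array <- function(m0, alpha, t1_eff, tis) {
  t1_star <- t1_eff / (alpha - 1)
  n <- length(tis)
  out <- array(0, c(dim(m0), n))
  for (k in seq_len(n)) {
    out[, , k] <- m0 * (1 - alpha * exp(-tis[k] / t1_star))
  }
  # background pixels (m0 == 0, t1_eff == 0) produce NaN in t1_star; zero them
  out[!is.finite(out)] <- 0
  out
}

#' Simulate a FAIR inversion-recovery series from a phantom
#'
#' Forward model of the Look-Locker fitting chain: each pixel recovers as
#' `Mz(TI) = M0 (1 - alpha exp(-TI/T1*))` with the apparent
#' `T1* = T1_eff / (alpha - 1)`. For a global inversion `T1_eff` is the
#' tissue T1; for a slice-selective inversion it is shortened by perfusion
#' via [t1_slice_selective_from_perfusion()], so a phantom with zero
#' perfusion yields identical series in both modes.
#'
#' Noise is zero-mean Gaussian added to the signed signal (default), which
#' keeps least-squares fitting unbiased; a Rician option applies the noise
#' in quadrature and returns magnitudes.
#'
#' @param phantom a [phantom_spec()].
#' @param mode inversion mode, `"global"` or `"slice_selective"`.
#' @param noise_sd noise standard deviation, same units as M0.
#' @param seed integer seed (noise only).
#' @param noise_model `"gaussian"` (signed) or `"rician"` (magnitude).
#' @param protocol acquisition protocol; defaults to [fair_protocol()] with
#'   the phantom's matrix size.
#' @return an [ir_series()].
#' @export
simulate_fair_series <- function(phantom,
                                 mode = c("global", "slice_selective"),
                                 noise_sd = 0, seed = phantom$seed,
                                 noise_model = c("gaussian", "rician"),
                                 protocol = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"))
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(protocol)) {
    protocol <- fair_protocol(matrix_size = phantom$grid_shape[1],
                              fov_mm = phantom$fov_mm)
  }
  truth <- phantom_truth_maps(phantom)
  t1_eff <- truth$t1
  if (mode == "slice_selective") {
    pos <- truth$t1 > 0
    t1_eff[pos] <- t1_slice_selective_from_perfusion(
      truth$t1[pos], truth$perfusion[pos],
      lambda_ = 0.95, t1_blood = phantom$t1_blood_ms)
  }
  alpha <- phantom$alpha_true[[mode]]
  tis <- protocol_tis(protocol)
  sig <- fair_signal_array(truth$m0, alpha, t1_eff, tis)
  if (noise_sd > 0) {
    sig <- with_seed(seed, {
      if (noise_model == "gaussian") {
        sig + array(stats::rnorm(length(sig), 0, noise_sd), dim(sig))
      } else {
        sqrt((sig + array(stats::rnorm(length(sig), 0, noise_sd), dim(sig)))^2 +
               array(stats::rnorm(length(sig), 0, noise_sd), dim(sig))^2)
      }
    })
  }
  ir_series(sig, tis, mode, protocol)
}
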