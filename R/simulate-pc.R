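#' Phase-contrast cine container
#'
#' Holds per-frame phase images (radians) of a through-plane
#' velocity-encoded cine, with the encoding velocity and frame timing
#' needed to decode velocities and integrate flow.
#'
#' @param phases array rows x cols x n_phases of phase values in (-pi, pi].
#' @param venc velocity producing a phase shift of pi, cm/s.
#' @param frame_times frame times within the cardiac cycle, ms.
#' @param voxel_area in-plane voxel area, mm^2.
#' @param vessel_label which vessel the cine images.
#' @param heart_rate_bpm heart rate, beats/min.
#' @param vessel_centre_px,vessel_radius_px vessel disc in pixel units
#'   (used for default ROI construction).
#' @return object of class `velocity_cine`.
#' @export
velocity_cine <- function(phases, venc, frame_times, voxel_area,
                          vessel_label, heart_rate_bpm,
                          vessel_centre_px = NULL, vessel_radius_px = NULL) {
  stop_if_not_scalar_positive(venc, "venc")
  n <- dim(phases)[3]
  if (n < 12 || n > 15) {
    stop("number of cardiac phases must lie in 12..15", call. = FALSE)
  }
  if (length(frame_times) != n) {
    stop("frame_times must match the number of frames", call. = FALSE)
  }
  if (any(phases <= -pi - 1e-12) || any(phases > pi + 1e-12)) {
    stop("phase values must lie in (-pi, pi]", call. = FALSE)
  }
  structure(list(phases = phases, venc = venc, frame_times = frame_times,
                 n_phases = n, voxel_area = voxel_area,
                 vessel_label = vessel_label,
                 heart_rate_bpm = heart_rate_bpm,
                 vessel_centre_px = vessel_centre_px,
                 vessel_radius_px = vessel_radius_px),
            class = "velocity_cine")
}

#' Simulate a cardiac-gated phase-contrast cine of a caval station
#'
#' Through-plane velocity over the vessel disc is parabolic (Poiseuille),
#' `v(r, t) = vmax(t) (1 - (r/R)^2)`, with the centreline velocity
#' modulated over the cardiac cycle by a single-harmonic zero-mean
#' waveform: `vmax(t) = peak_velocity (1 + pulsatility_fraction
#' sin(2 pi t / T))`. Velocity maps to phase as `phi = pi v / venc`,
#' wrapped into (-pi, pi] (velocities beyond the encoding velocity alias);
#' background tissue is static (zero phase) apart from noise.
#'
#' @param phantom a [phantom_spec()] providing vessel geometry, heart rate
#'   and pulsatility.
#' @param vessel `"infra_IVC"` or `"supra_IVC"`.
#' @param venc encoding velocity, cm/s; defaults to the vessel's protocol
#'   value (33 infra, 66 supra).
#' @param noise_sd phase noise standard deviation, radians.
#' @param n_phases number of cardiac phases (12-15).
#' @param seed integer seed (noise only).
#' @param matrix_size,fov_mm cine grid; defaults 192 x 192 over 40 mm
#'   (0.208 mm pixels).
#' @return a [velocity_cine()].
#' @export
simulate_pc_cine <- function(phantom, vessel = c("infra_IVC", "supra_IVC"),
                             venc = NULL, noise_sd = 0, n_phases = 13,
                             seed = phantom$seed,
                             matrix_size = 192L, fov_mm = 40) {
  stopifnot(inherits(phantom, "phantom_spec"))
  vessel <- match.arg(vessel)
  spec <- phantom$vessel_specs[[vessel]]
  if (is.null(spec)) stop("vessel not present in phantom", call. = FALSE)
  if (is.null(venc)) venc <- spec$venc
  stop_if_not_scalar_positive(venc, "venc")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)

  px <- fov_mm / matrix_size                 # mm
  centre <- c(matrix_size / 2 + 1, matrix_size / 2 + 1)
  rows <- matrix(seq_len(matrix_size), matrix_size, matrix_size)
  cols <- matrix(seq_len(matrix_size), matrix_size, matrix_size, byrow = TRUE)
  r_mm <- px * sqrt((rows - centre[1])^2 + (cols - centre[2])^2)
  R <- spec$radius_mm
  profile <- pmax(0, 1 - (r_mm / R)^2)       # parabolic, 0 outside the disc
  inside <- r_mm <= R

  period_ms <- 60000 / phantom$heart_rate_bpm
  frame_times <- (seq_len(n_phases) - 1) * period_ms / n_phases
  w <- sin(2 * pi * frame_times / period_ms)
  vmax <- spec$peak_velocity * (1 + phantom$pulsatility_fraction * w)

  phases <- array(0, c(matrix_size, matrix_size, n_phases))
  for (k in seq_len(n_phases)) {
    v <- vmax[k] * profile
    phases[, , k] <- pi * v / venc
  }
  if (noise_sd > 0) {
    phases <- with_seed(seed, {
      phases + array(stats::rnorm(length(phases), 0, noise_sd), dim(phases))
    })
  }
  phases <- wrap_phase(phases)
  velocity_cine(phases, venc, frame_times, voxel_area = px^2,
                vessel_label = vessel, heart_rate_bpm = phantom$heart_rate_bpm,
                vessel_centre_px = centre, vessel_radius_px = R / px)
}
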