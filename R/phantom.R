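#' Acquisition protocol metadata
#'
#' Default sequence parameters of the FAIR Look-Locker ASL and phase-contrast
#' acquisitions: 110 ms inversion-time spacing with 50 readouts, 2.3 ms RF
#' repetition time, 8 degree flip, 13 s inversion repetition time, 128x128
#' matrix over a 60 mm field of view for the ASL slice, and a 192x192 matrix
#' over 40 mm (0.208 mm pixels) for the phase-contrast cine.
#'
#' @param ti_spacing_ms spacing between inversion-recovery readouts, ms.
#' @param n_readouts number of inversion-recovery readouts (= number of TIs).
#' @param tr_rf_ms RF repetition time within a readout, ms.
#' @param flip_deg Look-Locker flip angle, degrees.
#' @param tr_inversion_s time between successive inversions, s.
#' @param matrix_size acquisition matrix (rows = phase-encode lines).
#' @param fov_mm field of view, mm.
#' @param slice_mm slice thickness, mm.
#' @param lines_per_segment k-space lines acquired per segmented readout.
#' @param pc_matrix_size,pc_fov_mm matrix and field of view of the
#'   phase-contrast cine.
#' @return a list of class `fair_protocol`.
#' @export
fair_protocol <- function(ti_spacing_ms = 110, n_readouts = 50,
                          tr_rf_ms = 2.3, flip_deg = 8,
                          tr_inversion_s = 13,
                          matrix_size = 128, fov_mm = 60, slice_mm = 2,
                          lines_per_segment = 4,
                          pc_matrix_size = 192, pc_fov_mm = 40) {
  stop_if_not_scalar_positive(ti_spacing_ms, "ti_spacing_ms")
  stop_if_not_scalar_positive(n_readouts, "n_readouts")
  if (matrix_size %% lines_per_segment != 0) {
    stop("matrix_size must be a multiple of lines_per_segment", call. = FALSE)
  }
  structure(list(
    ti_spacing_ms = ti_spacing_ms, n_readouts = as.integer(n_readouts),
    tr_rf_ms = tr_rf_ms, flip_deg = flip_deg,
    tr_inversion_s = tr_inversion_s,
    matrix_size = as.integer(matrix_size), fov_mm = fov_mm,
    slice_mm = slice_mm, lines_per_segment = as.integer(lines_per_segment),
    pc_matrix_size = as.integer(pc_matrix_size), pc_fov_mm = pc_fov_mm
  ), class = "fair_protocol")
}

#' Inversion times of a protocol
#'
#' TIs are placed on an even grid `k * ti_spacing_ms`, k = 1..n_readouts,
#' i.e. the first readout occurs one spacing after the inversion pulse.
#'
#' @param protocol a [fair_protocol()].
#' @return numeric vector of inversion times, ms.
#' @export
protocol_tis <- function(protocol) {
  protocol$ti_spacing_ms * seq_len(protocol$n_readouts)
}

#' Digital rodent-liver phantom
#'
#' Ground-truth single-slice digital animal: a liver parenchyma region with
#' known equilibrium signal, T1 and perfusion, an in-slice blood vessel at
#' blood T1, and two caval stations (infra- and supra-hepatic IVC) with
#' parabolic pulsatile flow for the phase-contrast cine. All downstream
#' stages (T1 fitting, perfusion mapping, gating, flow integration) can be
#' checked against the stored truth.
#'
#' Geometry is region-label based: 0 = background (no signal), 1 = liver
#' parenchyma, 2 = in-slice vessel. `tissue_t1`, `tissue_m0` and
#' `perfusion_true` are named per region.
#'
#' @param grid_shape image matrix (rows, cols); default 128 x 128.
#' @param fov_mm field of view of the ASL slice, mm.
#' @param t1_liver_ms liver parenchyma longitudinal relaxation time, ms.
#' @param m0_liver equilibrium signal of liver tissue, arbitrary units.
#' @param perfusion_liver liver perfusion, ml/min/100 g.
#' @param alpha_true apparent inversion efficiency (2 = perfect inversion);
#'   used for both global and slice-selective inversions.
#' @param t1_blood_ms blood T1, ms (default 1900).
#' @param liver_weight_g wet liver weight, g.
#' @param heart_rate_bpm heart rate, beats/min (rodent range 300-400).
#' @param pulsatility_fraction fractional modulation of caval peak velocity
#'   over the cardiac cycle.
#' @param resp_period_s respiratory cycle duration, s.
#' @param quiescent_fraction fraction of each respiratory cycle that is
#'   quiescent (end-expiration plateau), in (0, 1).
#' @param infra_peak_velocity,supra_peak_velocity peak (centreline) velocity
#'   in the infra-/supra-hepatic IVC, cm/s. If `supra_peak_velocity` is NULL
#'   it is set so that caval subtraction yields `tlbf_true`.
#' @param vessel_radius_mm caval vessel radius, mm (default 1.75, i.e. the
#'   3.5 mm diameter typical of the rat IVC).
#' @param tlbf_true total liver blood flow ground truth, ml/min/100 g; only
#'   used when `supra_peak_velocity` is NULL.
#' @param cohort `"sham"` or `"BDL"`.
#' @param seed integer seed recorded with the phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L), fov_mm = 60,
                         t1_liver_ms = 1256, m0_liver = 1000,
                         perfusion_liver = 316, alpha_true = 1.95,
                         t1_blood_ms = 1900, liver_weight_g = 14,
                         heart_rate_bpm = 350, pulsatility_fraction = 0.2,
                         resp_period_s = 1.0, quiescent_fraction = 0.4,
                         infra_peak_velocity = 20,
                         supra_peak_velocity = NULL,
                         vessel_radius_mm = 1.75,
                         tlbf_true = 335,
                         cohort = c("sham", "BDL"), seed = 1L) {
  cohort <- match.arg(cohort)
  grid_shape <- as.integer(grid_shape)
  stop_if_not_scalar_positive(t1_liver_ms, "t1_liver_ms")
  stop_if_not_scalar_positive(liver_weight_g, "liver_weight_g")
  stop_if_not_scalar_positive(t1_blood_ms, "t1_blood_ms")
  if (perfusion_liver < 0) stop("perfusion_liver must be >= 0", call. = FALSE)
  if (!(alpha_true > 1 && alpha_true <= 2)) {
    stop("alpha_true must lie in (1, 2]", call. = FALSE)
  }
  if (!(quiescent_fraction > 0 && quiescent_fraction < 1)) {
    stop("quiescent_fraction must lie in (0, 1)", call. = FALSE)
  }
  pixel_size <- fov_mm / grid_shape[2]
  # the caval vessels are imaged on the phase-contrast grid (0.208 mm
  # pixels); the radius must resolve there
  pc_pixel <- 40 / 192
  if (vessel_radius_mm <= pc_pixel) {
    stop("vessel radius must exceed the phase-contrast pixel size",
         call. = FALSE)
  }

  # region geometry: elliptical liver with an in-slice vessel disc
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2],
                 byrow = TRUE)
  cr <- grid_shape[1] / 2 + 1
  cc <- grid_shape[2] / 2 + 1
  a <- 0.42 * grid_shape[1]   # semi-axes in pixels
  b <- 0.30 * grid_shape[2]
  liver <- ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
  vessel <- disc_mask(grid_shape,
                      c(cr + 0.12 * grid_shape[1], cc),
                      max(2, vessel_radius_mm / pixel_size))
  region <- matrix(0L, grid_shape[1], grid_shape[2])
  region[liver] <- 1L
  region[vessel & liver] <- 2L

  # caval geometry for the phase-contrast stations; flows in ml/min
  infra_flow <- pi * (vessel_radius_mm / 10)^2 * infra_peak_velocity / 2 * 60
  if (is.null(supra_peak_velocity)) {
    hepatic_inflow <- tlbf_true * liver_weight_g / 100
    supra_flow <- infra_flow + hepatic_inflow
    supra_peak_velocity <- 2 * (supra_flow / 60) / (pi * (vessel_radius_mm / 10)^2)
  }
  vessel_specs <- list(
    infra_IVC = list(label = "infra_IVC", radius_mm = vessel_radius_mm,
                     peak_velocity = infra_peak_velocity, venc = 33),
    supra_IVC = list(label = "supra_IVC", radius_mm = vessel_radius_mm,
                     peak_velocity = supra_peak_velocity, venc = 66)
  )

  structure(list(
    grid_shape = grid_shape, pixel_size = pixel_size, fov_mm = fov_mm,
    region = region, liver_mask = region == 1L, vessel_mask = region == 2L,
    tissue_t1 = c(liver = t1_liver_ms, vessel = t1_blood_ms),
    tissue_m0 = c(liver = m0_liver, vessel = m0_liver),
    perfusion_true = c(liver = perfusion_liver, vessel = 0),
    alpha_true = c(global = alpha_true, slice_selective = alpha_true),
    t1_blood_ms = t1_blood_ms, liver_weight_g = liver_weight_g,
    heart_rate_bpm = heart_rate_bpm,
    pulsatility_fraction = pulsatility_fraction,
    resp_period_s = resp_period_s, quiescent_fraction = quiescent_fraction,
    vessel_specs = vessel_specs, cohort = cohort, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Digital liver phantom (", x$cohort, ")\n", sep = "")
  cat(sprintf("  grid %d x %d, pixel %.3f mm\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_size))
  cat(sprintf("  liver: T1 %.0f ms, perfusion %.0f ml/min/100 g, weight %.1f g\n",
              x$tissue_t1[["liver"]], x$perfusion_true[["liver"]],
              x$liver_weight_g))
  cat(sprintf("  heart rate %.0f bpm, respiration %.2f s (quiescent %.0f%%)\n",
              x$heart_rate_bpm, x$resp_period_s, 100 * x$quiescent_fraction))
  invisible(x)
}

# per-pixel parameter image from region-labelled values
region_image <- function(phantom, values) {
  img <- matrix(0, phantom$grid_shape[1], phantom$grid_shape[2])
  img[phantom$region == 1L] <- values[["liver"]]
  img[phantom$region == 2L] <- values[["vessel"]]
  img
}

#' Ground-truth parameter maps of a phantom
#'
#' @param phantom a [phantom_spec()].
#' @return list with matrices `t1`, `m0`, `perfusion` and the region labels.
#' @export
phantom_truth_maps <- function(phantom) {
  list(t1 = region_image(phantom, phantom$tissue_t1),
       m0 = region_image(phantom, phantom$tissue_m0),
       perfusion = region_image(phantom, phantom$perfusion_true),
       region = phantom$region)
}

#' Default parenchymal ROI set for a phantom
#'
#' Places the three circular ROIs (right, middle, left) on hepatic
#' parenchyma, clear of the in-slice vessel, mirroring consensus manual
#' placement.
#'
#' @param phantom a [phantom_spec()].
#' @param radius_px ROI radius in pixels (default 8, about 3.75 mm at the
#'   default resolution; scaled down proportionally for smaller grids).
#' @return an [roi_set()].
#' @export
default_rois <- function(phantom, radius_px = NULL) {
  g <- phantom$grid_shape
  if (is.null(radius_px)) radius_px <- max(2, round(8 * g[1] / 128))
  cr <- g[1] / 2 + 1
  cc <- g[2] / 2 + 1
  centres <- rbind(
    right  = c(cr - 0.08 * g[1], cc - 0.17 * g[2]),
    middle = c(cr - 0.22 * g[1], cc),
    left   = c(cr - 0.08 * g[1], cc + 0.17 * g[2])
  )
  roi_set(centres, radius_px, labels = c("right", "middle", "left"),
          liver_mask = phantom$liver_mask, vessel_mask = phantom$vessel_mask)
}
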