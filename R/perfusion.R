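#' Perfusion quantification parameters
#'
#' @param lambda_ blood-tissue partition coefficient, ml/g (default 0.95,
#'   from krypton-85 clearance measurements in liver).
#' @param t1_blood blood T1 at field, ms (default 1900).
#' @param upper_threshold perfusion above this is non-physiological and the
#'   pixel is marked invalid, ml/min/100 g (default 2000).
#' @return list of class `perfusion_params`.
#' @export
perfusion_params <- function(lambda_ = 0.95, t1_blood = 1900,
                             upper_threshold = 2000) {
  stop_if_not_scalar_positive(lambda_, "lambda_")
  stop_if_not_scalar_positive(t1_blood, "t1_blood")
  stop_if_not_scalar_positive(upper_threshold, "upper_threshold")
  structure(list(lambda_ = lambda_, t1_blood = t1_blood,
                 upper_threshold = upper_threshold),
            class = "perfusion_params")
}

#' Perfusion map from paired global and slice-selective T1 maps
#'
#' FAIR perfusion quantification: assuming constant blood inflow,
#' `P = (lambda / T1_blood) (T1_global / T1_ss - 1)`, converted to
#' ml/min/100 g. The unit conversion (60000 ms/min x 100 g) is computed
#' from `lambda_` and `t1_blood` at call time -- 3000 x the T1 ratio excess
#' at the defaults -- so overrides of either constant propagate. Negative
#' perfusion is clamped to zero; values above `upper_threshold` are
#' non-physiological and marked invalid (excluded, not capped), as are
#' pixels invalid in either T1 map.
#'
#' @param t1_global global-inversion (control) [fit_t1_map()] result.
#' @param t1_ss slice-selective (flow-sensitised) result, co-registered and
#'   of the same shape.
#' @param params a [perfusion_params()].
#' @return object of class `perfusion_map`: matrix `values`
#'   (ml/min/100 g; NA where invalid), logical `valid`, and the parameters.
#' @export
perfusion_map <- function(t1_global, t1_ss, params = perfusion_params()) {
  stopifnot(inherits(params, "perfusion_params"))
  g <- if (inherits(t1_global, "t1_map_set")) t1_global$t1 else t1_global
  s <- if (inherits(t1_ss, "t1_map_set")) t1_ss$t1 else t1_ss
  if (!all(dim(g) == dim(s))) {
    stop("global and slice-selective maps must have the same shape",
         call. = FALSE)
  }
  vg <- if (inherits(t1_global, "t1_map_set")) t1_global$valid else
    is.finite(g) & g > 0
  vs <- if (inherits(t1_ss, "t1_map_set")) t1_ss$valid else
    is.finite(s) & s > 0
  scale <- params$lambda_ / params$t1_blood * 6e6   # -> ml/min/100 g
  p <- scale * (g / s - 1)
  valid <- vg & vs & is.finite(p) & p <= params$upper_threshold
  p[p < 0] <- 0
  p[!valid] <- NA_real_
  structure(list(values = p, valid = valid, params = params),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf("Perfusion map: %d x %d, %d valid pixels, median %.0f ml/min/100 g\n",
              nrow(x$values), ncol(x$values), sum(x$valid),
              stats::median(x$values[x$valid])))
  invisible(x)
}

#' Three-ROI parenchymal measurement set
#'
#' Three identically sized circular ROIs on the right, middle and left
#' hepatic parenchyma, avoiding major vessels and extra-hepatic tissue.
#'
#' @param centres 3 x 2 matrix of (row, col) centres, pixels; row names are
#'   used as labels if `labels` is NULL.
#' @param radius_px common ROI radius, pixels.
#' @param labels ROI labels, default right/middle/left.
#' @param liver_mask optional logical matrix; every ROI must lie fully
#'   inside it.
#' @param vessel_mask optional logical matrix; ROIs must not overlap it.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(centres, radius_px,
                    labels = c("right", "middle", "left"),
                    liver_mask = NULL, vessel_mask = NULL) {
  centres <- as.matrix(centres)
  if (nrow(centres) != 3L || ncol(centres) != 2L) {
    stop("exactly three ROI centres (rows of a 3 x 2 matrix) are required",
         call. = FALSE)
  }
  stop_if_not_scalar_positive(radius_px, "radius_px")
  if (!is.null(liver_mask) || !is.null(vessel_mask)) {
    shape <- dim(liver_mask %||% vessel_mask)
    for (i in 1:3) {
      m <- disc_mask(shape, centres[i, ], radius_px)
      if (!is.null(liver_mask) && any(m & !liver_mask)) {
        stop(sprintf("ROI '%s' extends outside the liver mask", labels[i]),
             call. = FALSE)
      }
      if (!is.null(vessel_mask) && any(m & vessel_mask)) {
        stop(sprintf("ROI '%s' overlaps a vessel", labels[i]), call. = FALSE)
      }
    }
  }
  structure(list(centres = centres, radius_px = radius_px, labels = labels),
            class = "roi_set")
}

roi_masks <- function(rois, shape) {
  masks <- lapply(1:3, function(i) disc_mask(shape, rois$centres[i, ],
                                             rois$radius_px))
  names(masks) <- rois$labels
  masks
}

#' Average a map over the three parenchymal ROIs
#'
#' Returns the unweighted mean of the three per-ROI means computed over
#' valid pixels only (a mean of ROI means, not a pooled pixel mean, so
#' unequal valid-pixel counts do not weight the result). Works on
#' [perfusion_map()] results, [fit_t1_map()] results (averaging T1) or a
#' plain numeric matrix (NA = invalid).
#'
#' @param map a `perfusion_map`, `t1_map_set`, or numeric matrix.
#' @param rois an [roi_set()].
#' @return scalar in the map's units.
#' @export
roi_mean <- function(map, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (inherits(map, "perfusion_map")) {
    vals <- map$values; ok <- map$valid
  } else if (inherits(map, "t1_map_set")) {
    vals <- map$t1; ok <- map$valid
  } else {
    vals <- map; ok <- is.finite(map)
  }
  masks <- roi_masks(rois, dim(vals))
  means <- vapply(seq_along(masks), function(i) {
    sel <- masks[[i]] & ok
    if (!any(sel)) {
      stop(sprintf("ROI '%s' contains no valid pixels", rois$labels[i]),
           call. = FALSE)
    }
    mean(vals[sel])
  }, numeric(1))
  mean(means)
}
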