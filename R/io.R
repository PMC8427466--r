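# File interfaces: NIfTI for image series and maps, CSV for tables and
# line flags, YAML for reproducible configuration snapshots.

#' Write an inversion-recovery series as NIfTI
#'
#' The 50-TI stack is stored as a 3-D volume (rows x cols x TI) with the
#' in-plane pixel size recorded in the header; TIs and inversion mode go
#' to a sidecar YAML next to the image.
#'
#' @param series an [ir_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "ir_series"))
  px <- series$protocol$fov_mm / series$protocol$matrix_size
  img <- RNifti::asNifti(series$images,
                         pixdim = c(px, px, series$protocol$slice_mm))
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(tis_ms = series$tis,
                        inversion_mode = series$inversion_mode),
                   paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml"))
  invisible(path)
}

#' Read an inversion-recovery series written by [write_series_nifti()]
#'
#' @param path NIfTI path.
#' @param protocol protocol to attach (defaults to a [fair_protocol()]
#'   matching the image matrix).
#' @return an [ir_series()].
#' @export
read_series_nifti <- function(path, protocol = NULL) {
  img <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml"))
  arr <- array(as.numeric(img), dim(img))
  if (is.null(protocol)) {
    protocol <- fair_protocol(matrix_size = dim(arr)[1],
                              n_readouts = dim(arr)[3],
                              ti_spacing_ms = diff(meta$tis_ms[1:2]))
  }
  ir_series(arr, meta$tis_ms, meta$inversion_mode, protocol)
}

#' Write a perfusion or T1 map as NIfTI
#'
#' Invalid pixels are stored as NA; the unit is recorded in the NIfTI
#' intent description.
#'
#' @param map a `perfusion_map` or `t1_map_set`.
#' @param path output path.
#' @param pixel_size_mm in-plane pixel size, mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, pixel_size_mm = 0.469) {
  vals <- if (inherits(map, "perfusion_map")) map$values else map$t1
  unit <- if (inherits(map, "perfusion_map")) "ml/min/100g" else "ms"
  img <- RNifti::asNifti(vals, pixdim = c(pixel_size_mm, pixel_size_mm, 2))
  attr(img, "description") <- unit
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the long measurement table as CSV
#'
#' @param measurements data.frame (animal, cohort, timepoint, metric,
#'   value).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' Write gating line flags as CSV
#'
#' @param flags a `line_flags` from [flag_lines()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_flags_csv <- function(flags, path) {
  utils::write.csv(as.data.frame(flags), path, row.names = FALSE)
  invisible(path)
}

#' Snapshot a run configuration as YAML
#'
#' Flattens the configuration (cohort distributions, noise levels, seeds,
#' perfusion constants) into a YAML file sufficient to re-run the study.
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_config_snapshot <- function(config, path) {
  flat <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(flat, path)
  invisible(path)
}
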