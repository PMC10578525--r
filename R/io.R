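# Configuration reading and map export.

#' Read a protocol configuration file
#'
#' YAML or JSON protocol description with fields such as `fov_mm`, `res_mm`,
#' `etl`, `shots`, `gmax_mT_m`, `smax_T_m_s`, `dt_us`, `readout_ms`, `b0_T`,
#' `tr_ms`. Returns SI-unit values suitable for [design_ring_set()].
#'
#' @param path file path (.yaml/.yml/.json).
#' @return named list of protocol parameters in SI units.
#' @export
read_protocol_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite needed for JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml needed for YAML configs")
    yaml::read_yaml(path)
  }
  out <- list()
  grab <- function(name, scale = 1, default = NULL) {
    v <- cfg[[name]]
    if (is.null(v)) default else as.numeric(v) * scale
  }
  out$fov <- grab("fov_mm", 1e-3)
  out$resolution <- grab("res_mm", 1e-3)
  out$etl <- as.integer(grab("etl"))
  out$n_shots <- as.integer(grab("shots"))
  out$gmax <- grab("gmax_mT_m", 1e-3, 0.021)
  out$smax <- grab("smax_T_m_s", 1, 120)
  out$dt <- grab("dt_us", 1e-6, 1e-5)
  out$readout_dur <- grab("readout_ms", 1e-3)
  out$B0 <- grab("b0_T", 1, 0.55)
  out$tr <- grab("tr_ms", 1e-3, 3)
  out
}

#' Write a map or image as NIfTI
#'
#' @param map numeric matrix (e.g. a field map in Hz or an image magnitude).
#' @param path output file (.nii or .nii.gz).
#' @param pixel pixel size (m) recorded in the header (mm units).
#' @export
write_map_nifti <- function(map, path, pixel = 7.1e-4) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  arr <- array(if (is.complex(map)) Mod(map) else map, dim = c(dim(map), 1))
  img <- RNifti::asNifti(arr, pixdim = c(pixel * 1e3, pixel * 1e3, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
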