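# Protocol arithmetic and reference configurations.

#' Reference protocol parameter sets
#'
#' Parameter bundles for the 0.55T and 1.5T spiral-ring TSE protocols
#' (field of view 230 mm, ~0.7 mm in-plane resolution, 21 mT/m gradient
#' amplitude budget) and their Cartesian TSE references.
#'
#' @param field `"0.55T"` or `"1.5T"`.
#' @return named list of protocol parameters.
#' @export
protocol_defaults <- function(field = c("0.55T", "1.5T")) {
  field <- match.arg(field)
  if (field == "0.55T") {
    list(field = field, B0 = 0.55, fov = 0.23, resolution = 7.0e-4,
         etl = 8L, central_echo = 4L, n_shots = 8L, readout = 0.021,
         esp = 0.0317, tr = 3, nsa = 6, gmax = 0.021, smax = 120,
         cartesian = list(etl = 16L, esp = 0.0126, n_shots = 20L, nsa = 3))
  } else {
    list(field = field, B0 = 1.5, fov = 0.23, resolution = 7.1e-4,
         etl = 9L, central_echo = 5L, n_shots = 11L, readout = 0.012,
         esp = 0.0228, tr = 3, nsa = 1, gmax = 0.021, smax = 120,
         cartesian = list(etl = 16L, esp = 0.0107, n_shots = 20L, nsa = 1))
  }
}

#' Protocol timing and RF-power arithmetic
#'
#' Computes the effective echo time (central-ring echo index times echo
#' spacing), total scan time (shots x TR x NSA), and the refocusing-pulse
#' energy ratio against a Cartesian reference with identical 180 degree
#' pulses (`100 x etl / etl_ref`).
#'
#' @param proto list with `esp` (s), `etl`, `central_echo`, `n_shots`,
#'   `tr` (s), `nsa` (see [protocol_defaults()]).
#' @param etl_ref Cartesian reference echo train length (NULL omits the
#'   ratio).
#' @return data.frame with `teeff_ms`, `scan_time_s`, `sar_ratio_pct`.
#' @export
protocol_arithmetic <- function(proto, etl_ref = NULL) {
  teeff <- proto$central_echo * proto$esp * 1e3
  scan <- proto$n_shots * proto$tr * proto$nsa
  sar <- if (is.null(etl_ref)) NA_real_ else 100 * proto$etl / etl_ref
  data.frame(teeff_ms = teeff, scan_time_s = scan, sar_ratio_pct = sar)
}

#' Concomitant offset scaling with the gradient amplitude
#'
#' Ratio of the concomitant offset frequency at two reference gradient
#' amplitudes, evaluated from the offset-frequency maps at a probe pixel;
#' the quadratic dependence makes halving the amplitude reduce the offset by
#' a factor of four.
#'
#' @param gm1,gm2 reference amplitudes (T/m), default 21 and 10.5 mT/m.
#' @param geom scan geometry (default axial, 50 mm off-center at 0.55T).
#' @param probe logical in-plane probe coordinates (m).
#' @return scalar ratio `dwc(gm1) / dwc(gm2)`.
#' @export
gm_scaling_factor <- function(gm1 = 0.021, gm2 = 0.0105,
                              geom = scan_geometry("axial", slice_offset = 0.05, B0 = 0.55),
                              probe = c(0.03, 0.02)) {
  m1 <- concomitant_offset_map(geom, gm1, probe[1], probe[2])$dwc
  m2 <- concomitant_offset_map(geom, gm2, probe[1], probe[2])$dwc
  as.numeric(m1 / m2)
}
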