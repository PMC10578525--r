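#' Scan-plane geometry
#'
#' Describes how the logical frame (X = readout 1, Y = readout 2, Z = slice)
#' maps to the physical gradient frame (x, y, z), plus the slice offset along
#' logical Z, in-plane FOV shifts, and the main field strength.
#'
#' @param orientation one of `"axial"`, `"sagittal"`, `"coronal"`, or a 3x3
#'   rotation matrix whose columns are the physical directions of the logical
#'   axes.
#' @param slice_offset slice position along logical Z (m).
#' @param fov_shift length-2 in-plane offsets (m).
#' @param B0 main field (T), must be positive.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(orientation = "axial", slice_offset = 0,
                          fov_shift = c(0, 0), B0 = 0.55) {
  if (B0 <= 0) stop("B0 must be positive")
  R <- if (is.matrix(orientation)) orientation else switch(orientation,
    axial    = diag(3),
    sagittal = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
    coronal  = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
    stop("unknown orientation: ", orientation)
  )
  if (max(abs(crossprod(R) - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10)
    stop("orientation must be a proper rotation (orthonormal, det +1)")
  structure(list(R = R, slice_offset = slice_offset,
                 fov_shift = fov_shift, B0 = B0),
            class = "scan_geometry")
}

#' Physical position of slice-grid coordinates
#'
#' @param geom a [scan_geometry()].
#' @param X,Y logical in-plane coordinates (m), any shape.
#' @return n x 3 matrix of physical (x, y, z) positions.
#' @export
slice_to_physical <- function(geom, X, Y) {
  Xl <- as.vector(X) + geom$fov_shift[1]
  Yl <- as.vector(Y) + geom$fov_shift[2]
  cbind(Xl, Yl, geom$slice_offset) %*% t(geom$R)
}

#' Lowest-order concomitant (Maxwell) field
#'
#' Evaluates the quadratic Maxwell field produced by linear gradients:
#' `Bc = gz^2 (x^2+y^2) / (8 B0) + (gx^2+gy^2) z^2 / (2 B0)
#'      - gx gz x z / (2 B0) - gy gz y z / (2 B0)`
#' (third and higher orders omitted). The first two terms are the
#' self-squared terms, the last two the quadratic cross-terms.
#'
#' @param g physical gradient vector(s), length 3 or n x 3 (T/m).
#' @param r physical position(s), length 3 or n x 3 (m).
#' @param B0 main field (T), positive.
#' @param terms `"all"`, `"self"` (self-squared only) or `"cross"`.
#' @return field offset(s) in T.
#' @export
maxwell_field <- function(g, r, B0, terms = c("all", "self", "cross")) {
  terms <- match.arg(terms)
  if (B0 <= 0) stop("B0 must be positive")
  g <- if (is.matrix(g)) g else matrix(g, ncol = 3)
  r <- if (is.matrix(r)) r else matrix(r, ncol = 3)
  if (nrow(g) != nrow(r)) {
    if (nrow(g) == 1L) g <- g[rep(1, nrow(r)), , drop = FALSE]
    if (nrow(r) == 1L) r <- r[rep(1, nrow(g)), , drop = FALSE]
  }
  self <- g[, 3]^2 * (r[, 1]^2 + r[, 2]^2) / (8 * B0) +
    (g[, 1]^2 + g[, 2]^2) * r[, 3]^2 / (2 * B0)
  cross <- -(g[, 1] * g[, 3] * r[, 1] * r[, 3] +
             g[, 2] * g[, 3] * r[, 2] * r[, 3]) / (2 * B0)
  switch(terms, all = self + cross, self = self, cross = cross)
}

#' Orientation constants of the concomitant offset-frequency map
#'
#' For a spiral readout in quadrature (gX^2 + gY^2 = g0(t)^2, in-plane cross
#' products averaging out over the spiral rotation), the time-averaged
#' Maxwell field is a quadratic form in the logical coordinates. This
#' function expands the physical Maxwell expansion under that assumption and
#' returns the six constants `F1..F6` such that
#' `dwc(r) = gamma gm^2 / (4 B0) (F1 X^2 + F2 Y^2 + F3 Z^2 + F4 XZ + F5 YZ + F6 XY)`.
#'
#' @param geom a [scan_geometry()].
#' @return named numeric vector `F1..F6` (dimensionless).
#' @export
f_constants <- function(geom) {
  R <- geom$R
  if (max(abs(crossprod(R) - diag(3))) > 1e-10) stop("non-orthonormal rotation")
  # in-plane parts of the rows of R: <g_i g_j> = g0^2 (u_i . u_j) / 2
  u <- R[, 1:2, drop = FALSE]
  uu <- u %*% t(u)                      # 3x3 matrix of u_i . u_j
  A <- matrix(0, 3, 3)
  A[1, 1] <- A[2, 2] <- uu[3, 3] / 4    # gz^2 (x^2+y^2)/8B0 with <gz^2>=g0^2 u33/2
  A[3, 3] <- uu[1, 1] + uu[2, 2]        # (gx^2+gy^2) z^2 / 2B0
  A[1, 3] <- A[3, 1] <- -uu[1, 3] / 2
  A[2, 3] <- A[3, 2] <- -uu[2, 3] / 2
  Alog <- t(R) %*% A %*% R
  c(F1 = Alog[1, 1], F2 = Alog[2, 2], F3 = Alog[3, 3],
    F4 = 2 * Alog[1, 3], F5 = 2 * Alog[2, 3], F6 = 2 * Alog[1, 2])
}

#' Concomitant offset-frequency map on the slice grid
#'
#' @param geom a [scan_geometry()].
#' @param gm reference maximal readout gradient amplitude (T/m).
#' @param X,Y logical in-plane pixel coordinates (m), matrices or vectors of
#'   equal shape.
#' @return object of class `concomitant_map`: list with `dwc` (same shape as
#'   `X`, rad/s), the `F` constants, `gm` and the geometry.
#' @export
concomitant_offset_map <- function(geom, gm, X, Y) {
  F <- f_constants(geom)
  Xl <- X + geom$fov_shift[1]
  Yl <- Y + geom$fov_shift[2]
  Z <- geom$slice_offset
  q <- F[1] * Xl^2 + F[2] * Yl^2 + F[3] * Z^2 +
    F[4] * Xl * Z + F[5] * Yl * Z + F[6] * Xl * Yl
  dwc <- GAMMA_RAD * gm^2 / (4 * geom$B0) * q
  structure(list(dwc = dwc, F = F, gm = gm, geom = geom),
            class = "concomitant_map")
}

#' Scaled concomitant-field time parameter
#'
#' `mode = "plain"` returns `tc(t) = (1/gm^2) int_0^t g0^2 dt'` for the
#' readout envelope `g0`; `mode = "tse"` recenters it for TSE so the phase
#' conjugation by refocusing pulses is honored:
#' `tcj(t) = (1/gm^2) int_0^t gj^2 dt' - Mj / (2 gm^2)` (`ref =
#' "half-integral"`, the zero falls where half the ring's concomitant
#' integral has accrued) or, with `ref = "echo-center"`, recentred at the
#' temporal spin-echo center of the readout (identical for
#' amplitude-symmetric rings).
#'
#' @param w ring readout: complex gradient vector, [grad_waveform()], or a
#'   ring entry from [design_ring_set()].
#' @param gm reference maximal gradient amplitude (T/m), positive.
#' @param mode `"plain"` or `"tse"`.
#' @param ref recentering rule for `"tse"`.
#' @param dt raster time if `w` is a bare vector.
#' @return numeric vector tc(t) in seconds, one value per raster sample.
#' @export
scaled_time <- function(w, gm, mode = c("plain", "tse"),
                        ref = c("half-integral", "echo-center"), dt = NULL) {
  mode <- match.arg(mode); ref <- match.arg(ref)
  if (gm <= 0) stop("gm must be positive")
  if (is.list(w) && !inherits(w, "grad_waveform")) { dt <- w$dt; g <- w$g }
  else if (inherits(w, "grad_waveform")) { dt <- w$dt; g <- w$g[, 1] + 1i * w$g[, 2] }
  else g <- w
  stopifnot(!is.null(dt))
  g0sq <- Mod(g)^2
  tc <- cumtrapz_dt(g0sq, dt) / gm^2   # value at each raster sample time
  if (mode == "plain") return(tc)
  Mj <- trapz_dt(g0sq, dt)
  if (ref == "half-integral") tc - Mj / (2 * gm^2)
  else {
    i_echo <- floor(length(g0sq) / 2) + 1L
    tc - tc[i_echo]
  }
}
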