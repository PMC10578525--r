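#' Construct a sampled gradient waveform
#'
#' A `grad_waveform` holds per-axis gradient amplitude series on a uniform
#' raster. Axes are the logical frame: 1 = readout 1 (X), 2 = readout 2 (Y),
#' 3 = slice (Z).
#'
#' @param g numeric matrix (n x 3) of gradient amplitudes in T/m, or an n x 2
#'   matrix / complex vector (readout plane only; slice axis padded with 0).
#' @param dt raster time in seconds.
#' @param t0 time of the associated spin echo relative to waveform start (s).
#' @param check validate amplitude/slew limits if `gmax`/`smax` supplied.
#' @param gmax,smax optional hardware limits (T/m, T/m/s) to validate against.
#' @return object of class `grad_waveform`.
#' @export
grad_waveform <- function(g, dt, t0 = 0, check = TRUE, gmax = NULL, smax = NULL) {
  if (is.complex(g)) g <- cbind(Re(g), Im(g))
  g <- as.matrix(g)
  if (ncol(g) == 2L) g <- cbind(g, 0)
  stopifnot(ncol(g) == 3L, dt > 0)
  w <- structure(list(g = g, dt = dt, t0 = t0), class = "grad_waveform")
  if (check && !is.null(gmax)) {
    if (max(abs(g)) > gmax + 1e-12)
      stop(sprintf("gradient amplitude limit violated: max |g| = %.3g > gmax = %.3g T/m",
                   max(abs(g)), gmax))
  }
  if (check && !is.null(smax)) {
    sl <- max(abs(diff(g))) / dt
    if (sl > smax * (1 + 1e-9))
      stop(sprintf("slew limit violated: max |dg|/dt = %.3g > smax = %.3g T/m/s", sl, smax))
  }
  w
}

#' @export
print.grad_waveform <- function(x, ...) {
  cat(sprintf("<grad_waveform> %d samples, dt = %.3g us, duration = %.3g ms, max |g| = %.3g mT/m\n",
              nrow(x$g), x$dt * 1e6, nrow(x$g) * x$dt * 1e3, max(abs(x$g)) * 1e3))
  invisible(x)
}

#' k-space trajectory of a gradient waveform
#'
#' Integrates the gradient (trapezoidal quadrature) to k(t) =
#' k_start + gamma_bar * int_0^t g dt', in cycles/m.
#'
#' @param w a [grad_waveform()] or an n x 3 gradient matrix (then `dt` needed).
#' @param k_start starting k-space position, length-2 or length-3 (cycles/m).
#' @param dt raster time if `w` is a bare matrix.
#' @return n x 3 matrix of k-space positions (cycles/m).
#' @export
kspace_trajectory <- function(w, k_start = c(0, 0, 0), dt = NULL) {
  if (inherits(w, "grad_waveform")) { g <- w$g; dt <- w$dt } else {
    g <- as.matrix(w)
    if (ncol(g) == 2L) g <- cbind(g, 0)
  }
  stopifnot(!is.null(dt))
  if (length(k_start) == 2L) k_start <- c(k_start, 0)
  k <- vapply(1:3, function(a) k_start[a] + GAMMA_BAR * cumtrapz_dt(g[, a], dt),
              numeric(nrow(g)))
  k
}

#' Concomitant-field integral of a waveform
#'
#' Per-axis time integral of the squared gradient, M_axis = int g_axis^2 dt
#' (T^2 s), by trapezoidal quadrature. Additive over waveform concatenation
#' and invariant to gradient sign.
#'
#' @param w a [grad_waveform()] or n x 3 gradient matrix.
#' @param dt raster time if `w` is a bare matrix.
#' @return length-3 numeric vector (X, Y, Z axis integrals).
#' @export
maxwell_integral <- function(w, dt = NULL) {
  if (inherits(w, "grad_waveform")) { g <- w$g; dt <- w$dt } else {
    g <- as.matrix(w); if (ncol(g) == 2L) g <- cbind(g, 0)
  }
  stopifnot(!is.null(dt))
  vapply(1:3, function(a) trapz_dt(g[, a]^2, dt), numeric(1))
}

# concatenate waveforms on a shared raster
concat_waveforms <- function(...) {
  ws <- list(...)
  dt <- ws[[1]]$dt
  stopifnot(all(vapply(ws, function(w) isTRUE(all.equal(w$dt, dt)), logical(1))))
  grad_waveform(do.call(rbind, lapply(ws, `[[`, "g")), dt, check = FALSE)
}
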