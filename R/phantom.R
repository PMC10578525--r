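# Digital phantoms (proton density + relaxation maps) and synthetic smooth
# B0 field maps on a pixel grid with physical coordinates.

# label regions by ellipses (later entries overwrite earlier ones)
ellipse_label <- function(n, ellipses) {
  u <- (seq_len(n) - (n + 1) / 2) / (n / 2)   # normalized [-1, 1)
  X <- matrix(u, n, n); Y <- matrix(u, n, n, byrow = TRUE)
  lab <- matrix(0L, n, n)
  for (i in seq_along(ellipses)) {
    e <- ellipses[[i]]
    ct <- cos(e$phi); st <- sin(e$phi)
    xr <- (X - e$x0) * ct + (Y - e$y0) * st
    yr <- -(X - e$x0) * st + (Y - e$y0) * ct
    lab[(xr / e$a)^2 + (yr / e$b)^2 <= 1] <- e$label
  }
  lab
}

#' Generate a digital phantom
#'
#' Deterministic test objects with proton density and relaxation maps.
#' `"shepp-logan"` is a head-like ellipse phantom with four tissue classes
#' (white-matter-like background, gray-matter-like cortex band, CSF-like
#' ventricles, and high-PD lesions). `"resolution-grid"` is a disk with bar
#' groups at 2/3/4-pixel spacing and uniform vials for blur scoring.
#'
#' @param kind phantom type.
#' @param n matrix size (>= 32).
#' @param pixel pixel size (m).
#' @return object of class `digital_phantom`: PD, T1, T2 (s), B0 (Hz,
#'   initially zero) maps plus grid coordinates `x`, `y` (m, centered).
#' @export
make_phantom <- function(kind = c("shepp-logan", "resolution-grid"), n = 64,
                         pixel = 7.1e-4) {
  kind <- match.arg(kind)
  if (n < 32) stop("matrix size must be at least 32")
  # tissue table: label -> (PD, T1, T2); relaxation values typical of ~0.55T
  tissues <- rbind(
    c(0.00, 1.00, 1.00),   # 0 background (PD 0)
    c(0.75, 0.50, 0.080),  # 1 white-matter-like
    c(0.85, 0.80, 0.100),  # 2 gray-matter-like
    c(1.00, 3.00, 1.500),  # 3 CSF-like
    c(0.95, 1.20, 0.200)   # 4 lesion / vial
  )
  if (kind == "shepp-logan") {
    ell <- list(
      list(x0 = 0, y0 = 0, a = 0.72, b = 0.92, phi = 0, label = 2L),
      list(x0 = 0, y0 = 0, a = 0.65, b = 0.85, phi = 0, label = 1L),
      list(x0 = 0.20, y0 = 0, a = 0.12, b = 0.31, phi = -0.3, label = 3L),
      list(x0 = -0.20, y0 = 0, a = 0.12, b = 0.31, phi = 0.3, label = 3L),
      list(x0 = 0, y0 = 0.35, a = 0.10, b = 0.10, phi = 0, label = 4L),
      list(x0 = 0, y0 = -0.45, a = 0.06, b = 0.06, phi = 0, label = 4L),
      list(x0 = 0.35, y0 = -0.40, a = 0.05, b = 0.08, phi = 0.5, label = 3L)
    )
    lab <- ellipse_label(n, ell)
  } else {
    lab <- ellipse_label(n, list(list(x0 = 0, y0 = 0, a = 0.9, b = 0.9, phi = 0, label = 1L)))
    ctr <- (n + 1) / 2
    for (sp in c(2L, 3L, 4L)) {    # bar groups at 2/3/4-pixel spacing
      row0 <- round(ctr + (sp - 3L) * n / 4.5 - n / 16)
      for (b in 0:3) {
        rows <- row0 + b * 2L * sp + seq_len(sp) - 1L
        cols <- round(ctr - n / 4):round(ctr + n / 4)
        rows <- rows[rows >= 1 & rows <= n]
        lab[rows, cols] <- 3L
      }
    }
    # vials
    lab[ellipse_label(n, list(list(x0 = -0.55, y0 = 0.55, a = 0.12, b = 0.12,
                                   phi = 0, label = 4L))) == 4L] <- 4L
  }
  idx <- lab + 1L
  ph <- structure(list(
    PD = matrix(tissues[idx, 1], n, n),
    T1 = matrix(tissues[idx, 2], n, n),
    T2 = matrix(tissues[idx, 3], n, n),
    B0 = matrix(0, n, n),
    label = lab, n = n, pixel = pixel,
    x = (seq_len(n) - (n + 1) / 2) * pixel,
    y = (seq_len(n) - (n + 1) / 2) * pixel
  ), class = "digital_phantom")
  ph
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %d x %d, pixel %.2f mm, FOV %.1f mm, B0 range [%.1f, %.1f] Hz\n",
              x$n, x$n, x$pixel * 1e3, x$n * x$pixel * 1e3, min(x$B0), max(x$B0)))
  invisible(x)
}

#' Generate a smooth synthetic B0 field map
#'
#' @param n matrix size.
#' @param pixel pixel size (m).
#' @param style `"linear"` (plane), `"polynomial"` (quadratic bowl plus
#'   plane) or `"smooth-random"` (seeded Gaussian-filtered noise).
#' @param amplitude peak |field| in Hz.
#' @param seed RNG seed for `"smooth-random"` (bitwise reproducible).
#' @param B0 optional main field (T); if given, amplitudes beyond the
#'   correction-table working range (80 Hz below 1 T, 150 Hz at/above 1 T)
#'   produce a warning.
#' @param gradient for `"linear"`: Hz/m along (x, y); overrides `amplitude`.
#' @return n x n matrix of off-resonance in Hz.
#' @export
make_field_map <- function(n, pixel, style = c("linear", "polynomial", "smooth-random"),
                           amplitude = 40, seed = 1, B0 = NULL, gradient = NULL) {
  style <- match.arg(style)
  if (!is.null(B0)) {
    lim <- if (B0 < 1) 80 else 150
    if (amplitude > lim)
      warning(sprintf("field-map amplitude %.0f Hz exceeds the %g Hz correction-table range at %.2fT",
                      amplitude, lim, B0))
  }
  u <- (seq_len(n) - (n + 1) / 2) * pixel
  X <- matrix(u, n, n); Y <- matrix(u, n, n, byrow = TRUE)
  ext <- max(abs(u))
  if (style == "linear") {
    if (!is.null(gradient)) return(gradient[1] * X + gradient[2] * Y)
    return(amplitude * (0.6 * X + 0.8 * Y) / ext)
  }
  if (style == "polynomial") {
    m <- 0.5 * (X^2 + 0.6 * Y^2) / ext^2 + 0.4 * X / ext + 0.2 * Y / ext - 0.3
    return(amplitude * m / max(abs(m)))
  }
  # smooth-random: seeded white noise, Gaussian low-pass in k-space
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  w <- matrix(rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  H <- exp(-(outer(f^2, f^2, `+`)) / (2 * (2 / n)^2))
  sm <- Re(fft(fft(w) * H, inverse = TRUE)) / (n * n)
  amplitude * sm / max(abs(sm))
}
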