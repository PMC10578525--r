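# Minimal base-graphics visualization helpers.

#' Display a (complex) image matrix
#'
#' @param img numeric or complex matrix (magnitude shown).
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @export
plot_image <- function(img, main = "", ...) {
  m <- if (is.complex(img)) Mod(img) else img
  graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, main = main, useRaster = TRUE, ...)
}

#' @export
plot.echo_phase_path <- function(x, ...) {
  graphics::plot(x$t * 1e3, x$phi, type = "l", xlab = "time (ms)",
                 ylab = "Maxwell phase (rad)", ...)
  graphics::abline(h = 0, lty = 3)
  idx <- which(x$t %in% x$t)
  graphics::points(x$t[seq_along(x$phi)][match(x$echo_phi, x$phi)] * 1e3,
                   x$echo_phi, col = 2, pch = 16)
  invisible(x)
}

#' @export
plot.digital_phantom <- function(x, what = c("PD", "T1", "T2", "B0"), ...) {
  what <- match.arg(what)
  plot_image(x[[what]], main = what, ...)
  invisible(x)
}

#' k-space trajectory plot of an echo-train sequence
#'
#' @param seq an `echo_train_seq`.
#' @param interleaves which interleaves to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot_trajectory <- function(seq, interleaves = 1, ...) {
  tr <- composite_trajectory(seq, interleaves)
  graphics::plot(Re(tr$k), Im(tr$k), type = "p", pch = ".", asp = 1,
                 xlab = "kx (cycles/m)", ylab = "ky (cycles/m)", ...)
  invisible(seq)
}
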