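# Reconstruction: density-compensated adjoint transforms, Chebyshev
# conjugate-phase correction of concomitant + B0 phase, linear
# pre-corrections, and semiautomatic field-map deblurring.

recon_grid <- function(acq) {
  n <- acq$n
  u <- (seq_len(n) - (n + 1) / 2) * acq$pixel
  list(x = as.vector(matrix(u, n, n)), y = as.vector(matrix(u, n, n, byrow = TRUE)), n = n)
}

acq_weights <- function(acq) {
  if (!is.null(acq$streams[[1]]$w)) return(acq)
  warning("density weights missing; computing them on the fly")
  w <- density_compensation(lapply(acq$streams, `[[`, "k"), fov = acq$fov,
                            retraced = vapply(acq$streams, `[[`, logical(1), "retraced"))
  ofs <- 0L
  for (i in seq_along(acq$streams)) {
    nS <- length(acq$streams[[i]]$s)
    acq$streams[[i]]$w <- w[ofs + seq_len(nS)]
    ofs <- ofs + nS
  }
  acq
}

#' Density-compensated gridding (adjoint transform) reconstruction
#'
#' Adjoint non-uniform discrete Fourier transform of all echo streams onto
#' the image grid, with density-compensation weights. With a sensitivity
#' map, the result is conjugate-weighted (single-coil complex sensitivity).
#'
#' @param acq a `kspace_acq`.
#' @param sens optional complex sensitivity map (n x n).
#' @return complex n x n image matrix.
#' @export
gridding_recon <- function(acq, sens = NULL) {
  acq <- acq_weights(acq)
  gr <- recon_grid(acq)
  img <- rep(0i, gr$n * gr$n)
  for (st in acq$streams) {
    if (length(st$s) == 0L || all(st$s == 0)) next
    img <- img + cpp_adjoint_multi(st$s, st$w, matrix(1, length(st$s), 1),
                                   Re(st$k), Im(st$k), gr$x, gr$y)[, 1]
  }
  img <- matrix(img, gr$n, gr$n)
  if (!is.null(sens)) img <- Conj(sens) * img / pmax(Mod(sens)^2, 1e-9)
  img
}

# Chebyshev polynomial values T_k(u), k = 0..N-1, as an S x N matrix
cheb_basis <- function(u, N) {
  u <- pmin(1, pmax(-1, u))
  th <- acos(u)
  vapply(0:(N - 1L), function(k) cos(k * th), numeric(length(u)))
}

#' Chebyshev-demodulated base images
#'
#' Computes the stack of adjoint reconstructions with Chebyshev time weights
#' T_k(u), u = 2t/tau in [-1, 1], per echo (ring), used by the
#' conjugate-phase combination. Order 0 equals the plain gridding
#' reconstruction of that ring.
#'
#' @param acq a `kspace_acq` with per-echo time axes centered on the spin
#'   echoes; `u` is each acquired segment's normalized time in `[-1, 1]`.
#' @param N number of base images (default 15).
#' @return object of class `base_image_stack`: complex array
#'   `I[pixel, k, segment]` plus grid/N/tau metadata.
#' @export
base_images <- function(acq, N = 15) {
  acq <- acq_weights(acq)
  gr <- recon_grid(acq)
  n_seg <- if (!is.null(acq$n_seg)) acq$n_seg else acq$etl
  I <- array(0i, c(gr$n * gr$n, N, n_seg))
  for (st in acq$streams) {
    basis <- cheb_basis(st$u, N)
    I[, , st$seg] <- I[, , st$seg] +
      cpp_adjoint_multi(st$s, st$w, basis, Re(st$k), Im(st$k), gr$x, gr$y)
  }
  structure(list(I = I, N = N, tau = acq$tau, n_seg = n_seg, n = gr$n,
                 pixel = acq$pixel), class = "base_image_stack")
}

#' Precompute the Chebyshev conjugate-phase coefficient table
#'
#' For every (B0 offset, concomitant offset) node on a regular Hz grid and
#' every ring, computes coefficients `h_k` of the Chebyshev interpolant (N
#' nodes) of the demodulation exponential
#' `exp(+i [dw t + dwc tc_j(t)])` over the readout, in the convention
#' `f(u) ~ sum_k h_k T_k(u) - h_0 / 2`. The TSE scaled time `tc_j` is taken
#' from the acquisition's per-echo streams, so the table is ring-specific.
#'
#' @param acq a `kspace_acq` (supplies `tau` and per-ring `tc`).
#' @param dw_range_hz B0 offset range (Hz), e.g. `c(-80, 80)`.
#' @param dwc_range_hz concomitant offset range (Hz), e.g. `c(0, 400)`.
#' @param N base-image count (default 15).
#' @param dw_step,dwc_step grid increments (Hz), default 1.
#' @param check audit the approximation on sampled nodes and error if the
#'   max modulus error exceeds `tol`.
#' @param check_nodes number of randomly sampled audit nodes per ring.
#' @param tol approximation contract (default 1e-3).
#' @return object of class `coeff_table` with complex array
#'   `h[dw, dwc, k, echo]` and the grids.
#' @export
build_coefficient_table <- function(acq, dw_range_hz = c(-80, 80),
                                    dwc_range_hz = c(0, 400), N = 15,
                                    dw_step = 1, dwc_step = 1,
                                    check = TRUE, check_nodes = 200, tol = 1e-3) {
  dw_hz <- seq(dw_range_hz[1], dw_range_hz[2], by = dw_step)
  dwc_hz <- seq(dwc_range_hz[1], dwc_range_hz[2], by = dwc_step)
  i_nodes <- 0:(N - 1L)
  u_nodes <- cos(pi * (i_nodes + 0.5) / N)
  Cmat <- (2 / N) * cos(outer(i_nodes + 0.5, i_nodes, `*`) * pi / N)  # [node, k]
  n_seg <- if (!is.null(acq$n_seg)) acq$n_seg else acq$etl
  h <- array(0i, c(length(dw_hz), length(dwc_hz), N, n_seg))
  first_of_seg <- sapply(seq_len(n_seg), function(j)
    which(vapply(acq$streams, function(s) s$seg == j, logical(1)))[1])
  worst <- 0; worst_node <- NULL
  for (j in seq_len(n_seg)) {
    st <- acq$streams[[first_of_seg[j]]]
    t_nodes <- stats::approx(st$u, st$t, xout = u_nodes, rule = 2)$y
    tc_nodes <- stats::approx(st$u, st$tc, xout = u_nodes, rule = 2)$y
    E1 <- exp(1i * 2 * pi * outer(dw_hz, t_nodes))     # [A, node]
    E2 <- exp(1i * 2 * pi * outer(dwc_hz, tc_nodes))   # [B, node]
    for (k in seq_len(N))
      h[, , k, j] <- (sweep(E1, 2, Cmat[, k], `*`)) %*% t(E2)
    if (check) {
      sub <- seq(1, length(st$t), by = max(1L, length(st$t) %/% 64L))
      Tb <- cheb_basis(st$u[sub], N)
      ia <- sample.int(length(dw_hz), check_nodes, replace = TRUE)
      ib <- sample.int(length(dwc_hz), check_nodes, replace = TRUE)
      for (q in seq_len(check_nodes)) {
        hk <- h[ia[q], ib[q], , j]
        appr <- as.vector(Tb %*% hk) - hk[1] / 2
        exact <- exp(1i * 2 * pi * (dw_hz[ia[q]] * st$t[sub] + dwc_hz[ib[q]] * st$tc[sub]))
        err <- max(Mod(appr - exact))
        if (err > worst) { worst <- err; worst_node <- c(dw_hz[ia[q]], dwc_hz[ib[q]], j) }
      }
    }
  }
  if (check && worst > tol)
    stop(sprintf(paste0("coefficient-table contract violated: max error %.2e at ",
                        "(dw = %g Hz, dwc = %g Hz, segment %d); increase N"),
                 worst, worst_node[1], worst_node[2], worst_node[3]))
  structure(list(h = h, dw_hz = dw_hz, dwc_hz = dwc_hz, N = N, tau = acq$tau,
                 n_seg = n_seg, check_err = if (check) worst else NA_real_),
            class = "coeff_table")
}

#' Audit a coefficient table against dense evaluation
#'
#' Maximum modulus error of the Chebyshev approximant over a dense time grid
#' at randomly sampled table nodes.
#'
#' @param table a `coeff_table`.
#' @param acq the acquisition the table was built for.
#' @param n_nodes sampled nodes per ring.
#' @return max modulus error across sampled nodes.
#' @export
audit_coefficient_table <- function(table, acq, n_nodes = 1000) {
  worst <- 0
  first_of_seg <- sapply(seq_len(table$n_seg), function(j)
    which(vapply(acq$streams, function(s) s$seg == j, logical(1)))[1])
  for (j in seq_len(table$n_seg)) {
    st <- acq$streams[[first_of_seg[j]]]
    sub <- seq(1, length(st$t), by = max(1L, length(st$t) %/% 128L))
    Tb <- cheb_basis(st$u[sub], table$N)
    ia <- sample.int(length(table$dw_hz), n_nodes, replace = TRUE)
    ib <- sample.int(length(table$dwc_hz), n_nodes, replace = TRUE)
    for (q in seq_len(n_nodes)) {
      hk <- table$h[ia[q], ib[q], , j]
      appr <- as.vector(Tb %*% hk) - hk[1] / 2
      exact <- exp(1i * 2 * pi * (table$dw_hz[ia[q]] * st$t[sub] +
                                  table$dwc_hz[ib[q]] * st$tc[sub]))
      worst <- max(worst, max(Mod(appr - exact)))
    }
  }
  worst
}

#' Conjugate-phase combination of base images
#'
#' Per-pixel nearest-node coefficient lookup and ring-matched weighted sum
#' of the base images:
#' `m(r) = sum_j sum_k h_k(dw(r) + dwi, dwc(r)) I_k,j(r) - h_0 I_0,j(r)/2`.
#' With zero maps this reduces to the gridding reconstruction.
#'
#' @param stack a `base_image_stack`.
#' @param table a `coeff_table`.
#' @param dw_hz B0 off-resonance map (Hz), matrix or vector over pixels.
#' @param dwc_hz concomitant offset map (Hz).
#' @param dwi constant frequency shift added to `dw_hz` (Hz).
#' @return complex n x n image.
#' @export
conjugate_phase_combine <- function(stack, table, dw_hz = 0, dwc_hz = 0, dwi = 0) {
  P <- stack$n^2
  dw <- rep_len(as.vector(dw_hz), P) + dwi
  dwc <- rep_len(as.vector(dwc_hz), P)
  A <- length(table$dw_hz); B <- length(table$dwc_hz)
  ia <- round((dw - table$dw_hz[1]) / (table$dw_hz[2] - table$dw_hz[1])) + 1L
  ib <- if (B > 1L) round((dwc - table$dwc_hz[1]) / (table$dwc_hz[2] - table$dwc_hz[1])) + 1L
        else rep(1L, P)
  n_clamp <- sum(ia < 1L | ia > A | ib < 1L | ib > B)
  if (n_clamp > 0)
    warning(sprintf("%d pixels outside the coefficient-table range were clamped", n_clamp))
  ia <- pmin(A, pmax(1L, ia)); ib <- pmin(B, pmax(1L, ib))
  node <- ia + (ib - 1L) * A
  img <- rep(0i, P)
  Hflat <- array(table$h, c(A * B, table$N, table$n_seg))
  for (j in seq_len(stack$n_seg)) {
    hk <- Hflat[node, , j]
    img <- img + rowSums(hk * stack$I[, , j]) - 0.5 * hk[, 1] * stack$I[, 1, j]
  }
  matrix(img, stack$n, stack$n)
}

#' Estimate a B0 field map from dual-TE images
#'
#' `dw_hz = angle(img2 conj(img1)) / (2 pi dTE)`, masked where the magnitude
#' is below `mask_frac` of its maximum. Unambiguous for offsets below
#' `1/(2 dTE)`; larger offsets wrap.
#'
#' @param img1,img2 complex images at the two echo times.
#' @param dTE echo-time difference (s).
#' @param mask_frac magnitude threshold fraction.
#' @return list with `map_hz` (masked entries 0), `mask` (logical matrix).
#' @export
estimate_field_map <- function(img1, img2, dTE, mask_frac = 0.1) {
  mask <- Mod(img1) >= mask_frac * max(Mod(img1))
  # signal phase evolves as exp(-i dw t), so the longer-TE image carries the
  # more negative phase; conjugate accordingly to return dw on the forward
  # model's sign convention
  map <- Arg(img1 * Conj(img2)) / (2 * pi * dTE)
  map[!mask] <- 0
  list(map_hz = map, mask = mask)
}

# least-squares plane fit a0 + ax X + ay Y over masked pixels
plane_fit <- function(map, pixel, mask = NULL) {
  n <- nrow(map)
  u <- (seq_len(n) - (n + 1) / 2) * pixel
  X <- matrix(u, n, n); Y <- matrix(u, n, n, byrow = TRUE)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  df <- data.frame(f = map[mask], X = X[mask], Y = Y[mask])
  co <- coef(lm(f ~ X + Y, data = df))
  list(a0 = co[[1]], ax = co[[2]], ay = co[[3]],
       plane = co[[1]] + co[[2]] * X + co[[3]] * Y)
}

#' Linear B0 and concomitant pre-corrections
#'
#' Removes the constant and in-plane-linear parts of the B0 and concomitant
#' offset maps from the raw data before conjugate-phase reconstruction:
#' constants are demodulated per sample (with `t` for B0 and the ring's
#' scaled time `tc` for the concomitant term), linear parts become
#' time-dependent trajectory shifts. This shrinks the residual map ranges to
#' roughly those of an isocenter slice, keeping the coefficient table small.
#'
#' @param acq a `kspace_acq`.
#' @param dw_hz B0 map (Hz) or NULL.
#' @param dwc_hz concomitant offset map (Hz) or NULL.
#' @param mask logical matrix restricting the plane fits.
#' @return list with the corrected `acq`, residual maps `dw_res`/`dwc_res`
#'   (Hz), and the fitted `applied` plane parameters.
#' @export
linear_corrections <- function(acq, dw_hz = NULL, dwc_hz = NULL, mask = NULL) {
  applied <- list()
  dw_res <- dwc_res <- NULL
  if (!is.null(dw_hz)) {
    pf <- plane_fit(dw_hz, acq$pixel, mask)
    applied$dw <- pf
    dw_res <- dw_hz - pf$plane
    for (i in seq_along(acq$streams)) {
      st <- acq$streams[[i]]
      st$s <- st$s * exp(2i * pi * pf$a0 * st$t)
      st$k <- st$k + (pf$ax * st$t) + 1i * (pf$ay * st$t)
      acq$streams[[i]] <- st
    }
  }
  if (!is.null(dwc_hz)) {
    pf <- plane_fit(dwc_hz, acq$pixel, mask)
    applied$dwc <- pf
    dwc_res <- dwc_hz - pf$plane
    mn <- min(dwc_res)
    if (mn < 0) {            # keep the residual concomitant range nonnegative
      pf$a0 <- pf$a0 + mn
      dwc_res <- dwc_res - mn
      applied$dwc <- pf
    }
    for (i in seq_along(acq$streams)) {
      st <- acq$streams[[i]]
      st$s <- st$s * exp(2i * pi * pf$a0 * st$tc)
      st$k <- st$k + (pf$ax * st$tc) + 1i * (pf$ay * st$tc)
      acq$streams[[i]] <- st
    }
  }
  list(acq = acq, dw_res = dw_res, dwc_res = dwc_res, applied = applied)
}

# separable Gaussian blur with edge renormalization
gauss_blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kx <- exp(-((-r):r)^2 / (2 * sigma^2))
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- kx[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' Semiautomatic B0 deblurring by local energy maximization
#'
#' Reconstructs candidate images `m(r; dwi)` over a grid of constant
#' frequency shifts added to the low-resolution constraint map, smooths each
#' candidate's squared magnitude with a circularly symmetric Gaussian, and
#' selects per pixel the shift maximizing the local energy (ties broken
#' toward the smallest |dwi|). Returns the assembled image and the
#' high-resolution field map `dw_hz + dwi*`.
#'
#' @param stack a `base_image_stack`.
#' @param table a `coeff_table` covering `range(dw_hz) + range(search_hz)`.
#' @param dw_hz low-resolution B0 constraint map (Hz).
#' @param dwc_hz concomitant offset map (Hz).
#' @param search_hz candidate shifts (Hz), default -60..60 by 10.
#' @param kernel_sigma Gaussian kernel sigma (pixels). The window must be
#'   wider than the off-resonance point-spread so edge pixels are voted by
#'   the surrounding tissue rather than by maximal spreading; default 8.
#' @param median3 apply a 3x3 median filter to the selected-shift map.
#' @return list with `image`, `map_hi_hz`, `dwi_star`, `search_hz`.
#' @export
semiauto_deblur <- function(stack, table, dw_hz = 0, dwc_hz = 0,
                            search_hz = seq(-60, 60, by = 10),
                            kernel_sigma = 8, median3 = FALSE) {
  ord <- order(abs(search_hz), search_hz)   # smallest |dwi| first
  n <- stack$n
  best_e <- matrix(-Inf, n, n)
  best_i <- matrix(search_hz[ord[1]], n, n)
  best_img <- matrix(0i, n, n)
  for (s in ord) {
    dwi <- search_hz[s]
    img <- conjugate_phase_combine(stack, table, dw_hz, dwc_hz, dwi = dwi)
    e <- gauss_blur2d(Mod(img)^2, kernel_sigma)
    upd <- e > best_e            # strict: earlier (smaller |dwi|) wins ties
    best_e[upd] <- e[upd]
    best_i[upd] <- dwi
    best_img[upd] <- img[upd]
  }
  if (median3) {
    pad <- rbind(best_i[1, ], best_i, best_i[n, ])
    pad <- cbind(pad[, 1], pad, pad[, n])
    med <- best_i
    for (i in 1:n) for (j in 1:n)
      med[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
    best_i <- med
  }
  map_hi <- (if (length(dw_hz) == 1L) matrix(dw_hz, n, n) else dw_hz) + best_i
  list(image = best_img, map_hi_hz = map_hi, dwi_star = best_i,
       search_hz = search_hz)
}
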