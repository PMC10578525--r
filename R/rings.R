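#' Annulus partition of the k-space disk
#'
#' Splits `[0, kmax]` into `etl` annuli. `"balanced"` (default) makes annulus
#' areas proportional to the per-ring sampling time (the central retraced
#' annulus counts twice because it is traversed in and out), which equalizes
#' the readout gradient amplitude across rings and thereby minimizes the
#' worst-ring concomitant field integral. `"equal-area"` and `"equal-width"`
#' are the textbook alternatives; equal width concentrates path length (and
#' Maxwell phase) in the outer rings.
#'
#' @param kmax disk radius, cycles/m.
#' @param etl number of annuli (= echoes per shot).
#' @param partition partition rule.
#' @return numeric vector of annulus boundaries, length `etl + 1`, from 0.
#' @export
annulus_partition <- function(kmax, etl,
                              partition = c("balanced", "equal-area", "equal-width")) {
  partition <- match.arg(partition)
  j <- 0:etl
  b <- switch(partition,
    "equal-width" = kmax * j / etl,
    "equal-area"  = kmax * sqrt(j / etl),
    "balanced"    = kmax * sqrt(pmax(0, j - 0.5) / (etl - 0.5))
  )
  b[1] <- 0
  b[etl + 1] <- kmax
  b
}

# Archimedean spiral-out segment covering [k1, k2] with n_int interleaves,
# traversed in `dur` seconds at (approximately) constant path speed with
# raised-cosine end ramps and a centripetal slew limit near the center.
# Returns readout-plane gradients as a complex vector plus the spiral-law k.
spiral_segment <- function(k1, k2, n_int, fov, gmax, smax, dt, dur, phase0 = 0) {
  a <- n_int / (2 * pi * fov)           # radial pitch: composite spacing 1/fov
  th1 <- k1 / a; th2 <- k2 / a
  n <- max(8L, round(dur / dt))
  tt <- (seq_len(n) - 0.5) / n          # midpoint times, fraction of dur
  t_ramp <- min(0.15, max(0.02, 6e-4 / dur))  # ramp fraction of duration
  env <- pmin(1, pmin(tt, 1 - tt) / t_ramp)
  env <- (1 - cos(pi * pmin(1, env))) / 2     # raised-cosine end ramps
  smax_c <- 0.7 * smax                   # centripetal share of the slew budget
  vmax_hw <- 0.995 * GAMMA_BAR * gmax

  advance <- function(v0) {
    th <- numeric(n + 1L); th[1] <- th1
    thd <- numeric(n)
    for (i in seq_len(n)) {
      kap <- (th[i]^2 + 2) / (a * (1 + th[i]^2)^1.5)  # spiral curvature
      vlim <- sqrt(smax_c * GAMMA_BAR / kap)
      v <- min(v0 * env[i], vlim)
      thd[i] <- v / (a * sqrt(1 + th[i]^2))
      th[i + 1L] <- th[i] + thd[i] * dt
    }
    list(theta = th, theta_dot = thd)
  }
  reach <- function(v0) advance(v0)$theta[n + 1L] - th2

  if (reach(vmax_hw) < 0)
    stop(sprintf(paste0("infeasible spiral segment: amplitude limit gmax = %.3g mT/m ",
                        "cannot cover [%.1f, %.1f] cycles/m in %.3g ms"),
                 gmax * 1e3, k1, k2, dur * 1e3))
  lo <- 0; hi <- vmax_hw
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (reach(mid) < 0) lo <- mid else hi <- mid
  }
  sol <- advance(hi)
  th <- sol$theta[seq_len(n)]
  # gradients from central differences of the spiral law so the trapezoidal
  # k-space integral reproduces the law without a half-step bias (end speeds
  # vanish, so zeroing the end samples is exact)
  k_law <- a * sol$theta * exp(1i * (sol$theta + phase0))
  g <- rep(0i, n)
  g[2:(n - 1L)] <- (k_law[3:n] - k_law[1:(n - 2L)]) / (2 * dt * GAMMA_BAR)
  slew <- max(abs(diff(g))) / dt
  if (slew > smax * (1 + 1e-6))
    stop(sprintf("infeasible spiral segment: slew limit smax = %.3g T/m/s exceeded (%.3g)",
                 smax, slew))
  if (max(abs(c(Re(g), Im(g)))) > gmax * (1 + 1e-6))
    stop(sprintf("infeasible spiral segment: per-axis amplitude exceeds gmax = %.3g mT/m",
                 gmax * 1e3))
  list(g = g, theta = th, a = a, k_law = k_law[seq_len(n)])
}

#' Design a single spiral-ring readout waveform
#'
#' Builds the readout-plane gradient waveform for one annulus:
#' `"spiral-out"` traverses `[k_inner, k_outer]` outward, `"spiral-in"` is the
#' time-reversed waveform with negated polarity, and `"retraced-in-out"`
#' (only for the central annulus, `k_inner = 0`) plays the negated-reverse of
#' a half-duration spiral-out followed by the spiral-out itself, so the in
#' half exactly retraces the out half and k = 0 is crossed at the temporal
#' center.
#'
#' @param k_inner,k_outer annulus radii (cycles/m).
#' @param n_int interleaves sharing the annulus.
#' @param fov field of view (m); sets the composite radial pitch 1/fov.
#' @param gmax,smax hardware limits (T/m, T/m/s).
#' @param dt raster time (s).
#' @param dur readout duration (s).
#' @param direction ring type.
#' @param phase0 starting azimuth (rad).
#' @return list with complex gradient `g` (readout plane), complex sampled
#'   trajectory `k`, echo-center sample index `i_echo`, and the annulus spec.
#' @export
spiral_ring_waveform <- function(k_inner, k_outer, n_int, fov, gmax, smax, dt, dur,
                                 direction = c("spiral-out", "spiral-in", "retraced-in-out"),
                                 phase0 = 0) {
  direction <- match.arg(direction)
  if (direction == "retraced-in-out") {
    if (k_inner > 1e-9) stop("retraced-in-out ring must cover k = 0")
    half <- spiral_segment(0, k_outer, n_int, fov, gmax, smax, dt, dur / 2, phase0)
    g <- c(-rev(half$g), half$g)
    k_start <- half$k_law[length(half$k_law)]
  } else {
    seg <- spiral_segment(k_inner, k_outer, n_int, fov, gmax, smax, dt, dur, phase0)
    if (direction == "spiral-out") {
      g <- seg$g
      k_start <- seg$k_law[1]
    } else {
      g <- -rev(seg$g)
      k_start <- seg$k_law[length(seg$k_law)]
    }
  }
  kxy <- kspace_trajectory(cbind(Re(g), Im(g)), k_start = c(Re(k_start), Im(k_start)), dt = dt)
  k <- kxy[, 1] + 1i * kxy[, 2]
  i_echo <- floor(length(g) / 2) + 1L
  # acquisition window: the constant-speed plateau (the ADC is off during the
  # slew-limited entry/exit ramps); the self-retraced ring is split into
  # sub-segments per half so the slow gradient reversal around k = 0 sits at
  # segment ends, keeping each segment's scaled time low-order smooth
  glev <- stats::quantile(abs(Mod(g)), 0.8)
  plat <- which(Mod(g) >= 0.98 * glev)
  segs <- if (direction == "retraced-in-out") {
    i1 <- min(plat); i2 <- max(plat)
    c1 <- round(i1 + 0.85 * (i_echo - i1))
    c2 <- round(i_echo + 1 + 0.15 * (i2 - i_echo - 1))
    list(i1:c1, (c1 + 1L):i_echo, (i_echo + 1L):c2, (c2 + 1L):i2)
  } else list(min(plat):max(plat))
  list(g = g, k = k, i_echo = i_echo, acq_segments = segs,
       k_inner = k_inner, k_outer = k_outer, direction = direction,
       n_int = n_int, phase0 = phase0, dt = dt)
}

#' Design a SPRING-RIO spiral-ring echo train
#'
#' Generates the full set of ring readouts for one shot: spiral-in rings
#' first (outermost annulus at echo 1, moving inward), the self-retraced
#' central ring at the effective-TE echo, then spiral-out rings moving back
#' outward. Also lays out the echo-spacing timing (RF/crusher block, bipolar
#' compensation slots, prephaser/rewinder slots around each readout) and the
#' slice-axis events; bipolar compensation gradients are added separately by
#' [compensate_sequence()].
#'
#' @param fov field of view (m).
#' @param resolution pixel size (m); `kmax = 1/(2 resolution)`.
#' @param etl echo train length (= number of annuli).
#' @param n_shots interleaves per annulus.
#' @param gmax,smax gradient amplitude (T/m) and slew (T/m/s) limits.
#' @param dt raster time (s), default 10 us.
#' @param readout_dur per-echo readout duration (s).
#' @param partition annulus partition rule, see [annulus_partition()].
#' @param even_central `"error"` rejects even `etl`; `"floor"` places the
#'   central retraced ring at echo `etl/2`.
#' @param bip_slot duration reserved before and after each readout for
#'   bipolar compensation pairs (s), default 2.5 ms.
#' @return an object of class `echo_train_seq`.
#' @export
design_ring_set <- function(fov, resolution, etl, n_shots,
                            gmax = 0.021, smax = 120, dt = 1e-5,
                            readout_dur = 0.016,
                            partition = c("balanced", "equal-area", "equal-width"),
                            even_central = c("error", "floor"),
                            bip_slot = 2.5e-3) {
  partition <- match.arg(partition)
  even_central <- match.arg(even_central)
  stopifnot(fov > 0, resolution > 0, etl >= 3, n_shots >= 1)
  kmax <- 1 / (2 * resolution)
  if (etl %% 2 == 0) {
    if (even_central == "error")
      stop("etl is even: central ring placement ambiguous; set even_central = \"floor\"")
    central <- etl %/% 2L
  } else central <- (etl + 1L) %/% 2L
  n_in <- central - 1L
  n_out <- etl - central

  b <- annulus_partition(kmax, etl, partition)
  # echo -> annulus index (annulus 1 central) and direction
  ann <- integer(etl); dirn <- character(etl)
  for (e in seq_len(etl)) {
    if (e < central) { ann[e] <- etl - e + 1L; dirn[e] <- "spiral-in" }
    else if (e == central) { ann[e] <- 1L; dirn[e] <- "retraced-in-out" }
    else { ann[e] <- e - central + 1L; dirn[e] <- "spiral-out" }
  }

  rings <- vector("list", etl)
  for (e in seq_len(etl)) {
    a_i <- ann[e]
    # all annuli share the same spiral law (phase0 = 0), so consecutive rings
    # continue one Archimedean spiral and the composite radial pitch stays
    # uniform across annulus boundaries
    rings[[e]] <- spiral_ring_waveform(b[a_i], b[a_i + 1L], n_shots, fov, gmax, smax,
                                       dt, readout_dur, dirn[e])
    rings[[e]]$echo <- e
    rings[[e]]$annulus <- a_i
  }

  # prephaser/rewinder slot: fixed trapezoid shape (25% ramps), amplitude
  # scaled per axis to the needed zeroth moment
  max_mom <- max(vapply(rings, function(r)
    max(abs(c(Re(r$k[1]), Im(r$k[1]), Re(r$k[length(r$k)]), Im(r$k[length(r$k)]))))
    , numeric(1))) / GAMMA_BAR
  pre_slot <- max(4e-4, round((max_mom / (0.85 * gmax) / 0.75) / dt) * dt + 2 * dt)

  layout <- list(
    rf_plateau = 2.5e-3, g_ss = 6e-3,
    crusher_slot = 1.6e-3, crusher_area = 2e-5,
    bip_slot = bip_slot, pre_slot = pre_slot,
    exc_reph_slot = 8e-4
  )
  esp <- layout$rf_plateau + 2 * layout$crusher_slot + 2 * bip_slot +
    2 * pre_slot + readout_dur
  esp <- round(esp / dt) * dt
  exc_content <- layout$rf_plateau / 2 + layout$exc_reph_slot + 2 * bip_slot +
    layout$crusher_slot + layout$rf_plateau / 2
  if (esp / 2 < exc_content)
    stop("echo spacing too short to lay out the excitation interval")

  structure(list(
    etl = etl, central_echo = central, n_in = n_in, n_out = n_out,
    esp = esp, dt = dt, rings = rings, layout = layout,
    bipolars = NULL, crusher_scale_first = 1,
    compensated = "none",
    meta = list(fov = fov, resolution = resolution, kmax = kmax,
                n_shots = n_shots, gmax = gmax, smax = smax,
                readout_dur = readout_dur, gm = gmax, partition = partition)
  ), class = "echo_train_seq")
}

#' @export
print.echo_train_seq <- function(x, ...) {
  cat(sprintf("<echo_train_seq> ETL %d (central echo %d), ESP %.2f ms, readout %.1f ms\n",
              x$etl, x$central_echo, x$esp * 1e3, x$meta$readout_dur * 1e3))
  cat(sprintf("  kmax %.1f cycles/m, %d shots, partition '%s', compensation: %s\n",
              x$meta$kmax, x$meta$n_shots, x$meta$partition, x$compensated))
  amp <- vapply(x$rings, function(r) max(abs(r$g)), numeric(1))
  cat(sprintf("  ring max |g| (mT/m): %s\n", paste(sprintf("%.1f", amp * 1e3), collapse = " ")))
  invisible(x)
}

#' Density compensation weights for a sampled trajectory
#'
#' Computes per-sample k-space area weights. For ring trajectories
#' (`mode = "rings"`) each sample covers (path spacing) x (radial pitch
#' `1/fov`); retraced rings (doubly sampled annuli) get half weight. For
#' radial-spoke-like inputs (`mode = "radial"`) the polar Jacobian
#' |k| x (path spacing) x (azimuthal increment) applies.
#'
#' @param k complex vector (or list of complex vectors, one per ring stream)
#'   of sample positions, cycles/m.
#' @param fov field of view (m), sets the radial pitch for `mode = "rings"`.
#' @param mode weighting rule; `"voronoi-grid"` computes Voronoi cell areas
#'   by fine-grid nearest-neighbor assignment over the sampled disk.
#' @param retraced logical per stream: stream covers its annulus twice.
#' @param n_spokes azimuthal count for `mode = "radial"`.
#' @param cell grid cell size for `"voronoi-grid"` (cycles/m; default
#'   pitch/6).
#' @return numeric vector of nonnegative weights, one per sample (streams
#'   concatenated).
#' @export
density_compensation <- function(k, fov = NULL,
                                 mode = c("rings", "radial", "voronoi-grid"),
                                 retraced = NULL, n_spokes = 1, cell = NULL) {
  mode <- match.arg(mode)
  if (mode == "voronoi-grid") {
    kk <- unlist(k)
    stopifnot(!is.null(fov))
    dk <- 1 / fov
    if (is.null(cell)) cell <- dk / 6
    ex <- max(Mod(kk)) + dk
    g <- seq(-ex, ex, by = cell)
    GX <- rep(g, times = length(g)); GY <- rep(g, each = length(g))
    keep <- GX^2 + GY^2 <= (max(Mod(kk)) + dk / 2)^2
    asg <- cpp_nn_assign(GX[keep], GY[keep], Re(kk), Im(kk), dk)
    return(tabulate(asg, nbins = length(kk)) * cell^2)
  }
  if (!is.list(k)) k <- list(k)
  if (is.null(retraced)) retraced <- rep(FALSE, length(k))
  stopifnot(length(retraced) == length(k))
  ws <- vector("list", length(k))
  for (s in seq_along(k)) {
    kk <- k[[s]]
    n <- length(kk)
    d <- abs(diff(kk))
    ds <- if (n == 1L) 0 else c(d[1], (d[-1] + d[-(n - 1)]) / 2, d[n - 1L])
    w <- switch(mode,
      rings = { stopifnot(!is.null(fov)); ds / fov },
      radial = abs(kk) * ds * (2 * pi / n_spokes)
    )
    if (retraced[s]) w <- w / 2
    ws[[s]] <- w
  }
  w <- unlist(ws)
  kk_all <- unlist(k)
  # duplicate positions beyond the retrace pairing: split weight evenly
  key <- paste(round(Re(kk_all), 6), round(Im(kk_all), 6))
  from_retrace <- unlist(mapply(function(kki, r) rep(r, length(kki)),
                                k, retraced, SIMPLIFY = FALSE))
  scan <- !from_retrace
  if (any(scan)) {
    tab <- table(key[scan])
    dup <- names(tab)[tab > 1L]
    if (length(dup)) {
      idx <- scan & key %in% dup
      # adjacent in-stream duplicates already share their path spacing
      adj <- c(FALSE, diff(match(key, unique(key))) == 0)
      idx <- idx & !(adj | c(adj[-1], FALSE))
      if (any(idx)) {
        warning("duplicate k-space sample positions beyond retrace pairing; splitting weights")
        mult <- as.numeric(tab[key[idx]])
        w[idx] <- w[idx] / mult
      }
    }
  }
  # strictly positive floor so the k = 0 sample never gets a singular weight
  wfloor <- if (!is.null(fov)) 1e-3 * (1 / fov)^2 else 1e-6 * max(w)
  w <- pmax(w, wfloor)
  if (mode == "rings" && !is.null(fov)) {
    # near k = 0 the path-times-pitch area model breaks down (the spiral turn
    # geometry is strongly curved); renormalize the innermost shells to the
    # exact polar area share, calibrated against the well-conditioned
    # mid-radius region
    dk <- 1 / fov
    kr <- Mod(kk_all)
    kmax <- max(kr)
    C <- sum(w) / (pi * kmax^2)
    for (sh in 0:ceiling(kmax / dk)) {
      sel <- kr >= sh * dk & kr < (sh + 1) * dk
      if (!any(sel)) next
      target <- C * pi * (min(kmax, (sh + 1) * dk)^2 - (sh * dk)^2)
      w[sel] <- w[sel] * target / sum(w[sel])
    }
  }
  w
}

#' Composite k-space trajectory of an echo-train sequence
#'
#' @param seq an `echo_train_seq`.
#' @param interleaves which interleaves (default all `n_shots`).
#' @return list with per-(echo, interleave) complex sample streams `k`, the
#'   matching ring echo indices, retrace flags, and concatenated vectors.
#' @export
composite_trajectory <- function(seq, interleaves = seq_len(seq$meta$n_shots)) {
  streams <- list(); echo_id <- integer(0); retr <- logical(0)
  for (m in interleaves) {
    rot <- exp(1i * 2 * pi * (m - 1) / seq$meta$n_shots)
    for (r in seq$rings) {
      streams[[length(streams) + 1L]] <- r$k * rot
      echo_id <- c(echo_id, r$echo)
      retr <- c(retr, r$direction == "retraced-in-out")
    }
  }
  list(streams = streams, echo = echo_id, retraced = retr,
       k = unlist(streams))
}
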