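# Forward simulation of multi-echo spiral-ring k-space acquisitions:
# discrete pixel-sum of the signal model with trajectory encoding, B0
# off-resonance, concomitant phase (echo-train pathway + intra-readout
# scaled-time term), optional EPG echo-train weighting and complex noise.

phantom_grid <- function(ph) {
  n <- ph$n
  list(X = matrix(ph$x, n, n), Y = matrix(ph$y, n, n, byrow = TRUE))
}

# Eq.-13-style conjugated pathway phase at each spin-echo center
pathway_echo_phase <- function(sched) {
  etl <- nrow(sched$pre)
  m <- length(sched$exc)
  phi <- matrix(0, etl, m)
  run <- sched$exc
  for (j in seq_len(etl)) {
    run <- -run + sched$pre[j, ]
    phi[j, ] <- run
    run <- run + sched$post[j, ]
  }
  phi
}

#' Simulate a multi-echo spiral-ring k-space acquisition
#'
#' Discrete sum over phantom pixels of the TSE signal model per echo:
#' trajectory encoding, B0 off-resonance phase (time referenced to each
#' spin-echo center), concomitant phase as the echo-train pathway value at
#' the echo center plus the intra-readout term `dwc(r) tc_j(t)`, and either
#' EPG complex echo-train weighting (flip-angle and Maxwell-pathway
#' dependent) or plain T2 decay with the conjugated pathway phase.
#'
#' @param ph a [make_phantom()] phantom; its `B0` field (Hz) is the
#'   off-resonance map.
#' @param seq an `echo_train_seq` whose FOV/resolution match the phantom.
#' @param geom a [scan_geometry()].
#' @param maxwell include concomitant-field effects.
#' @param b0 include B0 off-resonance effects.
#' @param epg_weighting use EPG complex echo amplitudes per pixel (otherwise
#'   pure T2 decay times the pathway phase).
#' @param flip refocusing flip angle for the EPG weighting (degrees).
#' @param noise_sd complex Gaussian noise standard deviation (per channel).
#' @param seed RNG seed for the noise.
#' @param interleaves which interleaves to acquire (default all).
#' @param cross_terms include Maxwell cross-terms in the pathway phase.
#' @return object of class `kspace_acq`.
#' @export
simulate_kspace <- function(ph, seq, geom, maxwell = TRUE, b0 = TRUE,
                            epg_weighting = TRUE, flip = 150,
                            noise_sd = 0, seed = NULL,
                            interleaves = seq_len(seq$meta$n_shots),
                            cross_terms = FALSE) {
  if (abs(ph$pixel - seq$meta$resolution) > 1e-9 * max(ph$pixel, seq$meta$resolution) ||
      abs(ph$n * ph$pixel - seq$meta$fov) > 1e-6)
    stop("phantom grid and sequence FOV/resolution do not match")
  gr <- phantom_grid(ph)
  mask <- ph$PD > 0
  xs <- gr$X[mask]; ys <- gr$Y[mask]
  P <- sum(mask)
  dwc <- if (maxwell) concomitant_offset_map(geom, seq$meta$gm, gr$X, gr$Y)$dwc[mask]
         else rep(0, P)
  dw <- if (b0) 2 * pi * ph$B0[mask] else rep(0, P)
  probes <- slice_to_physical(geom, gr$X[mask], gr$Y[mask])
  sched <- if (maxwell) epg_phase_schedule(seq, geom, probes, cross_terms = cross_terms)
           else list(exc = rep(0, P), pre = matrix(0, seq$etl, P),
                     post = matrix(0, seq$etl, P))
  T2v <- ph$T2[mask]; T1v <- ph$T1[mask]
  if (epg_weighting) {
    amp <- epg_echo_train(seq$etl, seq$esp, T1v, T2v, alpha = flip, phases = sched)
  } else {
    dec <- exp(-outer(seq_len(seq$etl) * seq$esp, 1 / T2v))
    amp <- dec * exp(-1i * pathway_echo_phase(sched))
  }
  if (!is.null(seed)) set.seed(seed)
  # density weights from the full (unsplit) ring trajectories, then subset to
  # the acquired plateau segments
  w_ring <- density_compensation(lapply(seq$rings, `[[`, "k"), fov = seq$meta$fov,
                                 retraced = vapply(seq$rings, function(r)
                                   r$direction == "retraced-in-out", logical(1)))
  w_ofs <- c(0, cumsum(vapply(seq$rings, function(r) length(r$k), numeric(1))))
  seg_id0 <- c(0, cumsum(vapply(seq$rings, function(r) length(r$acq_segments), numeric(1))))
  streams <- list()
  for (m in interleaves) {
    rot <- exp(1i * 2 * pi * (m - 1) / seq$meta$n_shots)
    for (j in seq_len(seq$etl)) {
      r <- seq$rings[[j]]
      kk_full <- r$k * rot
      tt_full <- (seq_along(kk_full) - r$i_echo) * seq$dt
      tc_full <- if (maxwell) scaled_time(r, seq$meta$gm, mode = "tse", ref = "echo-center")
                 else rep(0, length(kk_full))
      meff <- complex(real = ph$PD[mask]) * amp[j, ]
      for (sgi in seq_along(r$acq_segments)) {
        idx <- r$acq_segments[[sgi]]
        kk <- kk_full[idx]; tt <- tt_full[idx]; tc <- tc_full[idx]
        nS <- length(kk)
        s <- cpp_sim_echo(meff, xs, ys, dw, dwc, Re(kk), Im(kk), tt, tc)
        if (noise_sd > 0)
          s <- s + complex(real = rnorm(nS, sd = noise_sd),
                           imaginary = rnorm(nS, sd = noise_sd))
        streams[[length(streams) + 1L]] <- list(
          s = s, k = kk, t = tt, tc = tc,
          u = 2 * (tt - mean(range(tt))) / max(diff(range(tt)), seq$dt),
          w = w_ring[w_ofs[j] + idx],
          echo = j, seg = seg_id0[j] + sgi, interleave = m,
          retraced = r$direction == "retraced-in-out")
      }
    }
  }
  structure(list(streams = streams, etl = seq$etl, central_echo = seq$central_echo,
                 n_seg = seg_id0[length(seg_id0)],
                 tau = seq$meta$readout_dur, gm = seq$meta$gm,
                 fov = seq$meta$fov, n = ph$n, pixel = ph$pixel,
                 geom = geom,
                 opts = list(maxwell = maxwell, b0 = b0,
                             epg_weighting = epg_weighting, flip = flip,
                             noise_sd = noise_sd, seed = seed,
                             compensated = seq$compensated)),
            class = "kspace_acq")
}

#' @export
print.kspace_acq <- function(x, ...) {
  cat(sprintf("<kspace_acq> %d streams (ETL %d), %d samples total, matrix %d, maxwell=%s b0=%s\n",
              length(x$streams), x$etl,
              sum(vapply(x$streams, function(s) length(s$s), numeric(1))),
              x$n, x$opts$maxwell, x$opts$b0))
  invisible(x)
}

#' Simulate the dual-TE single-shot spiral calibration scan
#'
#' Two low-resolution single-shot spiral acquisitions at echo times
#' differing by `dTE`; the reconstructed phase difference divided by
#' `2 pi dTE` estimates the B0 map at low resolution.
#'
#' @param ph phantom (its B0 map in Hz is the ground truth).
#' @param geom scan geometry.
#' @param dTE echo-time increment (s), default 1 ms.
#' @param n_low low-resolution matrix size.
#' @param gmax,smax,dt spiral design limits.
#' @return list with `te1`, `te2` (`kspace_acq` objects) and `dTE`.
#' @export
simulate_dual_te_calibration <- function(ph, geom, dTE = 1e-3, n_low = 16,
                                         gmax = 0.021, smax = 120, dt = 1e-5) {
  fov <- ph$n * ph$pixel
  klow <- n_low / (2 * fov)
  path <- pi * klow^2 * fov              # single-shot Archimedean path length
  dur <- max(2e-3, round(path / (GAMMA_BAR * 0.8 * gmax) / dt) * dt)
  ring <- NULL
  for (try in 1:8) {   # extend if ramps/centripetal limits make it infeasible
    ring <- tryCatch(spiral_ring_waveform(0, klow, 1, fov, gmax, smax, dt, dur,
                                          "spiral-out"),
                     error = function(e) NULL)
    if (!is.null(ring)) break
    dur <- round(dur * 1.3 / dt) * dt
  }
  if (is.null(ring)) stop("could not design the calibration spiral under the hardware limits")
  gr <- phantom_grid(ph)
  mask <- ph$PD > 0
  xs <- gr$X[mask]; ys <- gr$Y[mask]
  dw <- 2 * pi * ph$B0[mask]
  meff <- complex(real = ph$PD[mask])
  w <- density_compensation(list(ring$k), fov = fov)
  mk <- function(te) {
    tt <- (seq_along(ring$k) - 1) * dt + te
    s <- cpp_sim_echo(meff, xs, ys, dw, rep(0, length(dw)),
                      Re(ring$k), Im(ring$k), tt, rep(0, length(tt)))
    structure(list(streams = list(list(s = s, k = ring$k, t = tt,
                                       tc = rep(0, length(tt)),
                                       u = 2 * (tt - mean(range(tt))) / diff(range(tt)),
                                       echo = 1L, seg = 1L,
                                       interleave = 1L, retraced = FALSE, w = w)),
                   etl = 1L, n_seg = 1L, central_echo = 1L, tau = dur, gm = gmax,
                   fov = fov, n = ph$n, pixel = ph$pixel, geom = geom,
                   opts = list(maxwell = FALSE, b0 = TRUE, te = te)),
              class = "kspace_acq")
  }
  list(te1 = mk(0), te2 = mk(dTE), dTE = dTE)
}

#' Acquisition frame of a sequence (no data)
#'
#' Builds the per-segment stream scaffolding (trajectory, time axes, scaled
#' time, normalized segment time, weights) of one interleave without
#' simulating any object, for trajectory export, density-weight inspection
#' and coefficient-table construction at protocol scale.
#'
#' @param seq an `echo_train_seq`.
#' @param interleave interleave index.
#' @return a `kspace_acq` whose streams carry zero samples.
#' @export
ring_acquisition_frame <- function(seq, interleave = 1) {
  w_ring <- density_compensation(lapply(seq$rings, `[[`, "k"), fov = seq$meta$fov,
                                 retraced = vapply(seq$rings, function(r)
                                   r$direction == "retraced-in-out", logical(1)))
  w_ofs <- c(0, cumsum(vapply(seq$rings, function(r) length(r$k), numeric(1))))
  seg_id0 <- c(0, cumsum(vapply(seq$rings, function(r) length(r$acq_segments), numeric(1))))
  rot <- exp(1i * 2 * pi * (interleave - 1) / seq$meta$n_shots)
  streams <- list()
  for (j in seq_len(seq$etl)) {
    r <- seq$rings[[j]]
    tt_full <- (seq_along(r$k) - r$i_echo) * seq$dt
    tc_full <- scaled_time(r, seq$meta$gm, mode = "tse", ref = "echo-center")
    for (sgi in seq_along(r$acq_segments)) {
      idx <- r$acq_segments[[sgi]]
      tt <- tt_full[idx]
      streams[[length(streams) + 1L]] <- list(
        s = rep(0i, length(idx)), k = r$k[idx] * rot, t = tt, tc = tc_full[idx],
        u = 2 * (tt - mean(range(tt))) / max(diff(range(tt)), seq$dt),
        w = w_ring[w_ofs[j] + idx],
        echo = j, seg = seg_id0[j] + sgi, interleave = interleave,
        retraced = r$direction == "retraced-in-out")
    }
  }
  structure(list(streams = streams, etl = seq$etl, n_seg = seg_id0[length(seg_id0)],
                 central_echo = seq$central_echo, tau = seq$meta$readout_dur,
                 gm = seq$meta$gm, fov = seq$meta$fov,
                 n = round(seq$meta$fov / seq$meta$resolution),
                 pixel = seq$meta$resolution, geom = NULL,
                 opts = list(frame_only = TRUE)),
            class = "kspace_acq")
}
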