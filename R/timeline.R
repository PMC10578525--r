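# Materialization of a full single-shot gradient timeline (logical axes) and
# Maxwell phase pathways along the echo train.

# sampled slice-select trapezoid centered on the RF (ramp 0.1 ms)
ss_trapezoid <- function(layout, dt) {
  ramp <- 1e-4
  flat <- layout$rf_plateau - 2 * ramp
  trapezoid_lobe(layout$g_ss, ramp, flat, dt)
}

# crusher trapezoid within its slot; shape 25/50/25 unless an explicit
# (amplitude, ramp, flat) override is given (used by balance_crushers)
crusher_wave <- function(layout, dt, override = NULL) {
  if (!is.null(override))
    return(trapezoid_lobe(override$a, override$ramp, override$flat, dt))
  slot <- layout$crusher_slot
  ramp <- 0.25 * slot; flat <- 0.5 * slot
  a <- layout$crusher_area / (flat + ramp)
  trapezoid_lobe(a, ramp, flat, dt)
}

# prephaser/rewinder trapezoids: fixed 25/50/25 shape in pre_slot, per-axis
# amplitude from the required zeroth moment
prephaser_wave <- function(moment, layout, gmax, dt) {
  slot <- layout$pre_slot
  ramp <- 0.25 * slot; flat <- 0.5 * slot
  a <- moment / (flat + ramp)
  if (abs(a) > gmax * (1 + 1e-9))
    stop(sprintf("prephaser amplitude %.3g mT/m exceeds gmax", abs(a) * 1e3))
  trapezoid_lobe(a, ramp, flat, dt)
}

bipolar_pair_wave <- function(pair, dt) {
  if (pair$amplitude == 0 && is.null(pair$trim)) return(numeric(0))
  w <- if (pair$amplitude > 0) {
    lobe <- trapezoid_lobe(pair$amplitude, pair$ramp, pair$flat, dt)
    c(lobe, -lobe) * pair$polarity
  } else numeric(0)
  if (!is.null(pair$trim)) {
    tr <- pair$trim
    lob <- trapezoid_lobe(1, tr$ramp, tr$flat, dt)
    wt <- c(lob, -lob) * tr$v
    n <- max(length(w), length(wt))
    w <- c(w, rep(0, n - length(w))) + c(wt, rep(0, n - length(wt)))
  }
  w
}

#' Materialize the gradient timeline of one shot
#'
#' Lays out the complete logical-frame gradient arrays for one excitation:
#' excitation slice select and rephaser, excitation-interval bipolar pairs,
#' per-echo crushers, refocusing slice selects, bipolar compensation pairs,
#' prephasers, ring readouts and rewinders. Time origin is the excitation RF
#' center; refocusing RF centers sit at `esp/2 + (j-1) esp` and spin-echo
#' centers at `j esp`.
#'
#' @param seq an `echo_train_seq`.
#' @param interleave which interleave's readout rotation to use.
#' @param include character subset of `c("rings", "prephasers", "bipolars",
#'   "slice")` to include.
#' @return list with `t`, `G` (n x 3 logical gradients), RF center indices
#'   `rf_idx` (excitation first), echo center indices `echo_idx`, per-echo
#'   readout index ranges `ro_idx`, `esp` and `dt`.
#' @export
seq_timeline <- function(seq, interleave = 1,
                         include = c("rings", "prephasers", "bipolars", "slice")) {
  dt <- seq$dt; esp <- seq$esp; lay <- seq$layout
  etl <- seq$etl
  n <- round((esp / 2 + etl * esp) / dt) + 1L
  G <- matrix(0, n, 3)
  t_ax <- (seq_len(n) - 1L) * dt
  idx_of <- function(tt) round(tt / dt) + 1L
  place <- function(axis, t_start, wave) {
    i0 <- idx_of(t_start)
    ii <- i0 + seq_along(wave) - 1L
    ok <- ii >= 1L & ii <= n
    G[ii[ok], axis] <<- G[ii[ok], axis] + wave[ok]
  }
  rot <- exp(1i * 2 * pi * (interleave - 1) / seq$meta$n_shots)

  rf_t <- c(0, esp / 2 + (seq_len(etl) - 1L) * esp)
  echo_t <- seq_len(etl) * esp
  ro_dur <- vapply(seq$rings, function(r) length(r$g) * dt, numeric(1))

  if ("slice" %in% include) {
    ss <- ss_trapezoid(lay, dt)
    half <- ss[(length(ss) %/% 2L + 1L):length(ss)]
    place(3, 0, half)                       # excitation slice select, second half
    reph_area <- -trapz_dt(half, dt)
    reph_a <- reph_area / (0.75 * lay$exc_reph_slot)
    place(3, lay$rf_plateau / 2 + 2 * dt,
          trapezoid_lobe(reph_a, 0.25 * lay$exc_reph_slot, 0.5 * lay$exc_reph_slot, dt))
    for (j in seq_len(etl)) {
      rfc <- rf_t[j + 1L]
      place(3, rfc - lay$rf_plateau / 2, ss)          # refocusing slice select
      place(3, rfc + lay$rf_plateau / 2, crusher_wave(lay, dt))   # right crusher
      # left crusher preceding this refocusing (first one may be rebalanced)
      ovr <- if (j == 1L && !is.null(lay$first_crusher)) lay$first_crusher else NULL
      wl <- crusher_wave(lay, dt, override = ovr)
      place(3, rfc - lay$rf_plateau / 2 - length(wl) * dt, wl)
    }
  }

  for (j in seq_len(etl)) {
    r <- seq$rings[[j]]
    t_ro <- echo_t[j] - ro_dur[j] / 2
    if ("rings" %in% include) {
      gj <- r$g * rot
      place(1, t_ro, Re(gj)); place(2, t_ro, Im(gj))
    }
    if ("prephasers" %in% include) {
      ks <- r$k[1] * rot; ke <- r$k[length(r$k)] * rot
      wpre_x <- prephaser_wave(Re(ks) / GAMMA_BAR, lay, seq$meta$gmax, dt)
      wpre_y <- prephaser_wave(Im(ks) / GAMMA_BAR, lay, seq$meta$gmax, dt)
      place(1, t_ro - lay$pre_slot, wpre_x)
      place(2, t_ro - lay$pre_slot, wpre_y)
      wrew_x <- prephaser_wave(-Re(ke) / GAMMA_BAR, lay, seq$meta$gmax, dt)
      wrew_y <- prephaser_wave(-Im(ke) / GAMMA_BAR, lay, seq$meta$gmax, dt)
      place(1, t_ro + ro_dur[j], wrew_x)
      place(2, t_ro + ro_dur[j], wrew_y)
    }
    if ("bipolars" %in% include && !is.null(seq$bipolars)) {
      for (p in seq$bipolars$echo[[j]]) {
        w <- bipolar_pair_wave(p, dt)
        if (!length(w)) next
        t0 <- if (p$slot == "pre") t_ro - lay$pre_slot - lay$bip_slot
              else t_ro + ro_dur[j] + lay$pre_slot
        place(p$axis, t0, w)
      }
    }
  }
  if ("bipolars" %in% include && !is.null(seq$bipolars)) {
    # excitation-interval pairs: two slots after the excitation rephaser
    t_slot1 <- lay$rf_plateau / 2 + lay$exc_reph_slot + 4 * dt
    for (p in seq$bipolars$exc) {
      w <- bipolar_pair_wave(p, dt)
      if (!length(w)) next
      t0 <- t_slot1 + (p$slot_index - 1L) * lay$bip_slot
      place(p$axis, t0, w)
    }
  }

  list(t = t_ax, G = G, rf_idx = idx_of(rf_t), echo_idx = idx_of(echo_t),
       ro_idx = lapply(seq_len(etl), function(j) {
         i0 <- idx_of(echo_t[j] - ro_dur[j] / 2)
         i0:(i0 + round(ro_dur[j] / dt) - 1L)
       }),
       esp = esp, dt = dt)
}

# Per-segment gradient-product integrals of a timeline. Segments split the
# shot at RF centers and echo centers: (exc), then (pre_1, post_1, ...,
# pre_etl, post_etl). Returns a matrix with columns Jxx, Jyy, Jzz, Jxz, Jyz
# (physical frame, T^2 s).
segment_integrals <- function(tl, geom) {
  Gp <- tl$G %*% t(geom$R)             # physical gradients per sample
  cuts <- c(sort(c(tl$rf_idx, tl$echo_idx)), nrow(tl$G))
  bounds <- cbind(cuts[-length(cuts)], cuts[-1])
  prods <- cbind(Gp[, 1]^2, Gp[, 2]^2, Gp[, 3]^2,
                 Gp[, 1] * Gp[, 3], Gp[, 2] * Gp[, 3])
  J <- t(apply(bounds, 1, function(b) {
    ii <- b[1]:b[2]
    vapply(1:5, function(c) trapz_dt(prods[ii, c], tl$dt), numeric(1))
  }))
  colnames(J) <- c("xx", "yy", "zz", "xz", "yz")
  J
}

# Maxwell phase increments per segment at given physical probe positions.
# J: segments x 5; r: n x 3. Returns segments x n matrix (rad).
segment_phases <- function(J, r, B0, cross_terms = FALSE) {
  r <- if (is.matrix(r)) r else matrix(r, ncol = 3)
  self <- outer(J[, "zz"], (r[, 1]^2 + r[, 2]^2) / (8 * B0)) +
    outer(J[, "xx"] + J[, "yy"], r[, 3]^2 / (2 * B0))
  ph <- self
  if (cross_terms)
    ph <- ph - (outer(J[, "xz"], r[, 1] * r[, 3]) +
                outer(J[, "yz"], r[, 2] * r[, 3])) / (2 * B0)
  GAMMA_RAD * ph
}

#' Maxwell phase pathway along the echo train
#'
#' Integrates the concomitant field at a probe location over the full
#' sequence timeline, negating the accumulated phase at every refocusing RF
#' center (phase conjugation), and reports the sampled pathway plus per-echo
#' summaries.
#'
#' @param seq an `echo_train_seq`.
#' @param geom a [scan_geometry()] (supplies rotation and B0).
#' @param probe physical (x, y, z) location (m).
#' @param cross_terms include quadratic cross-terms (default FALSE: spiral
#'   rings self-balance them; enable to audit bipolar cross-terms).
#' @param interleave readout rotation index.
#' @param include timeline components, see [seq_timeline()].
#' @return object of class `echo_phase_path`: sampled `t`, `phi` (rad),
#'   per-echo `echo_phi` (phase at spin-echo centers), `esp_start`/`esp_end`
#'   (phase just after/before each refocusing), and unconjugated segment
#'   `increments` (`exc`, `pre`, `post`) for EPG use.
#' @export
echo_train_phase <- function(seq, geom, probe, cross_terms = FALSE, interleave = 1,
                             include = c("rings", "prephasers", "bipolars", "slice")) {
  if (sqrt(sum(probe^2)) > 0.3)
    warning("probe is more than 0.3 m from isocenter; lowest-order Maxwell model may not hold")
  tl <- seq_timeline(seq, interleave = interleave, include = include)
  Gp <- tl$G %*% t(geom$R)
  bc <- maxwell_field(Gp, matrix(probe, ncol = 3), geom$B0,
                      terms = if (cross_terms) "all" else "self")
  n <- length(bc)
  dphi <- GAMMA_RAD * c(0, (bc[-1] + bc[-n]) / 2) * tl$dt
  phi <- numeric(n)
  run <- 0
  flips <- tl$rf_idx[-1]               # refocusing centers (skip excitation)
  fi <- 1L
  for (i in seq_len(n)) {
    if (fi <= length(flips) && i == flips[fi]) { run <- -run; fi <- fi + 1L }
    run <- run + dphi[i]
    phi[i] <- run
  }
  J <- segment_integrals(tl, geom)
  inc <- as.vector(segment_phases(J, probe, geom$B0, cross_terms))
  etl <- seq$etl
  structure(list(
    t = tl$t, phi = phi,
    echo_phi = phi[tl$echo_idx],
    esp_start = phi[pmin(n, tl$rf_idx[-1] + 1L)],
    esp_end = c(phi[pmax(1L, tl$rf_idx[-c(1, 2)] - 1L)], phi[n]),
    phi_final = phi[n],
    increments = list(exc = inc[1],
                      pre = inc[1 + 2 * seq_len(etl) - 1],
                      post = inc[1 + 2 * seq_len(etl)]),
    probe = probe, cross_terms = cross_terms
  ), class = "echo_phase_path")
}

#' @export
print.echo_phase_path <- function(x, ...) {
  cat("<echo_phase_path> phase at spin-echo centers (rad):\n")
  print(signif(x$echo_phi, 4))
  invisible(x)
}
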