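# Sequence-based Maxwell compensation: crusher balancing, per-echo bipolar
# pairs topping every half-interval up to a constant concomitant integral,
# and polarity reversal (plus an exact trim solve) for cross-term balance.

#' Self-squared integral of one bipolar pair
#'
#' Closed form for a pair of equal-area opposed trapezoid lobes:
#' `2 a^2 (flat + 2 ramp / 3)`.
#'
#' @param a lobe amplitude (T/m).
#' @param ramp,flat lobe ramp and flat durations (s).
#' @return integral of g^2 over the pair (T^2 s).
#' @export
bipolar_pair_integral <- function(a, ramp, flat) 2 * trap_sq_integral(a, ramp, flat)

#' Maximum per-axis concomitant integral over the ring set
#'
#' `Mmax` per logical readout axis: the maximum over rings of the ring
#' readout's self-squared integral, attained by the ring with the highest
#' gradient amplitude.
#'
#' @param seq an `echo_train_seq`.
#' @param interleave readout rotation used for the per-axis split.
#' @return length-2 vector (axes X, Y), T^2 s.
#' @export
compute_mmax <- function(seq, interleave = 1) {
  if (length(seq$rings) == 0L) stop("ring list is empty")
  rot <- exp(1i * 2 * pi * (interleave - 1) / seq$meta$n_shots)
  M <- vapply(seq$rings, function(r) {
    g <- r$g * rot
    c(trapz_dt(Re(g)^2, seq$dt), trapz_dt(Im(g)^2, seq$dt))
  }, numeric(2))
  c(X = max(M[1, ]), Y = max(M[2, ]))
}

# solve one bipolar pair for a target self-squared integral within a slot;
# lobes fill half the slot each (duration maximized before amplitude),
# amplitude rescaled so the raster-sampled integral hits the target exactly
solve_pair <- function(target, slot, gmax, smax, dt) {
  if (target <= 1e-16)
    return(list(amplitude = 0, ramp = 0, flat = 0, polarity = 1L))
  lobe <- floor((slot / 2 - dt) / dt) * dt
  ramp <- max(2 * dt, round(0.25 * lobe / dt) * dt)
  flat <- lobe - 2 * ramp
  for (it in 1:4) {
    a <- sqrt(target / (2 * (flat + 2 * ramp / 3)))
    need_ramp <- max(2 * dt, ceiling(a / smax / dt) * dt)
    if (need_ramp <= ramp) break
    ramp <- need_ramp; flat <- lobe - 2 * ramp
    if (flat < 0) stop("bipolar slot too short for the slew limit")
  }
  if (a > gmax) {
    min_slot <- 2 * (target / (2 * gmax^2) + 2 * (gmax / smax) * 2 / 3) + 2 * dt
    stop(sprintf(paste0("bipolar integral %.3g T^2 s unachievable in %.2f ms slot at ",
                        "gmax = %.3g mT/m; need at least %.2f ms"),
                 target, slot * 1e3, gmax * 1e3, min_slot * 1e3))
  }
  wave <- c(trapezoid_lobe(a, ramp, flat, dt), -trapezoid_lobe(a, ramp, flat, dt))
  meas <- trapz_dt(wave^2, dt)
  a <- a * sqrt(target / meas)
  list(amplitude = a, ramp = ramp, flat = flat, polarity = 1L)
}

#' Design bipolar compensation pairs for one echo spacing
#'
#' Sizes the pre- and post-readout pairs on each readout axis so the
#' half-interval self-squared integrals reach `Mmax/2` given the ring's own
#' integral `Mj` and its pre-echo-center share `Aj` (defaults to the
#' symmetric split `Mj/2`).
#'
#' @param Mj per-axis ring integrals (length 2, T^2 s).
#' @param Mmax per-axis maxima (length 2).
#' @param slot_dur bipolar slot duration (s).
#' @param gmax,smax hardware limits.
#' @param dt raster time (s).
#' @param Aj per-axis pre-echo-center share of `Mj`.
#' @return list of four pairs with fields `axis`, `slot` ("pre"/"post"),
#'   `amplitude`, `ramp`, `flat`, `polarity`.
#' @export
design_bipolars <- function(Mj, Mmax, slot_dur = 2.5e-3, gmax = 0.021, smax = 120,
                            dt = 1e-5, Aj = Mj / 2) {
  stopifnot(all(Mmax >= Mj - 1e-15))
  pairs <- list()
  for (ax in 1:2) {
    tp <- max(0, Mmax[ax] / 2 - Aj[ax])
    tq <- max(0, Mmax[ax] / 2 - (Mj[ax] - Aj[ax]))
    pp <- solve_pair(tp, slot_dur, gmax, smax, dt)
    pq <- solve_pair(tq, slot_dur, gmax, smax, dt)
    pp$axis <- ax; pp$slot <- "pre"
    pq$axis <- ax; pq$slot <- "post"
    pairs <- c(pairs, list(pp, pq))
  }
  pairs
}

# cross integral of two waves placed at the start of a shared slot
cross_int <- function(w1, w2, dt) {
  n <- max(length(w1), length(w2))
  if (n == 0L) return(0)
  a <- c(w1, rep(0, n - length(w1)))
  b <- c(w2, rep(0, n - length(w2)))
  trapz_dt(a * b, dt)
}

# unit-amplitude pair shape (positive leading lobe, no polarity)
unit_pair <- function(ramp, flat, dt) {
  if (ramp <= 0 && flat <= 0) return(numeric(0))
  lob <- trapezoid_lobe(1, ramp, flat, dt)
  c(lob, -lob)
}

# Exact cross-term trim: in every slot where both axes carry a pair, rewrite
# the axis-2 waveform as u * P + v * R (P its pair shape, R a half-duration
# trim pair, both zero-moment) with (u, v) chosen on the self-squared
# isocontour so the slot waveform is orthogonal to the axis-1 pair. Each
# slot's bipolar cross integral then vanishes identically, so the per-ESP
# total does too, while all self-squared integrals are preserved exactly.
trim_cross <- function(pairs, slot_dur, dt) {
  idx <- function(ax, sl) which(vapply(pairs, function(p)
    p$axis == ax && p$slot == sl, logical(1)))
  for (sl in c("pre", "post")) {
    w1 <- bipolar_pair_wave(pairs[[idx(1, sl)]], dt)
    if (length(w1) == 0L || max(abs(w1)) == 0) next     # axes decoupled
    i2 <- idx(2, sl)
    p2 <- pairs[[i2]]
    w2 <- bipolar_pair_wave(p2, dt)
    T2 <- trapz_dt(w2^2, dt)
    if (T2 <= 0) next
    P <- unit_pair(p2$ramp, p2$flat, dt)
    ramp_t <- max(2 * dt, round(p2$ramp / 2 / dt) * dt)
    flat_t <- max(2 * dt, round(p2$flat / 2 / dt) * dt)
    Rt <- unit_pair(ramp_t, flat_t, dt)
    A <- trapz_dt(P^2, dt); B <- cross_int(P, Rt, dt); C <- trapz_dt(Rt^2, dt)
    X <- cross_int(w1, P, dt); Y <- cross_int(w1, Rt, dt)
    if (abs(X) < 1e-300 && abs(Y) < 1e-300) next
    d <- c(Y, -X)                        # orthogonal direction to (X, Y)
    qd <- A * d[1]^2 + 2 * B * d[1] * d[2] + C * d[2]^2
    s <- sqrt(T2 / qd)
    u <- s * d[1]; v <- s * d[2]
    if ((u != 0 && sign(u) != p2$polarity) || (u == 0 && v < 0)) { u <- -u; v <- -v }
    p2$amplitude <- abs(u)
    if (u != 0) p2$polarity <- as.integer(sign(u))
    p2$trim <- list(ramp = ramp_t, flat = flat_t, v = v)
    pairs[[i2]] <- p2
  }
  pairs
}

#' Rebalance the first left crusher for slice-axis phase consistency
#'
#' Resizes the left crusher of the first refocusing pulse (at fixed zeroth
#' moment, trading amplitude against duration) so the slice-axis self-squared
#' integral of the excitation-to-first-refocusing interval equals half that
#' of each refocusing-to-refocusing interval.
#'
#' @param seq an `echo_train_seq`.
#' @return the sequence with an adjusted first-crusher override.
#' @export
balance_crushers <- function(seq) {
  lay <- seq$layout; dt <- seq$dt
  if (lay$crusher_area <= 0) return(seq)
  tl <- seq_timeline(seq, include = "slice")
  cuts <- tl$rf_idx
  intg <- function(i0, i1) trapz_dt(tl$G[i0:i1, 3]^2, dt)
  I0 <- intg(cuts[1], cuts[2])
  I1 <- intg(cuts[2], cuts[3])
  c_now <- trapz_dt(crusher_wave(lay, dt, override = lay$first_crusher)^2, dt)
  c_req <- c_now + (I1 / 2 - I0)       # required first-crusher integral
  if (c_req <= 0)
    stop("crusher balancing infeasible: required negative crusher integral; increase crusher area")
  A <- lay$crusher_area
  # amplitude/duration trade at (approximately raster-exact) fixed area:
  # iterate shape from amplitude, then set amplitude from the M target
  a <- sqrt(c_req / (0.75 * lay$crusher_slot))
  ramp <- max(2 * dt, round(0.25 * lay$crusher_slot / dt) * dt)
  flat <- max(2 * dt, round(0.5 * lay$crusher_slot / dt) * dt)
  for (it in 1:30) {
    flat_new <- max(2 * dt, round((A / a - ramp) / dt) * dt)
    a_new <- sqrt(c_req / trap_sq_integral(1, ramp, flat_new))
    if (abs(a_new - a) < 1e-12 && flat_new == flat) { flat <- flat_new; a <- a_new; break }
    flat <- flat_new; a <- a_new
  }
  if (a > seq$meta$gmax || flat + 2 * ramp > 4 * lay$crusher_slot)
    stop("crusher balancing infeasible under hardware limits")
  # exact raster rescale of the amplitude for the target integral
  meas <- trapz_dt(trapezoid_lobe(a, ramp, flat, dt)^2, dt)
  a <- a * sqrt(c_req / meas)
  seq$layout$first_crusher <- list(a = a, ramp = ramp, flat = flat)
  seq
}

# per-interval logical readout-axis integrals of the uncompensated timeline:
# P (refocusing -> echo center) and Q (echo center -> next refocusing)
interval_axis_integrals <- function(seq, interleave = 1) {
  tl <- seq_timeline(seq, interleave = interleave, include = c("rings", "prephasers"))
  cuts <- c(sort(c(tl$rf_idx, tl$echo_idx)), nrow(tl$G))
  n_seg <- length(cuts) - 1L
  J <- matrix(0, n_seg, 2)
  for (s in seq_len(n_seg)) {
    ii <- cuts[s]:cuts[s + 1L]
    J[s, ] <- c(trapz_dt(tl$G[ii, 1]^2, tl$dt), trapz_dt(tl$G[ii, 2]^2, tl$dt))
  }
  etl <- seq$etl
  list(exc = J[1, ],
       P = J[1 + 2 * seq_len(etl) - 1, , drop = FALSE],
       Q = J[1 + 2 * seq_len(etl), , drop = FALSE])
}

#' Apply sequence-based Maxwell compensation
#'
#' Implements the full sequence modification: (1) rebalance the first left
#' crusher; (2) determine the per-axis maximum half-interval concomitant
#' integral H over the echo train; (3) add bipolar pairs before and after
#' each readout so every half interval (refocusing to echo center, echo
#' center to next refocusing) reaches exactly H per axis, with the
#' excitation interval reaching H via four equal pairs; (4) optionally
#' reverse the polarity of the fourth pair per interval (and solve an exact
#' trim) so the net bipolar cross-term integral per echo spacing vanishes.
#' Zeroth moments of all added events are zero, so ring trajectories are
#' unchanged. The bipolar slots (2.5 ms before and after each readout) are
#' reserved by [design_ring_set()] in both the compensated and uncompensated
#' layouts, so echo spacing is unchanged by compensation itself.
#'
#' @param seq an `echo_train_seq`.
#' @param reversal apply the fourth-pair polarity reversal + trim.
#' @param crushers rebalance the first crusher first.
#' @return list with the compensated `seq` and the compensation `plan`
#'   (targets, per-axis H, Mmax, pair tables).
#' @export
compensate_sequence <- function(seq, reversal = TRUE, crushers = TRUE) {
  if (crushers) seq <- balance_crushers(seq)
  dt <- seq$dt; lay <- seq$layout
  iv <- interval_axis_integrals(seq)
  H <- pmax(apply(iv$P, 2, max), apply(iv$Q, 2, max))
  Mmax <- compute_mmax(seq)
  etl <- seq$etl
  echo_pairs <- vector("list", etl)
  for (j in seq_len(etl)) {
    pairs <- list()
    for (ax in 1:2) {
      tp <- max(0, H[ax] - iv$P[j, ax])
      tq <- max(0, H[ax] - iv$Q[j, ax])
      pp <- solve_pair(tp, lay$bip_slot, seq$meta$gmax, seq$meta$smax, dt)
      pq <- solve_pair(tq, lay$bip_slot, seq$meta$gmax, seq$meta$smax, dt)
      pp$axis <- ax; pp$slot <- "pre"
      pq$axis <- ax; pq$slot <- "post"
      pairs <- c(pairs, list(pp, pq))
    }
    if (reversal) {
      i4 <- which(vapply(pairs, function(p) p$axis == 2 && p$slot == "post", logical(1)))
      pairs[[i4]]$polarity <- -1L
      pairs <- trim_cross(pairs, lay$bip_slot, dt)
    }
    echo_pairs[[j]] <- pairs
  }
  # excitation interval: four equal pairs (two per axis), fourth reversed
  exc_pairs <- list()
  for (ax in 1:2) for (sl in 1:2) {
    tgt <- max(0, (H[ax] - iv$exc[ax]) / 2)
    p <- solve_pair(tgt, lay$bip_slot, seq$meta$gmax, seq$meta$smax, dt)
    p$axis <- ax; p$slot_index <- sl
    exc_pairs <- c(exc_pairs, list(p))
  }
  if (reversal) exc_pairs[[4]]$polarity <- -1L
  seq$bipolars <- list(echo = echo_pairs, exc = exc_pairs)
  seq$compensated <- if (reversal) "seq+reversal" else "seq"
  plan <- list(H = H, Mmax = Mmax, exc = iv$exc, P = iv$P, Q = iv$Q)
  list(seq = seq, plan = plan)
}

#' Set the fourth-pair polarity reversal on an already compensated sequence
#'
#' @param seq a compensated `echo_train_seq` (see [compensate_sequence()]).
#' @return the sequence with reversed fourth pairs and exact cross-term trim.
#' @export
assign_polarity_reversal <- function(seq) {
  if (is.null(seq$bipolars)) stop("sequence has no bipolar pairs; run compensate_sequence first")
  for (j in seq_along(seq$bipolars$echo)) {
    pairs <- seq$bipolars$echo[[j]]
    if (length(pairs) < 4L) stop("fewer than four bipolar pairs in echo spacing ", j)
    i4 <- which(vapply(pairs, function(p) p$axis == 2 && p$slot == "post", logical(1)))
    pairs[[i4]]$polarity <- -1L
    pairs[[i4]]$trim <- NULL
    seq$bipolars$echo[[j]] <- trim_cross(pairs, seq$layout$bip_slot, seq$dt)
  }
  seq$bipolars$exc[[4]]$polarity <- -1L
  seq$compensated <- "seq+reversal"
  seq
}

#' Net bipolar cross-term integral per echo spacing
#'
#' Audit of `int g1 g2 dt` over each echo spacing, bipolar events only.
#'
#' @param seq a compensated `echo_train_seq`.
#' @return numeric vector, one value per echo spacing (T^2 s).
#' @export
bipolar_cross_integral <- function(seq) {
  if (is.null(seq$bipolars)) return(rep(0, seq$etl))
  tl <- seq_timeline(seq, include = "bipolars")
  cuts <- tl$rf_idx
  vapply(seq_len(seq$etl), function(j) {
    ii <- cuts[j + 1L]:(if (j < seq$etl) cuts[j + 2L] else length(tl$t))
    trapz_dt(tl$G[ii, 1] * tl$G[ii, 2], tl$dt)
  }, numeric(1))
}
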