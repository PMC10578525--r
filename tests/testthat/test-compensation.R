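# Sequence-based Maxwell compensation: Mmax, bipolar sizing, polarity
# reversal with exact cross-term balance, crusher balancing, and the
# full-sequence phase-nulling contract.

test_that("compute_mmax equals the brute-force maximum over ring integrals", {
  s <- fx_seq48()
  M <- compute_mmax(s)
  brute <- sapply(s$rings, function(r)
    c(springrio:::trapz_dt(Re(r$g)^2, s$dt), springrio:::trapz_dt(Im(r$g)^2, s$dt)))
  expect_equal(unname(M), c(max(brute[1, ]), max(brute[2, ])), tolerance = 1e-15)

  sw <- desk_sequence(48, 7e-4, etl = 9, n_shots = 1, readout_dur = 0.016,
                      partition = "equal-width")
  Mw <- compute_mmax(sw)
  bw <- sapply(sw$rings, function(r)
    springrio:::trapz_dt(Mod(r$g)^2, sw$dt))
  expect_equal(which.max(bw), 1L)   # outermost (first) ring dominates
  expect_error(compute_mmax(list(rings = list(), meta = list(n_shots = 1))), "empty")
})

test_that("bipolar pair integrals: closed form and target attainment", {
  # trapezoid lobe a = 20 mT/m, ramp 0.2 ms, flat 0.5 ms
  expect_equal(bipolar_pair_integral(0.02, 2e-4, 5e-4),
               2 * 0.02^2 * (5e-4 + 2 * 2e-4 / 3), tolerance = 1e-12)
  expect_equal(bipolar_pair_integral(0.02, 2e-4, 5e-4), 5.07e-7, tolerance = 1e-3)

  Mmax <- c(1.2e-6, 1.2e-6)
  # outermost ring: Mj = Mmax, symmetric split -> no pairs needed
  ps <- design_bipolars(Mmax, Mmax)
  expect_true(all(vapply(ps, function(p) p$amplitude == 0, logical(1))))
  # Mj = 0: both slots deliver Mmax/2
  ps0 <- design_bipolars(c(0, 0), Mmax)
  for (p in ps0) {
    w <- springrio:::bipolar_pair_wave(p, 1e-5)
    expect_equal(springrio:::trapz_dt(w^2, 1e-5), Mmax[1] / 2, tolerance = 1e-10)
  }
  expect_error(design_bipolars(c(0, 0), c(5e-5, 5e-5), slot_dur = 1e-3),
               "slot")
  expect_error(design_bipolars(c(0, 0), c(4e-6, 4e-6), slot_dur = 2.5e-3),
               "unachievable")
})

test_that("polarity reversal self-balances the bipolar cross-terms exactly", {
  s <- fx_seq48()
  s_rev <- compensate_sequence(s, reversal = TRUE)$seq
  s_norev <- compensate_sequence(s, reversal = FALSE)$seq
  cr <- bipolar_cross_integral(s_rev)
  cn <- bipolar_cross_integral(s_norev)
  H <- compensate_sequence(s)$plan$H
  expect_lt(max(abs(cr)) / max(H), 1e-12)
  expect_gt(max(abs(cn)) / max(H), 1e-3)
  # self-squared integrals unchanged by the reversal
  for (j in seq_len(s$etl)) {
    ax2 <- function(sq) {
      tl <- seq_timeline(sq, include = "bipolars")
      cuts <- tl$rf_idx
      ii <- cuts[j + 1L]:(if (j < s$etl) cuts[j + 2L] else length(tl$t))
      c(springrio:::trapz_dt(tl$G[ii, 1]^2, tl$dt),
        springrio:::trapz_dt(tl$G[ii, 2]^2, tl$dt))
    }
    expect_equal(ax2(s_rev), ax2(s_norev), tolerance = 1e-9)
  }
  expect_error(assign_polarity_reversal(s), "no bipolar")
})

test_that("crusher balancing halves the excitation-interval slice integral", {
  s <- balance_crushers(fx_seq48())
  tl <- seq_timeline(s, include = "slice")
  cuts <- tl$rf_idx
  I0 <- springrio:::trapz_dt(tl$G[cuts[1]:cuts[2], 3]^2, tl$dt)
  I1 <- springrio:::trapz_dt(tl$G[cuts[2]:cuts[3], 3]^2, tl$dt)
  I2 <- springrio:::trapz_dt(tl$G[cuts[3]:cuts[4], 3]^2, tl$dt)
  expect_equal(I0 / I1, 0.5, tolerance = 1e-6)
  expect_equal(I1, I2, tolerance = 1e-12)     # refocusing intervals identical
  # crusher area (zeroth moment) approximately preserved
  fc <- s$layout$first_crusher
  expect_equal(springrio:::trap_area(fc$a, fc$ramp, fc$flat),
               s$layout$crusher_area, tolerance = 0.03)
  # disabled crushers leave the sequence unchanged
  s2 <- fx_seq48(); s2$layout$crusher_area <- 0
  expect_identical(balance_crushers(s2)$layout$first_crusher, NULL)
})

test_that("compensated sequence nulls the self-squared phase at every spin echo", {
  sc <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 0.55)
  for (z in c(0.02, 0.05, -0.06)) {
    pp <- echo_train_phase(sc, geom, c(0, 0, z))
    expect_lt(max(abs(pp$echo_phi)), 1e-3)
    # each echo spacing starts at -phi and ends at +phi, phi constant
    expect_equal(pp$esp_start, -pp$esp_end, tolerance = 1e-9)
    expect_lt(diff(range(pp$esp_end)) / abs(mean(pp$esp_end)), 1e-3)
  }
  # isocenter probe: compensation leaves the path identically zero
  p0 <- echo_train_phase(sc, geom, c(0, 0, 0))
  expect_true(all(abs(p0$phi) < 1e-12))
})

test_that("bipolars have zero net moment: ring trajectories are unchanged", {
  s <- fx_seq48(); sc <- fx_seq48_comp()
  tl_u <- seq_timeline(s, include = c("rings", "prephasers"))
  tl_c <- seq_timeline(sc)
  for (ax in 1:2) {
    mu <- cumsum(tl_u$G[, ax]) * tl_u$dt
    mc <- cumsum(tl_c$G[, ax]) * tl_c$dt
    expect_lt(max(abs(mu[tl_u$echo_idx] - mc[tl_c$echo_idx])) * 42.577e6, 1e-8)
  }
})

test_that("EPG-level CPMG restoration: compensated echoes match the Maxwell-free train", {
  sc <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 0.55)
  for (z in c(0.03, 0.06)) {
    sched <- epg_phase_schedule(sc, geom, cbind(0, 0, z))
    e_ref <- epg_echo_train(sc$etl, sc$esp, 0.8, 0.07, alpha = 150)[, 1]
    e_c <- epg_echo_train(sc$etl, sc$esp, 0.8, 0.07, alpha = 150,
                          phases = sched)[, 1]
    expect_lt(max(Mod(Mod(e_c) - Mod(e_ref))) / max(Mod(e_ref)), 1e-3)
    expect_lt(diff(range(Arg(e_c))), 1e-3)   # constant echo phase along the train
  }
})
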