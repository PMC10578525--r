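# Spiral-ring design: partitions, hardware constraints, coverage, duality,
# and density compensation.

test_that("annulus partitions tile [0, kmax] without gaps", {
  for (p in c("balanced", "equal-area", "equal-width")) {
    b <- annulus_partition(704.2, 9, p)
    expect_length(b, 10)
    expect_equal(b[1], 0)
    expect_equal(b[10], 704.2)
    expect_true(all(diff(b) > 0))
  }
})

test_that("design rejects ambiguous or infeasible requests naming the limit", {
  expect_error(design_ring_set(0.046, 7e-4, etl = 8, n_shots = 2,
                               readout_dur = 0.012), "even")
  expect_error(design_ring_set(0.046, 7e-4, etl = 9, n_shots = 1,
                               gmax = 0.002, readout_dur = 0.004), "gmax")
})

test_that("designed rings respect amplitude and slew limits at every sample", {
  s <- fx_seq48()
  for (r in s$rings) {
    g <- cbind(Re(r$g), Im(r$g))
    expect_lt(max(abs(g)), s$meta$gmax * (1 + 1e-6))
    expect_lt(max(abs(diff(g))) / s$dt, s$meta$smax * (1 + 1e-6))
    expect_equal(abs(r$g[1]), 0)
    expect_equal(abs(r$g[length(r$g)]), 0)
  }
  # annuli of one shot partition the disk; one retraced ring covering k = 0
  dirs <- vapply(s$rings, `[[`, character(1), "direction")
  expect_equal(sum(dirs == "retraced-in-out"), 1L)
  expect_equal(s$rings[[s$central_echo]]$k_inner, 0)
  expect_equal(s$n_in, s$n_out)
  expect_equal(sort(vapply(s$rings, `[[`, numeric(1), "k_outer"))[s$etl],
               s$meta$kmax)
})

test_that("spiral-in rings retrace their paired spiral-out ring in reverse", {
  s <- fx_seq48()
  r_in <- s$rings[[1]]          # outermost annulus, spiral-in
  r_out <- spiral_ring_waveform(r_in$k_inner, r_in$k_outer, 1, s$meta$fov,
                                s$meta$gmax, s$meta$smax, s$dt,
                                s$meta$readout_dur, "spiral-out")
  raster_step <- 42.577e6 * s$meta$gmax * s$dt
  expect_lt(max(Mod(r_in$k - rev(r_out$k))), raster_step)
  expect_equal(r_in$g, -rev(r_out$g), tolerance = 1e-12)

  # the self-retraced central ring returns to its initial k
  rc <- s$rings[[s$central_echo]]
  expect_lt(Mod(rc$k[1] - rc$k[length(rc$k)]), raster_step)
  nh <- length(rc$k) %/% 2
  expect_lt(max(Mod(rc$k[1:nh] - rev(rc$k)[1:nh])), raster_step)
})

test_that("composite sampling of the 1.5T protocol has no radial gaps beyond 1/FOV", {
  p <- protocol_defaults("1.5T")
  s <- design_ring_set(fov = p$fov, resolution = p$resolution, etl = p$etl,
                       n_shots = p$n_shots, gmax = p$gmax, smax = p$smax,
                       readout_dur = p$readout)
  tr <- composite_trajectory(s)
  set.seed(7)
  nprobe <- 4000
  rr <- sqrt(runif(nprobe)) * s$meta$kmax * 0.95
  th <- runif(nprobe) * 2 * pi
  worst <- springrio:::cpp_max_nn_dist(rr * cos(th), rr * sin(th),
                                       Re(tr$k), Im(tr$k), 1.2 / p$fov)
  expect_lt(worst, 1 / p$fov)   # 4.35 cycles/m
})

test_that("density compensation: positivity, retrace halving, duplicate split", {
  s <- fx_seq48()
  klist <- lapply(s$rings, `[[`, "k")
  retr <- vapply(s$rings, function(r) r$direction == "retraced-in-out", logical(1))
  w <- density_compensation(klist, fov = s$meta$fov, retraced = retr)
  expect_true(all(w > 0))
  expect_true(all(is.finite(w)))

  # doubling every sample (simulated retrace) halves the weights
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- 300 * exp(1i * th)
  w1 <- density_compensation(list(circ), fov = 0.046)
  dup <- as.vector(rbind(circ, circ))
  w2 <- density_compensation(list(dup), fov = 0.046)
  expect_equal(sum(w2), sum(w1), tolerance = 0.02)
  expect_equal(w2[2 * (20:80)], w1[20:80] / 2, tolerance = 0.05)

  # two identical non-adjacent streams: weights split evenly with a warning
  expect_warning(w3 <- density_compensation(list(circ, circ), fov = 0.046),
                 "duplicate")
  expect_equal(sum(w3), sum(w1), tolerance = 0.02)
})

test_that("radial-mode weights follow the polar Jacobian, against a Voronoi oracle", {
  # radial spokes: uniform radius spacing, weights proportional to |k|
  nk <- 40; nspokes <- 32
  kr <- seq(5, 200, length.out = nk)
  spokes <- lapply(seq_len(nspokes) - 1, function(m) kr * exp(1i * 2 * pi * m / nspokes))
  w <- density_compensation(spokes, mode = "radial", n_spokes = nspokes)
  w1 <- w[seq_len(nk)]
  expect_gt(cor(w1[3:(nk - 2)], kr[3:(nk - 2)]), 0.9999)

  # grid-Voronoi areas agree with the analytic polar weights away from edges
  kk <- unlist(spokes)
  va <- density_compensation(spokes, fov = 1 / (kr[2] - kr[1]), mode = "voronoi-grid")
  mid <- rep(5:(nk - 5), nspokes) + rep((seq_len(nspokes) - 1) * nk, each = nk - 9)
  expect_equal(median(w[mid] / va[mid]), 1, tolerance = 0.05)
})

test_that("gridding a smooth phantom recovers it (NRMSE < 0.1) with low disk ripple", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  R2 <- grid_radius2(48)
  ph$PD <- exp(-R2 / (2 * 3^2))
  img <- gridding_recon(simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                                        epg_weighting = FALSE))
  expect_lt(nrmse(img, ph$PD), 0.1)

  ph$PD[] <- 0; ph$PD[R2 <= 16^2] <- 1
  m <- Mod(gridding_recon(simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                                          epg_weighting = FALSE)))
  inb <- R2 <= 12^2
  expect_lt(mean(abs(m[inb] - mean(m[inb]))) / mean(m[inb]), 0.05)
})
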