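# Gridding, base images, the Chebyshev coefficient table and conjugate-phase
# combination.

test_that("gridding: impulse localization and the zero-data null", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  ph$PD[] <- 0; ph$PD[31, 17] <- 1
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                         epg_weighting = FALSE)
  img <- gridding_recon(acq)
  expect_equal(as.vector(arrayInd(which.max(Mod(img)), c(48, 48))), c(31, 17))

  for (i in seq_along(acq$streams)) acq$streams[[i]]$s[] <- 0i
  expect_true(all(gridding_recon(acq) == 0))
})

test_that("missing weights are computed on the fly with a warning", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                         epg_weighting = FALSE)
  for (i in seq_along(acq$streams)) acq$streams[[i]]$w <- NULL
  expect_warning(img <- gridding_recon(acq), "weights missing")
  expect_gt(max(Mod(img)), 0)
})

test_that("base images: order zero is the gridding recon; stack is linear", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                         epg_weighting = FALSE)
  stk <- base_images(acq, N = 6)
  I0 <- matrix(rowSums(stk$I[, 1, ]), 48, 48)
  expect_equal(I0, gridding_recon(acq), tolerance = 1e-12)

  acq2 <- acq
  for (i in seq_along(acq2$streams)) acq2$streams[[i]]$s <- 2 * acq2$streams[[i]]$s
  stk2 <- base_images(acq2, N = 6)
  expect_equal(stk2$I, 2 * stk$I, tolerance = 1e-12)
})

test_that("odd-order base images vanish for a symmetric retraced readout", {
  # single-stream acquisition over the full self-retraced ring: symmetric u
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                         epg_weighting = FALSE)
  rc <- s$rings[[s$central_echo]]
  gr <- springrio:::phantom_grid(ph)
  mask <- ph$PD > 0
  tt <- (seq_along(rc$k) - rc$i_echo) * s$dt
  ss <- springrio:::cpp_sim_echo(complex(real = ph$PD[mask]), gr$X[mask], gr$Y[mask],
                                 rep(0, sum(mask)), rep(0, sum(mask)),
                                 Re(rc$k), Im(rc$k), tt, rep(0, length(tt)))
  w <- density_compensation(list(rc$k), fov = s$meta$fov, retraced = TRUE)
  one <- acq
  one$streams <- list(list(s = ss, k = rc$k, t = tt, tc = rep(0, length(tt)),
                           u = 2 * (tt - mean(range(tt))) / diff(range(tt)),
                           w = w, echo = 1L, seg = 1L, interleave = 1L,
                           retraced = TRUE))
  one$n_seg <- 1L; one$etl <- 1L
  stk <- base_images(one, N = 4)
  ratio <- max(Mod(stk$I[, 2, 1])) / max(Mod(stk$I[, 1, 1]))
  expect_lt(ratio, 0.05)
})

test_that("coefficient table: identity node, convergence, and contract errors", {
  fr <- ring_acquisition_frame(fx_seq055_comp())
  set.seed(11)
  tab <- build_coefficient_table(fr, c(-80, 80), c(0, 400), N = 15,
                                 dw_step = 4, dwc_step = 8,
                                 check = TRUE, check_nodes = 80)
  expect_lt(tab$check_err, 1e-3)
  # identity node: h reduces to weight one on I0 after the -h0/2 term
  i0 <- which(tab$dw_hz == 0); j0 <- which(tab$dwc_hz == 0)
  hk <- tab$h[i0, j0, , 1]
  expect_equal(Re(hk[1]) - Re(hk[1]) / 2, 1, tolerance = 1e-12)
  expect_lt(max(Mod(hk[-1])), 1e-12)

  # too few base images: the contract raises an informative error
  set.seed(11)
  expect_error(build_coefficient_table(fr, c(-80, 80), c(0, 400), N = 5,
                                       dw_step = 40, dwc_step = 100,
                                       check = TRUE, check_nodes = 40),
               "contract violated")
})

test_that("conjugate-phase combine reduces to gridding for zero maps", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                         epg_weighting = FALSE)
  tab <- build_coefficient_table(acq, c(-40, 40), c(0, 2), N = 15, check = FALSE)
  stk <- base_images(acq, 15)
  img_cp <- conjugate_phase_combine(stk, tab, 0, 0)
  img_g <- gridding_recon(acq)
  expect_lt(max(Mod(img_cp - img_g)) / max(Mod(img_g)), 1e-6)
  # out-of-range pixels are clamped with a warning
  expect_warning(conjugate_phase_combine(stk, tab, matrix(500, 48, 48), 0),
                 "clamped")
})

test_that("a 60 Hz off-resonance point source is refocused by the correction", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  ph$PD[] <- 0; ph$PD[25, 25] <- 1
  ph$B0[] <- 60
  acq0 <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                          epg_weighting = FALSE)
  peak0 <- max(Mod(gridding_recon(acq0)))
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = TRUE,
                         epg_weighting = FALSE)
  peak_unc <- max(Mod(gridding_recon(acq)))
  expect_lt(peak_unc / peak0, 0.8)
  tab <- build_coefficient_table(acq, c(-70, 70), c(0, 2), N = 15, check = FALSE)
  stk <- base_images(acq, 15)
  peak_cp <- max(Mod(conjugate_phase_combine(stk, tab, matrix(60, 48, 48), 0)))
  expect_gt(peak_cp / peak0, 0.95)
})

test_that("concomitant term in the demodulation at least halves the Maxwell error", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", slice_offset = 0.05, B0 = 0.55)
  ph <- make_phantom("shepp-logan", 48, 7e-4)
  acq_ref <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE, flip = 150)
  img_ref <- gridding_recon(acq_ref)
  acq <- simulate_kspace(ph, s, geom, maxwell = TRUE, b0 = FALSE, flip = 150)
  gr <- springrio:::phantom_grid(ph)
  dwc_hz <- concomitant_offset_map(geom, s$meta$gm, gr$X, gr$Y)$dwc / (2 * pi)
  err_without <- nrmse(gridding_recon(acq), img_ref)
  tab <- build_coefficient_table(acq, c(-2, 2), c(0, ceiling(max(dwc_hz)) + 1),
                                 N = 15, check = FALSE)
  stk <- base_images(acq, 15)
  err_with <- nrmse(conjugate_phase_combine(stk, tab, 0, dwc_hz), img_ref)
  expect_lt(err_with * 2, err_without)
})

test_that("approximating the scaled time by t misfocuses inner-ring data", {
  # B0-style deblurring (tc ~ t) applied to concomitant phase fails the
  # point-source focus test that the proper scaled time passes
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", slice_offset = 0.1, B0 = 0.55)
  ph <- make_phantom("shepp-logan", 48, 7e-4)
  ph$PD[] <- 0; ph$PD[25, 25] <- 1
  acq0 <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                          epg_weighting = FALSE)
  peak0 <- max(Mod(gridding_recon(acq0)))
  acq <- simulate_kspace(ph, s, geom, maxwell = TRUE, b0 = FALSE,
                         epg_weighting = FALSE)
  gr <- springrio:::phantom_grid(ph)
  dwc_hz <- concomitant_offset_map(geom, s$meta$gm, gr$X, gr$Y)$dwc / (2 * pi)
  rng <- c(0, ceiling(max(dwc_hz)) + 1)
  tab <- build_coefficient_table(acq, c(-2, 2), rng, N = 15, check = FALSE)
  stk <- base_images(acq, 15)
  peak_tc <- max(Mod(conjugate_phase_combine(stk, tab, 0, dwc_hz)))
  expect_gt(peak_tc / peak0, 0.95)
  # replace tc by t in the demodulation basis
  acq_t <- acq
  for (i in seq_along(acq_t$streams)) acq_t$streams[[i]]$tc <- acq_t$streams[[i]]$t
  tab_t <- build_coefficient_table(acq_t, c(-2, 2), rng, N = 18, check = FALSE)
  stk_t <- base_images(acq_t, 18)
  peak_t <- max(Mod(conjugate_phase_combine(stk_t, tab_t, 0, dwc_hz)))
  expect_lt(peak_t / peak0, 0.95)
})

test_that("linear corrections remove constant offsets exactly and no-op at zero", {
  s <- fx_seq48_comp()
  geom <- scan_geometry("axial", B0 = 1.5)
  ph <- fx_phantom48_norelax()
  acq0 <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = FALSE,
                          epg_weighting = FALSE)
  ph$B0[] <- 40
  acq <- simulate_kspace(ph, s, geom, maxwell = FALSE, b0 = TRUE,
                         epg_weighting = FALSE)
  lc <- linear_corrections(acq, dw_hz = matrix(40, 48, 48))
  d <- unlist(lapply(seq_along(lc$acq$streams), function(i)
    Mod(lc$acq$streams[[i]]$s - acq0$streams[[i]]$s)))
  expect_lt(max(d) / max(Mod(acq0$streams[[1]]$s)), 1e-9)
  expect_true(all(abs(lc$dw_res) < 1e-9))

  lc0 <- linear_corrections(acq0, dw_hz = matrix(0, 48, 48))
  expect_equal(lc0$acq$streams[[3]]$s, acq0$streams[[3]]$s, tolerance = 1e-12)

  # axial off-center slice: residual concomitant range equals the isocenter's
  gr <- springrio:::phantom_grid(ph)
  g_off <- scan_geometry("axial", slice_offset = -0.1, B0 = 1.5)
  dwc_off <- concomitant_offset_map(g_off, s$meta$gm, gr$X, gr$Y)$dwc / (2 * pi)
  lc2 <- linear_corrections(acq, dwc_hz = dwc_off)
  g_iso <- scan_geometry("axial", slice_offset = 0, B0 = 1.5)
  dwc_iso <- concomitant_offset_map(g_iso, s$meta$gm, gr$X, gr$Y)$dwc / (2 * pi)
  expect_equal(diff(range(lc2$dwc_res)), diff(range(dwc_iso)), tolerance = 1e-9)
})

test_that("field-map estimation: null, constant and the wrap bound", {
  img <- matrix(complex(real = 1), 8, 8)
  fm <- estimate_field_map(img, img, 1e-3)
  expect_true(all(fm$map_hz == 0))
  # offsets beyond +-1/(2 dTE) wrap
  img2 <- img * exp(-2i * pi * 600 * 1e-3)
  fm2 <- estimate_field_map(img, img2, 1e-3)
  expect_equal(fm2$map_hz[1, 1], -400, tolerance = 1e-9)
})
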