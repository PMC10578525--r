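# Maxwell field evaluation, orientation constants, offset maps, scaled time
# and echo-train phase pathways.

test_that("maxwell_field matches its closed form and vanishes at isocenter", {
  # 21 mT/m readout gradient, 50 mm off-center axial at 0.55T
  bc <- maxwell_field(c(0.021, 0, 0), c(0, 0, 0.05), 0.55)
  expect_equal(bc, 0.021^2 * 0.05^2 / (2 * 0.55), tolerance = 1e-12)
  expect_equal(bc, 1.0023e-6, tolerance = 1e-4)
  expect_equal(42.577e6 * bc, 42.7, tolerance = 1e-2)   # ~42.7 Hz offset

  expect_equal(maxwell_field(c(0.02, 0.01, 0.015), c(0, 0, 0), 0.55), 0)
  expect_error(maxwell_field(c(0.02, 0, 0), c(0, 0, 0.05), 0), "B0")

  # self minus cross structure for gx = gz = g at x = z = r, y = 0
  g <- 0.018; r <- 0.04; B0 <- 1.5
  sym <- g^2 * r^2 / (8 * B0) + g^2 * r^2 / (2 * B0) - g^2 * r^2 / (2 * B0)
  expect_equal(maxwell_field(c(g, 0, g), c(r, 0, r), B0), sym, tolerance = 1e-15)
})

test_that("orientation constants: axial identity and quadratic-form positivity", {
  expect_equal(unname(f_constants(scan_geometry("axial"))),
               c(0, 0, 2, 0, 0, 0), tolerance = 1e-12)
  expect_error(f_constants(list(R = matrix(1, 3, 3))))
  # offset maps nonnegative for standard and oblique geometries
  u <- seq(-0.05, 0.05, length.out = 11)
  X <- matrix(u, 11, 11); Y <- t(X)
  ob <- scan_geometry(scan_geometry("sagittal")$R %*%
                        rbind(c(cos(0.4), -sin(0.4), 0),
                              c(sin(0.4), cos(0.4), 0), c(0, 0, 1)),
                      slice_offset = 0.03, B0 = 0.55)
  for (geom in list(scan_geometry("axial", slice_offset = 0.05),
                    scan_geometry("sagittal", slice_offset = 0.02),
                    scan_geometry("coronal", slice_offset = -0.04), ob)) {
    cm <- concomitant_offset_map(geom, 0.021, X, Y)
    expect_true(all(cm$dwc >= -1e-9))
  }
})

test_that("offset maps scale exactly as gm^2 and 1/B0; isocenter axial map is zero", {
  u <- seq(-0.04, 0.04, length.out = 9)
  X <- matrix(u, 9, 9); Y <- t(X)
  g1 <- scan_geometry("sagittal", slice_offset = 0.03, B0 = 0.55)
  m1 <- concomitant_offset_map(g1, 0.021, X, Y)$dwc
  m2 <- concomitant_offset_map(g1, 0.0105, X, Y)$dwc
  expect_equal(m1 / pmax(m2, 1e-300), matrix(4, 9, 9), tolerance = 1e-9)
  g2 <- scan_geometry("sagittal", slice_offset = 0.03, B0 = 1.1)
  m3 <- concomitant_offset_map(g2, 0.021, X, Y)$dwc
  expect_equal(m1 / pmax(m3, 1e-300), matrix(2, 9, 9), tolerance = 1e-9)

  m0 <- concomitant_offset_map(scan_geometry("axial"), 0.021, X, Y)$dwc
  expect_true(all(m0 == 0))

  # axial, z = 50 mm, 21 mT/m, 0.55T: uniform ~42.7 Hz
  ma <- concomitant_offset_map(scan_geometry("axial", slice_offset = 0.05, B0 = 0.55),
                               0.021, X, Y)$dwc / (2 * pi)
  expect_equal(unname(ma[1, 1]), 42.7, tolerance = 1e-2)
  expect_lt(diff(range(ma)), 1e-9)
})

test_that("quadrature factorization reproduces brute-force Maxwell integration", {
  # Dwc * tc phase over one spiral ring vs direct time integration of the
  # instantaneous field at the probe, for several orientations
  s <- fx_seq48()
  r <- s$rings[[2]]
  gm <- s$meta$gm
  probes <- list(axial = c(0, 0, 0.05),
                 sagittal = c(0.05, 0.05, 0.03),
                 coronal = c(0.04, -0.03, 0.05))
  for (nm in names(probes)) {
    geom <- scan_geometry(nm, B0 = 0.55)
    # logical in-plane coordinates of the physical probe
    rl <- t(geom$R) %*% probes[[nm]]
    cm <- concomitant_offset_map(scan_geometry(nm, slice_offset = rl[3], B0 = 0.55),
                                 gm, rl[1], rl[2])
    tc <- scaled_time(r, gm, "plain")
    phi_fact <- unname(as.vector(cm$dwc)) * tc[length(tc)]
    Gl <- cbind(Re(r$g), Im(r$g), 0)
    Gp <- Gl %*% t(geom$R)
    bc <- maxwell_field(Gp, matrix(probes[[nm]], 1), 0.55)
    phi_brute <- 2.675e8 * springrio:::trapz_dt(bc, s$dt)
    expect_equal(phi_fact, phi_brute, tolerance = 0.02)
  }
})

test_that("scaled time: closed forms, monotonicity and zero crossing", {
  g <- rep(0.021, 1000)          # constant envelope at gm
  tc <- scaled_time(g + 0i, 0.021, "plain", dt = 1e-5)
  expect_equal(tc[1000], 999e-5, tolerance = 1e-9)   # tc(t) = t at envelope gm
  expect_true(all(diff(tc) >= 0))

  tct <- scaled_time(g + 0i, 0.021, "tse", dt = 1e-5)
  Mj <- 0.021^2 * 999e-5
  expect_equal(tct[1], -Mj / (2 * 0.021^2), tolerance = 1e-9)
  expect_equal(tct[1000], Mj / (2 * 0.021^2), tolerance = 1e-9)
  # Mj = 4.41e-6 T^2 s at gm = 21 mT/m ends at 5.0 ms
  expect_equal(4.41e-6 / (2 * 0.021^2), 5e-3, tolerance = 1e-12)
  expect_error(scaled_time(g + 0i, 0, "plain", dt = 1e-5), "gm")

  # tse crosses zero where half the integral has accrued
  r <- fx_seq48()$rings[[3]]
  tc2 <- scaled_time(r, 0.021, "tse", "half-integral")
  icross <- which.min(abs(tc2))
  cum <- cumsum(Mod(r$g)^2)
  expect_equal(cum[icross] / cum[length(cum)], 0.5, tolerance = 0.01)
})

test_that("echo-train phase pathway: isocenter null, sign flips, ring ordering", {
  s <- fx_seq48()
  geom <- scan_geometry("axial", B0 = 0.55)
  p0 <- echo_train_phase(s, geom, c(0, 0, 0))
  expect_true(all(abs(p0$phi) < 1e-12))

  expect_warning(echo_train_phase(s, geom, c(0, 0, 0.5)), "0.3 m")

  pz <- echo_train_phase(s, geom, c(0, 0, 0.05))
  expect_true(all(abs(pz$echo_phi) > 1e-3))  # uncompensated: nonzero at echoes
  # phase is conjugated at each refocusing pulse
  expect_equal(pz$esp_start[2:s$etl], -pz$esp_end[1:(s$etl - 1)], tolerance = 1e-9)

  # equal-width partition: outer rings accrue more Maxwell phase than inner
  sw <- desk_sequence(48, 7e-4, etl = 9, n_shots = 1, readout_dur = 0.016,
                      partition = "equal-width")
  pw <- echo_train_phase(sw, geom, c(0, 0, 0.05))
  inc <- abs(pw$increments$pre + pw$increments$post)
  expect_gt(inc[1], 3 * inc[sw$central_echo])   # outermost vs central ring
})
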