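# SPGR physics, VFA T1 estimation and concentration conversion.

test_that("SPGR closed form matches direct evaluation", {
  expect_equal(spgr_signal(1000, 1000, 0, 4.4), 0)
  expect_equal(spgr_signal(1000, 1000, 18, 4.4), 25.540568, tolerance = 1e-6)
  # 6 deg sits near the Ernst angle acos(exp(-TR/T1)) ~ 5.37 deg, so its
  # signal exceeds the 18 deg signal at this T1
  s6 <- spgr_signal(1000, 1000, 6, 4.4)
  expect_equal(s6, 46.616903, tolerance = 1e-6)
  expect_gt(s6, spgr_signal(1000, 1000, 18, 4.4))
  expect_error(spgr_signal(1000, -5, 18, 4.4), "positive")
})

test_that("VFA fit inverts the forward model across the physiological range", {
  flips <- c(6, 12, 18)
  for (T1 in c(200, 500, 1000, 1400, 2200, 3000)) {
    S <- spgr_signal(500, T1, flips, 4.4)
    fit <- fit_vfa_t1(S, flips, 4.4)
    expect_true(fit$valid)
    expect_equal(fit$T1_ms, T1, tolerance = 1e-3)
    expect_equal(fit$M0, 500, tolerance = 1e-3)
  }
})

test_that("nonphysical VFA signals are marked invalid, not fatal", {
  # super-linear rise with flip angle implies regression slope E1 > 1
  fit <- fit_vfa_t1(c(1, 3, 9), c(6, 12, 18), 4.4)
  expect_false(fit$valid)
  expect_true(is.nan(fit$T1_ms))
  fit0 <- fit_vfa_t1(c(0, 0, 0), c(6, 12, 18), 4.4)
  expect_false(fit0$valid)
  expect_error(fit_vfa_t1(c(1, 2), c(12, 12), 4.4), "distinct")
})

test_that("concentration conversion is an exact inverse of the forward SPGR model", {
  protocol <- acquisition_protocol()
  T10 <- 1000; M0 <- 800
  C_true <- c(rep(0, 10), seq(0, 10, length.out = 105))
  R1 <- 1000 / T10 + protocol$r1_relaxivity * C_true
  S <- spgr_signal(M0, 1000 / R1, protocol$dyn_flip_deg, protocol$TR_ms)
  series <- dynamic_series(array(S, c(1, 1, 1, 115)), frame_times())
  t1m0 <- structure(list(T1_ms = array(T10, c(1, 1, 1)),
                         M0 = array(1, c(1, 1, 1)),   # wrong scale on purpose
                         valid = array(TRUE, c(1, 1, 1))),
                    class = "t1m0_map")
  conc <- signal_to_concentration(series, t1m0, protocol, baseline_frames = 10)
  expect_lt(max(abs(conc$data[1, 1, 1, ] - C_true)), 1e-6)
  # identity baseline: constant signal converts to zero concentration
  s0 <- dynamic_series(array(S[1], c(1, 1, 1, 115)), frame_times())
  c0 <- signal_to_concentration(s0, t1m0, protocol, baseline_frames = 10)
  expect_equal(max(abs(c0$data)), 0)
})

test_that("recovered concentration scales inversely with relaxivity", {
  protocol <- acquisition_protocol(r1_relaxivity = 4.5)
  T10 <- 1000
  R1 <- 1000 / T10 + 4.5 * c(rep(0, 10), rep(0.5, 105))
  S <- spgr_signal(1000, 1000 / R1, protocol$dyn_flip_deg, protocol$TR_ms)
  series <- dynamic_series(array(S, c(1, 1, 1, 115)), frame_times())
  t1m0 <- structure(list(T1_ms = array(T10, c(1, 1, 1)),
                         M0 = array(1, c(1, 1, 1)),
                         valid = array(TRUE, c(1, 1, 1))),
                    class = "t1m0_map")
  c1 <- signal_to_concentration(series, t1m0, protocol)
  p2 <- acquisition_protocol(r1_relaxivity = 9.0)
  c2 <- signal_to_concentration(series, t1m0, p2)
  expect_equal(c2$data[1, 1, 1, 115], c1$data[1, 1, 1, 115] / 2,
               tolerance = 1e-12)
})

test_that("concentration conversion is monotone over the invertible range", {
  protocol <- acquisition_protocol()
  C_grid <- seq(0, 10, by = 0.5)
  R1 <- 1 + protocol$r1_relaxivity * C_grid
  S <- spgr_signal(1000, 1000 / R1, 18, protocol$TR_ms)
  expect_true(all(diff(S) > 0))  # larger C -> larger signal at these T1
})

test_that("AIF extraction applies the hematocrit plasma correction", {
  times <- frame_times()
  shape <- c(3, 3, 1)
  cb <- numeric(115); cb[40:60] <- 3.0   # blood peak 3 mM
  C <- array(rep(cb, each = prod(shape)), c(shape, 115))
  conc <- structure(list(data = C, frame_times_s = times,
                         n_invalid_frames = 0),
                    class = "concentration_series")
  amask <- voxel_mask(array(TRUE, shape), label = "artery")
  a <- extract_aif(conc, amask, hematocrit = 0.42)
  expect_equal(max(a$Cp), 3.0 / 0.58, tolerance = 1e-12)
  a0 <- extract_aif(conc, amask, hematocrit = 0)
  expect_equal(max(a0$Cp), 3.0)
  conc$data[] <- 0
  expect_warning(extract_aif(conc, amask), "low-quality AIF")
})
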