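# Forward-model correctness: extended Tofts, DP residue, DP convolution,
# and the finite-difference oracle.

test_that("extended Tofts limits match closed forms", {
  times <- frame_times()
  a <- fixture_aif(times)
  # pure-vascular limit
  expect_equal(et_forward(list(ktrans = 0, ve = 0, vp = 5), a, times),
               0.05 * a$Cp)
  # all-zero parameters
  expect_equal(et_forward(list(ktrans = 0, ve = 0, vp = 0), a, times),
               numeric(115))
  # constant input: Ctiss(t) = Ktrans/Kep (1 - exp(-Kep t))
  tg <- seq(0, 300, by = 0.5)
  step <- aif(tg, rep(1, length(tg)))
  ct <- et_forward(list(ktrans = 0.1, ve = 10, vp = 0), step, tg)
  expect_equal(ct[tg == 60], 0.1 * (1 - exp(-1)), tolerance = 1e-6)
  expect_error(et_forward(list(ktrans = 0.1, ve = 0, vp = 0), a, times),
               "Ve must be positive")
})

test_that("DP residue has the vascular plateau, no-exchange limit and area identity", {
  tt <- seq(0, 600, by = 0.05)
  p <- list(f = 12, tc_s = 15, ve = 6, ps = 6)
  R <- dp_residue(p, tt)
  expect_true(all(R[tt < 15] == 1))
  expect_true(all(diff(R) <= 1e-12))          # non-increasing
  expect_true(all(R >= 0 & R <= 1 + 1e-12))
  area <- sum(diff(tt / 60) * (R[-1] + R[-length(R)]) / 2)
  expect_equal(area, (12 * 15 / 60 + 6) / 12, tolerance = 5e-3)  # (Vp+Ve)/F
  # PS = 0: rectangular residue
  R0 <- dp_residue(list(f = 12, tc_s = 15, ve = 6, ps = 0), tt)
  expect_equal(R0, as.numeric(tt < 15))
  expect_error(dp_residue(list(f = 0, tc_s = 15, ve = 6, ps = 6), tt),
               "F > 0")
})

test_that("DP forward model equilibrates to (Vp+Ve)/100 of a constant input", {
  tg <- seq(0, 3600, by = 2.5)
  c0 <- 2
  ramp <- pmin(tg / 10, 1) * c0   # near-step input
  step <- aif(tg, ramp)
  p <- list(f = 13, tc_s = 14, ve = 6, ps = 8)
  ct <- dp_forward(p, step, tg)
  vp <- 13 * 14 / 60
  expect_equal(ct[length(ct)], (vp + 6) / 100 * c0, tolerance = 1e-3)
  # vascular-only plateau when PS = 0
  ct0 <- dp_forward(list(f = 13, tc_s = 14, ve = 6, ps = 0), step, tg)
  expect_equal(ct0[length(ct0)], vp / 100 * c0, tolerance = 1e-3)
})

test_that("DP forward agrees with the PDE oracle over the reported parameter range", {
  times <- frame_times()
  a <- fixture_aif(times)
  for (f in c(8, 13)) for (ps in c(4, 8)) {
    p <- list(f = f, tc_s = 60 * 2 / f, ve = 7, ps = ps)
    ct <- dp_forward(p, a, times)
    oracle <- dp_pde_oracle(p, a, times, n_segments = 200)
    expect_lt(max(abs(ct - oracle)), 0.01 * max(oracle))
  }
})

test_that("PDE oracle converges and reduces to plug-flow delay at PS = 0", {
  times <- frame_times()
  a <- fixture_aif(times)
  p <- list(f = 13, tc_s = 15, ve = 6, ps = 0)
  oracle <- dp_pde_oracle(p, a, times, n_segments = 300)
  # PS=0: tissue curve = (Vp/100) * box-average of the AIF over [t-Tc, t]
  vp <- 13 * 15 / 60
  I <- c(0, cumsum(diff(times) * (a$Cp[-1] + a$Cp[-115]) / 2))
  Ishift <- approx(times, I, xout = times - 15, yleft = 0, rule = 2)$y
  analytic <- (vp / 100) * (I - Ishift) / 15
  expect_lt(max(abs(oracle - analytic)), 0.02 * max(analytic))
  # grid refinement shrinks the gap to dp_forward
  p2 <- list(f = 13, tc_s = 15, ve = 6, ps = 8)
  ct <- dp_forward(p2, a, times)
  gap <- function(n) max(abs(dp_pde_oracle(p2, a, times, n) - ct))
  expect_lt(gap(400), gap(100))
})

test_that("DP collapses to the Tofts compartment model as Vp -> 0, PS/F -> 0", {
  times <- frame_times()
  a <- fixture_aif(times)
  p <- list(f = 100, tc_s = 0.001, ve = 8, ps = 1)
  ct_dp <- dp_forward(p, a, times)
  ct_et <- et_forward(list(ktrans = p$ps / 100, ve = 8, vp = 0), a, times)
  expect_lt(max(abs(ct_dp - ct_et)), 0.01 * max(ct_et))
})

test_that("derived parameters obey their defining identities", {
  times <- frame_times()
  a <- fixture_aif(times)
  fit <- fit_voxel(et_forward(list(ktrans = 0.10, ve = 8, vp = 1), a, times),
                   a, times, "et", seed = 2)
  pp <- derived_params(fit)
  expect_equal(unname(pp["kep"]), 100 * pp[["ktrans"]] / pp[["ve"]],
               tolerance = 1e-12)
  expect_equal(unname(pp["kep"]), 1.25, tolerance = 1e-3)
  fitd <- fit_voxel(dp_forward(list(f = 12, tc_s = 15, ve = 6, ps = 0), a, times),
                    a, times, "dp", seed = 2)
  pd <- derived_params(fitd)
  expect_equal(unname(pd["vp"]), pd[["f"]] * pd[["tc_s"]] / 60,
               tolerance = 1e-12)
  expect_equal(unname(pd["mtt_s"]), unname(pd["tc_s"]))
  expect_equal(unname(pd["e_pct"]),
               100 * (1 - exp(-pd[["ps"]] / pd[["f"]])), tolerance = 1e-12)
  # F=12, Tc=15 s -> Vp = 3 mL/100 mL; PS=0 -> E = 0
  expect_equal(unname(pd["vp"]), 3.0, tolerance = 0.05)
  expect_lt(abs(pd[["e_pct"]]), 1)
})
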