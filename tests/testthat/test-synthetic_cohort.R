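# Synthetic generator: AIF shape, group structure, file layout,
# determinism and construction-level consistency.

test_that("population AIF is causal, non-negative and peaks at t0 + scale", {
  tg <- seq(0, 1000, length.out = 1001)
  m <- aif_model()
  a <- population_aif(tg, m)
  expect_true(all(a$Cp[tg <= m$t0_s] == 0))
  expect_true(all(a$Cp >= 0))
  # gamma-variate term alone peaks at t0 + scale; with the small
  # recirculation term the overall peak stays within one sample of it
  fine <- seq(m$t0_s, m$t0_s + 60, by = 0.01)
  af <- population_aif(fine, m)
  gamma_only <- population_aif(fine, aif_model(A2 = 0))
  expect_equal(fine[which.max(gamma_only$Cp)], m$t0_s + m$scale_s,
               tolerance = 0.02)
  expect_equal(max(af$Cp), 5, tolerance = 0.15)   # ~5 mM bolus peak
  expect_error(aif_model(shape = -1), "positive")
})

test_that("patient parameter draws center on the configured group medians", {
  set.seed(11)
  lows <- replicate(400, sample_patient_params("low")$et$ktrans)
  set.seed(11)
  highs <- replicate(400, sample_patient_params("high")$dp$f)
  expect_equal(median(lows), 0.10, tolerance = 0.05)
  expect_equal(median(highs), 8.12, tolerance = 0.5)
  set.seed(12); p1 <- sample_patient_params("low")
  set.seed(12); p2 <- sample_patient_params("low")
  expect_identical(p1, p2)
  set.seed(13); p3 <- sample_patient_params("low")
  expect_false(identical(p1, p3))
})

test_that("cohort tables are risk-consistent by construction and reproducible", {
  tab <- simulate_cohort_table(6, 7, seed = 21)
  expect_equal(nrow(tab), 13)
  derived <- vapply(seq_len(nrow(tab)), function(i)
    classify_risk(tab$subtype[i], tab$grade[i], tab$dmi[i], tab$csi[i],
                  tab$lvsi[i], tab$lnm[i]), character(1))
  expect_identical(derived, tab$risk)
  expect_identical(tab, simulate_cohort_table(6, 7, seed = 21))
  # derived columns obey their identities
  expect_equal(tab$kep, 100 * tab$ktrans / tab$ve_et)
  expect_equal(tab$vp_dp, tab$f * tab$mtt_s / 60)
})

test_that("generated patients have the protocol's file layout and counts", {
  out <- withr::local_tempdir()
  set.seed(31)
  truth <- sample_patient_params("low")
  res <- generate_patient(truth, acquisition_protocol(), out,
                          geometry = c(8, 8, 3), roi_voxels = 10,
                          noise_snr = 20, seed = 31)
  dyn <- RNifti::readNifti(file.path(out, "dyn.nii.gz"))
  expect_equal(dim(dyn)[4], 115)
  for (fl in c(6, 12, 18)) {
    st <- RNifti::readNifti(file.path(out, sprintf("vfa_%02d.nii.gz", fl)))
    expect_equal(dim(st)[4], 10)
  }
  tm <- RNifti::readNifti(file.path(out, "tumor_mask.nii.gz"))
  expect_equal(sum(tm != 0), 10)
  am <- RNifti::readNifti(file.path(out, "artery_mask.nii.gz"))
  expect_equal(sum(am != 0), 3)
  expect_error(generate_patient(truth, acquisition_protocol(), out,
                                noise_snr = 0), "positive")
})

test_that("cohort generation is bit-identical for a fixed seed and refuses overwrite", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(2, 2, seed = 8, file.path(d1, "c"), geometry = c(6, 6, 3),
                  roi_voxels = 5, noise_snr = 20, force = TRUE)
  generate_cohort(2, 2, seed = 8, file.path(d2, "c"), geometry = c(6, 6, 3),
                  roi_voxels = 5, noise_snr = 20, force = TRUE)
  t1 <- read.csv(file.path(d1, "c", "truth.csv"))
  t2 <- read.csv(file.path(d2, "c", "truth.csv"))
  expect_identical(t1, t2)
  b1 <- readBin(file.path(d1, "c", "P001", "dyn.nii.gz"), "raw", 1e6)
  b2 <- readBin(file.path(d2, "c", "P001", "dyn.nii.gz"), "raw", 1e6)
  expect_identical(b1, b2)
  expect_error(generate_cohort(1, 1, seed = 8, file.path(d1, "c")),
               "force")
})

test_that("simulated reader calls track the configured operating points", {
  tab <- simulate_cohort_table(300, 300, seed = 41)
  hi <- tab$risk == "high"
  expect_equal(mean(tab$reader_dmi[hi]), 0.58, tolerance = 0.08)
  expect_equal(mean(!tab$reader_dmi[!hi]), 0.68, tolerance = 0.08)
  expect_equal(mean(!tab$reader_csi[!hi]), 1.00, tolerance = 0.01)
  # MVD group medians near 55 / 90 vessels per mm^2
  expect_equal(median(tab$mvd[!hi]), 55, tolerance = 0.1 * 55)
  expect_equal(median(tab$mvd[hi]), 90, tolerance = 0.1 * 90)
})
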