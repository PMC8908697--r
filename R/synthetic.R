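# Synthetic-cohort generator: population AIF, group-structured kinetic
# truths, SPGR signal synthesis with noise, masks and clinical tables.
# Every output is fully determined by (seed, configuration).

#' Population arterial input function model
#'
#' Gamma-variate first pass plus a recirculation/washout term:
#' `Cp(t) = A1 ((t-t0)/b)^a exp(a - a (t-t0)/b)
#'        + A2 (1 - exp(-(t-t0)/c)) exp(-(t-t0)/d)` for `t >= t0`, 0 before.
#' The gamma term peaks at `t = t0 + b` with height `A1`. Defaults give a
#' plasma peak near 5 mM about 15 s after bolus arrival and a tail near
#' 1 mM at 4 min, typical of a standard-dose gadolinium bolus.
#'
#' The default arrival of 30 s leaves the protocol's 10 baseline frames
#' (25 s at 2.5 s spacing) contrast-free.
#'
#' @param t0_s bolus arrival time (s)
#' @param A1 first-pass amplitude (mM)
#' @param shape gamma-variate shape `a` (dimensionless, > 0)
#' @param scale_s gamma-variate scale `b` (s, > 0); time-to-peak after t0
#' @param A2 recirculation amplitude (mM)
#' @param wash_in_s recirculation wash-in constant `c` (s)
#' @param wash_out_s washout constant `d` (s)
#' @return object of class `aif_model`
#' @export
aif_model <- function(t0_s = 30, A1 = 4.0, shape = 3, scale_s = 15,
                      A2 = 1.5, wash_in_s = 12, wash_out_s = 480) {
  if (shape <= 0 || scale_s <= 0 || wash_in_s <= 0 || wash_out_s <= 0)
    stop("shape/scale parameters must be positive")
  structure(list(t0_s = t0_s, A1 = A1, shape = shape, scale_s = scale_s,
                 A2 = A2, wash_in_s = wash_in_s, wash_out_s = wash_out_s),
            class = "aif_model")
}

#' Evaluate the population AIF on a time grid
#'
#' @param times_s increasing time grid (s)
#' @param model `aif_model`
#' @return `aif` object (plasma concentration, mM)
#' @export
population_aif <- function(times_s, model = aif_model()) {
  stopifnot(inherits(model, "aif_model"))
  if (any(diff(times_s) <= 0)) stop("times must be increasing")
  tau <- times_s - model$t0_s
  Cp <- numeric(length(times_s))
  pos <- tau > 0
  a <- model$shape; b <- model$scale_s
  Cp[pos] <- model$A1 * (tau[pos] / b)^a * exp(a - a * tau[pos] / b) +
    model$A2 * (1 - exp(-tau[pos] / model$wash_in_s)) *
      exp(-tau[pos] / model$wash_out_s)
  aif(times_s, Cp)
}

#' Cohort-generation configuration
#'
#' Group medians default to the published low/high-risk medians of the
#' endometrial-carcinoma study the generator emulates (Ktrans 0.10/0.05
#' min^-1, F 13.01/8.12, PS 8.32/4.01 mL/min/100 mL, Vp(DP) 3.03/1.46 and
#' Ve(DP) 6.17/6.31 mL/100 mL; MVD 55/90 vessels/mm^2). Patient-level
#' spread is log-normal with `log_sd` 0.3 (0.4 for MVD). ET truths are
#' generated coherently with the DP truths: Ve(ET) and Vp(ET) are the DP
#' draws scaled by fixed factors (defaults 1.3 and 0.34, the ratios of the
#' published cross-model medians). Reader calls are simulated conditional
#' on the true risk group with sensitivity/specificity defaults matching
#' the published radiologist performance (DMI 58/68, CSI 19/100,
#' LNM 31/96, in %).
#'
#' @param medians_low,medians_high named lists of group medians
#'   (`ktrans`, `f`, `vp_dp`, `ve_dp`, `ps`, `mvd`)
#' @param log_sd log-normal sd of the kinetic draws
#' @param mvd_log_sd log-normal sd of the MVD draws
#' @param ve_et_factor,vp_et_factor ET/DP scale factors for Ve and Vp
#' @param reader_sens,reader_spec named vectors (dmi, csi, lnm), fractions
#' @param t1_tissue_ms,t1_blood_ms,t1_background_ms precontrast T1 defaults
#' @param m0 equilibrium signal scale (a.u.)
#' @param aif `aif_model` used for every patient
#' @param truth_model `"dp"` (default; realistic model mismatch for ET
#'   fitting) or `"et"` (pure recovery tests)
#' @param heterogeneity_log_sd per-voxel jitter of tumor truths (0 = off)
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(medians_low = list(ktrans = 0.10, f = 13.01,
                                             vp_dp = 3.03, ve_dp = 6.17,
                                             ps = 8.32, mvd = 55),
                          medians_high = list(ktrans = 0.05, f = 8.12,
                                              vp_dp = 1.46, ve_dp = 6.31,
                                              ps = 4.01, mvd = 90),
                          log_sd = 0.3, mvd_log_sd = 0.4,
                          ve_et_factor = 1.3, vp_et_factor = 0.34,
                          reader_sens = c(dmi = 0.58, csi = 0.19, lnm = 0.31),
                          reader_spec = c(dmi = 0.68, csi = 1.00, lnm = 0.96),
                          t1_tissue_ms = 1000, t1_blood_ms = 1400,
                          t1_background_ms = 800, m0 = 1000,
                          aif = aif_model(),
                          truth_model = c("dp", "et"),
                          heterogeneity_log_sd = 0) {
  truth_model <- match.arg(truth_model)
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw one patient's ground-truth kinetic parameters
#'
#' Log-normal draws centered (in median) on the group medians; the DP
#' primitives (F, Vp, Ve, PS) are drawn and `Tc = 60 Vp / F` derived; the
#' ET truths share the Ve/Vp draws through fixed scale factors so the two
#' models are coherent within a patient. Uses the current RNG state —
#' seed with `set.seed()` for reproducibility.
#'
#' @param group `"low"` or `"high"`
#' @param config `cohort_config`
#' @return named list with `et` (ktrans, ve, vp), `dp` (f, tc_s, ve, ps)
#'   and `mvd`
#' @export
sample_patient_params <- function(group = c("low", "high"),
                                  config = cohort_config()) {
  group <- match.arg(group)
  med <- if (group == "low") config$medians_low else config$medians_high
  draw <- function(m, s = config$log_sd) m * exp(stats::rnorm(1, 0, s))
  f <- draw(med$f)
  vp_dp <- draw(med$vp_dp)
  ve_dp <- draw(med$ve_dp)
  ps <- draw(med$ps)
  ktrans <- draw(med$ktrans)
  mvd <- draw(med$mvd, config$mvd_log_sd)
  list(et = list(ktrans = ktrans, ve = ve_dp * config$ve_et_factor,
                 vp = vp_dp * config$vp_et_factor),
       dp = list(f = f, tc_s = 60 * vp_dp / f, ve = ve_dp, ps = ps),
       mvd = mvd)
}

# clinical flags for one patient, consistent with the risk rule
.sample_clinical <- function(group) {
  if (group == "low") {
    list(subtype = "endometrioid", grade = sample(1:2, 1),
         dmi = FALSE, csi = FALSE, lvsi = FALSE, lnm = FALSE)
  } else {
    subtype <- if (stats::runif(1) < 0.6) "nonendometrioid" else "endometrioid"
    grade <- if (subtype == "endometrioid")
      sample(1:3, 1, prob = c(0.2, 0.2, 0.6)) else NA
    flags <- stats::runif(4) < c(0.40, 0.15, 0.30, 0.20)
    # endometrioid grade 1-2 must carry at least one flag to be high risk
    if (subtype == "endometrioid" && grade <= 2 && !any(flags))
      flags[1] <- TRUE
    list(subtype = subtype, grade = grade,
         dmi = flags[1], csi = flags[2], lvsi = flags[3], lnm = flags[4])
  }
}

.sample_reader <- function(truth_high, sens, spec) {
  if (truth_high) stats::runif(1) < sens else stats::runif(1) < 1 - spec
}

#' Simulate a per-patient cohort table (no imaging)
#'
#' Draws ground-truth kinetic parameters, pathology flags consistent with
#' the risk rule, simulated consensus reader calls and MVD for `n_low`
#' low-risk and `n_high` high-risk patients. The kinetic truths stand in
#' for the per-patient ROI medians, so the table feeds
#' [run_group_comparison()] directly.
#'
#' @param n_low,n_high group sizes (defaults 25/26, a 51-patient cohort)
#' @param seed RNG seed; the output is fully determined by (seed, config)
#' @param config `cohort_config`
#' @return `data.frame` with clinical columns and parameter medians
#' @export
simulate_cohort_table <- function(n_low = 25, n_high = 26, seed = 1,
                                  config = cohort_config()) {
  stopifnot(n_low >= 1, n_high >= 1)
  set.seed(seed)
  groups <- c(rep("low", n_low), rep("high", n_high))
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    pars <- sample_patient_params(g, config)
    cl <- .sample_clinical(g)
    truth_high <- g == "high"
    et <- pars$et; dp <- pars$dp
    data.frame(
      id = sprintf("P%03d", i), risk = g,
      subtype = cl$subtype, grade = cl$grade,
      dmi = cl$dmi, csi = cl$csi, lvsi = cl$lvsi, lnm = cl$lnm,
      reader_dmi = .sample_reader(truth_high, config$reader_sens["dmi"],
                                  config$reader_spec["dmi"]),
      reader_csi = .sample_reader(truth_high, config$reader_sens["csi"],
                                  config$reader_spec["csi"]),
      reader_lnm = .sample_reader(truth_high, config$reader_sens["lnm"],
                                  config$reader_spec["lnm"]),
      mvd = pars$mvd,
      ktrans = et$ktrans, ve_et = et$ve, vp_et = et$vp,
      kep = 100 * et$ktrans / et$ve,
      f = dp$f, mtt_s = dp$tc_s, vp_dp = dp$f * dp$tc_s / 60,
      ve_dp = dp$ve, ps = dp$ps,
      e_pct = 100 * (1 - exp(-dp$ps / dp$f)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate one synthetic patient's image files
#'
#' Builds the full acquisition for one patient on a small 3D grid: a tumor
#' ROI whose voxels follow the ground-truth tissue curve (DP- or
#' ET-generated per `config$truth_model`, optional per-voxel log-normal
#' jitter), an artery ROI carrying the blood-form AIF
#' (`Cp (1 - Hct)`), concentration converted to SPGR signal through the
#' per-tissue precontrast T1, one 4D dynamic series, one 10-repeat
#' precontrast stack per flip angle, and the two masks. Additive Gaussian
#' noise on the signal with sd = baseline/`noise_snr` (`rician = TRUE`
#' applies magnitude-type noise instead); `noise_snr = Inf` is noiseless.
#'
#' @param truth list as returned by [sample_patient_params()]
#' @param protocol `acquisition_protocol`
#' @param out_dir patient output directory (created)
#' @param geometry spatial grid (default 16 x 16 x 9)
#' @param roi_voxels tumor ROI size in voxels (study median: 40)
#' @param noise_snr baseline signal-to-noise ratio (> 0)
#' @param seed RNG seed for noise and jitter
#' @param config `cohort_config`
#' @param rician use magnitude (Rician) noise instead of Gaussian
#' @return invisible list with the file paths and the noiseless tumor curve
#' @export
generate_patient <- function(truth, protocol = acquisition_protocol(),
                             out_dir, geometry = c(16, 16, 9),
                             roi_voxels = 40, noise_snr = Inf, seed = 1,
                             config = cohort_config(), rician = FALSE) {
  if (noise_snr <= 0) stop("noise_snr must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  nt <- protocol$n_dynamic
  times <- (seq_len(nt) - 1) * protocol$dt_s
  Cp <- population_aif(times, config$aif)
  # geometry: tumor block in the volume center, artery column in a corner
  stopifnot(prod(geometry) >= roi_voxels + geometry[3])
  artery <- array(FALSE, geometry)
  artery[1, 1, ] <- TRUE
  tumor <- array(FALSE, geometry)
  avail <- which(!artery)
  tumor[avail[floor(length(avail) / 3) + seq_len(roi_voxels)]] <- TRUE
  # ground-truth tissue curve
  ct_true <- if (config$truth_model == "dp")
    dp_forward(truth$dp, Cp, times) else et_forward(truth$et, Cp, times)
  cb <- Cp$Cp * (1 - protocol$hematocrit)   # blood-form AIF in the artery
  # per-voxel concentration
  T10 <- array(config$t1_background_ms, geometry)
  T10[tumor] <- config$t1_tissue_ms
  T10[artery] <- config$t1_blood_ms
  nv <- prod(geometry)
  C <- matrix(0, nv, nt)
  ti <- which(tumor)
  jit <- if (config$heterogeneity_log_sd > 0)
    exp(stats::rnorm(length(ti), 0, config$heterogeneity_log_sd)) else
      rep(1, length(ti))
  C[ti, ] <- outer(jit, ct_true)
  C[which(artery), ] <- matrix(cb, sum(artery), nt, byrow = TRUE)
  # concentration -> SPGR signal
  R10 <- 1000 / as.vector(T10)
  R1 <- R10 + protocol$r1_relaxivity * C          # s^-1
  T1t <- 1000 / R1                                 # ms
  S <- spgr_signal(config$m0, T1t, protocol$dyn_flip_deg, protocol$TR_ms)
  dyn <- array(S, c(geometry, nt))
  add_noise <- function(arr, sd) {
    if (!is.finite(noise_snr)) return(arr)
    if (rician) {
      re <- arr + stats::rnorm(length(arr), 0, sd)
      im <- stats::rnorm(length(arr), 0, sd)
      array(sqrt(re^2 + im^2), dim(arr))
    } else {
      arr + array(stats::rnorm(length(arr), 0, sd), dim(arr))
    }
  }
  sd0 <- mean(dyn[, , , 1]) / noise_snr
  dyn <- pmax(add_noise(dyn, if (is.finite(noise_snr)) sd0 else 0), 0)
  paths <- list(dynamic = file.path(out_dir, "dyn.nii.gz"),
                tumor_mask = file.path(out_dir, "tumor_mask.nii.gz"),
                artery_mask = file.path(out_dir, "artery_mask.nii.gz"))
  write_volume(dyn, paths$dynamic)
  write_volume(array(as.numeric(tumor), geometry), paths$tumor_mask)
  write_volume(array(as.numeric(artery), geometry), paths$artery_mask)
  for (fl in protocol$vfa_flips_deg) {
    Sf <- spgr_signal(config$m0, as.vector(T10), fl, protocol$TR_ms)
    stack <- array(Sf, c(geometry, protocol$n_baseline_per_flip))
    stack <- pmax(add_noise(stack, if (is.finite(noise_snr)) sd0 else 0), 0)
    p <- file.path(out_dir, sprintf("vfa_%02d.nii.gz", fl))
    write_volume(stack, p)
    paths[[sprintf("vfa_%02d", fl)]] <- p
  }
  invisible(c(paths, list(ct_true = ct_true, times_s = times)))
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one directory per patient (dynamic series, VFA stacks, tumor and
#' artery masks), a ground-truth table `truth.csv`, a clinical table
#' `clinical.csv` and a `config.yaml` protocol snapshot. Refuses to write
#' into a non-empty directory unless `force = TRUE`. Bit-identical across
#' runs for a fixed (seed, config).
#'
#' @param n_low,n_high group sizes
#' @param seed master seed; per-patient seeds are derived from it
#' @param out_dir cohort directory
#' @param protocol `acquisition_protocol`
#' @param config `cohort_config`
#' @param geometry,roi_voxels,noise_snr,rician passed to [generate_patient()]
#' @param force overwrite a non-empty `out_dir`
#' @return invisible path of `out_dir`
#' @export
generate_cohort <- function(n_low, n_high, seed, out_dir,
                            protocol = acquisition_protocol(),
                            config = cohort_config(),
                            geometry = c(16, 16, 9), roi_voxels = 40,
                            noise_snr = Inf, rician = FALSE, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- simulate_cohort_table(n_low, n_high, seed, config)
  for (i in seq_len(nrow(tab))) {
    truth <- list(et = list(ktrans = tab$ktrans[i], ve = tab$ve_et[i],
                            vp = tab$vp_et[i]),
                  dp = list(f = tab$f[i], tc_s = tab$mtt_s[i],
                            ve = tab$ve_dp[i], ps = tab$ps[i]))
    generate_patient(truth, protocol,
                     out_dir = file.path(out_dir, tab$id[i]),
                     geometry = geometry, roi_voxels = roi_voxels,
                     noise_snr = noise_snr, seed = (seed + i) %% 2147483647,
                     config = config, rician = rician)
  }
  utils::write.csv(tab, file.path(out_dir, "truth.csv"), row.names = FALSE)
  clinical <- tab[, c("id", "risk", "subtype", "grade", "dmi", "csi",
                      "lvsi", "lnm", "reader_dmi", "reader_csi",
                      "reader_lnm", "mvd")]
  utils::write.csv(clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  write_protocol_yaml(protocol, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Build a synthetic recruitment roster with the study's exclusion counts
#'
#' Returns a roster of `n` records of which exactly the given numbers fail
#' each eligibility check (in the exclusion-priority order: lesion not
#' evaluable, consent refused, therapy changed, diagnosis not confirmed,
#' AIF failure), shuffled by `seed`. Defaults reproduce the published
#' recruitment flow: 112 recruited, exclusions 33+9+7+6+6, 51 analyzed.
#'
#' @param n roster size
#' @param counts exclusions per category, in priority order
#' @param seed shuffle seed
#' @return data.frame consumable by [apply_exclusions()]
#' @export
synthetic_roster <- function(n = 112, counts = c(33, 9, 7, 6, 6), seed = 1) {
  stopifnot(sum(counts) <= n, length(counts) == 5)
  set.seed(seed)
  fail_cat <- rep(0L, n)
  fail_cat[seq_len(sum(counts))] <- rep(seq_along(counts), counts)
  fail_cat <- sample(fail_cat)
  data.frame(id = sprintf("R%03d", seq_len(n)),
             lesion_ok = fail_cat != 1L,
             consented = fail_cat != 2L,
             therapy_unchanged = fail_cat != 3L,
             diagnosis_confirmed = fail_cat != 4L,
             aif_ok = fail_cat != 5L,
             stringsAsFactors = FALSE)
}
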