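# Study orchestration: simulate -> fit -> compare, with exclusion
# accounting and structured logs. These functions are the programmatic
# interface; inst/cli/dce_study.R wraps them for shell use.

#' Simulate a synthetic cohort (pipeline stage 1)
#'
#' Thin wrapper around [generate_cohort()] with pipeline-style defaults.
#'
#' @inheritParams generate_cohort
#' @return invisible `out_dir`
#' @export
cmd_simulate <- function(out_dir, n_low = 25, n_high = 26, seed = 1,
                         protocol = acquisition_protocol(),
                         config = cohort_config(), geometry = c(16, 16, 9),
                         roi_voxels = 40, noise_snr = Inf, force = FALSE) {
  generate_cohort(n_low, n_high, seed, out_dir, protocol = protocol,
                  config = config, geometry = geometry,
                  roi_voxels = roi_voxels, noise_snr = noise_snr,
                  force = force)
}

# run the relaxometry + AIF + fitting chain for one patient directory
.fit_patient <- function(pdir, protocol, models, n_starts, seed, oversample,
                         baseline_frames) {
  need <- c("dyn.nii.gz", "tumor_mask.nii.gz", "artery_mask.nii.gz",
            sprintf("vfa_%02d.nii.gz", protocol$vfa_flips_deg))
  present <- file.exists(file.path(pdir, need))
  if (!all(present))
    return(list(ok = FALSE,
                reason = paste("missing", paste(need[!present],
                                                collapse = ", "))))
  series <- load_dynamic_series(file.path(pdir, "dyn.nii.gz"), protocol)
  tumor <- load_mask(file.path(pdir, "tumor_mask.nii.gz"), series, "tumor")
  artery <- tryCatch(
    load_mask(file.path(pdir, "artery_mask.nii.gz"), series, "artery"),
    error = function(e) NULL)
  if (is.null(artery)) return(list(ok = FALSE, reason = "empty artery mask"))
  stacks <- lapply(protocol$vfa_flips_deg, function(fl)
    as.array(RNifti::readNifti(file.path(pdir, sprintf("vfa_%02d.nii.gz", fl)))))
  t1m0 <- fit_vfa_t1_map(stacks, protocol$vfa_flips_deg, protocol$TR_ms)
  conc <- signal_to_concentration(series, t1m0, protocol,
                                  baseline_frames = baseline_frames)
  low_quality <- FALSE
  aif_ <- withCallingHandlers(
    extract_aif(conc, artery, protocol$hematocrit,
                baseline_frames = baseline_frames),
    warning = function(w) {
      if (grepl("low-quality AIF", conditionMessage(w))) {
        low_quality <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (low_quality) return(list(ok = FALSE, reason = "AIF failure"))
  out <- list(ok = TRUE, medians = list(), diagnostics = list())
  for (m in models) {
    fit <- fit_roi(conc, tumor, aif_, m, n_starts = n_starts, seed = seed,
                   oversample = oversample)
    out$medians[[m]] <- fit$medians
    out$diagnostics[[m]] <- list(n_fitted = fit$n_fitted,
                                 n_failed = fit$n_failed)
  }
  out
}

#' Fit every patient of a cohort directory (pipeline stage 2)
#'
#' For each patient: VFA T1 map, concentration conversion, AIF
#' extraction, voxelwise ET/DP fitting, median aggregation. Patients with
#' missing files or a failed AIF are skipped and listed once in the
#' exclusions block with a reason code. Writes `medians.csv` and a
#' `fit_log.json` diagnostics file into `cohort_dir`.
#'
#' @param cohort_dir directory as produced by [cmd_simulate()]
#' @param protocol `acquisition_protocol`
#' @param models character subset of `c("et", "dp")`
#' @param n_starts,oversample fitting controls (see [fit_voxel()])
#' @param seed fitting multi-start seed
#' @param baseline_frames precontrast dynamic frames
#' @return data.frame of per-patient medians (one column per parameter),
#'   with attribute `"exclusions"`
#' @export
cmd_fit <- function(cohort_dir, protocol = acquisition_protocol(),
                    models = c("et", "dp"), n_starts = 8, seed = 1,
                    oversample = 5, baseline_frames = 10) {
  models <- match.arg(models, c("et", "dp"), several.ok = TRUE)
  pdirs <- list.dirs(cohort_dir, recursive = FALSE)
  if (!length(pdirs)) stop("no patient directories under ", cohort_dir)
  rows <- list(); exclusions <- list()
  for (pdir in pdirs) {
    id <- basename(pdir)
    res <- .fit_patient(pdir, protocol, models, n_starts, seed, oversample,
                        baseline_frames)
    if (!res$ok) {
      message(sprintf("cmd_fit: skipping %s (%s)", id, res$reason))
      exclusions[[id]] <- res$reason
      next
    }
    row <- data.frame(id = id, stringsAsFactors = FALSE)
    if ("et" %in% models) {
      m <- res$medians$et
      row$ktrans <- m[["ktrans"]]; row$ve_et <- m[["ve"]]
      row$vp_et <- m[["vp"]]; row$kep <- m[["kep"]]
    }
    if ("dp" %in% models) {
      m <- res$medians$dp
      row$f <- m[["f"]]; row$mtt_s <- m[["mtt_s"]]; row$vp_dp <- m[["vp"]]
      row$ve_dp <- m[["ve"]]; row$ps <- m[["ps"]]; row$e_pct <- m[["e_pct"]]
    }
    rows[[id]] <- row
  }
  medians <- do.call(rbind, rows)
  attr(medians, "exclusions") <- exclusions
  utils::write.csv(medians, file.path(cohort_dir, "medians.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(exclusions = exclusions, models = models, seed = seed,
         n_patients_fitted = nrow(medians)),
    file.path(cohort_dir, "fit_log.json"), auto_unbox = TRUE, digits = NA)
  medians
}

#' Compare groups and write the study report (pipeline stage 3)
#'
#' Joins the per-patient medians with the clinical table, verifies the
#' risk labels against the pathology-based rule, runs
#' [run_group_comparison()] and serializes the report.
#'
#' @param medians data.frame from [cmd_fit()] (or path to `medians.csv`)
#' @param clinical data.frame or path to `clinical.csv`
#' @param out_dir report output directory
#' @param fdr_family `"model"` or `"global"`
#' @param seed recorded in the provenance block
#' @return `study_report`, invisibly
#' @export
cmd_compare <- function(medians, clinical, out_dir = NULL,
                        fdr_family = "model", seed = NA) {
  if (is.character(medians)) medians <- utils::read.csv(medians)
  if (is.character(clinical)) clinical <- read_cohort_table(clinical)
  cohort <- merge(clinical, medians, by = "id")
  if (!"risk" %in% names(cohort))
    cohort$risk <- vapply(seq_len(nrow(cohort)), function(i)
      classify_risk(cohort$subtype[i], cohort$grade[i], cohort$dmi[i],
                    cohort$csi[i], cohort$lvsi[i], cohort$lnm[i]),
      character(1))
  for (g in c("low", "high"))
    if (sum(cohort$risk == g) < 2)
      stop("need at least 2 patients in the ", g, "-risk class")
  report <- run_group_comparison(cohort, fdr_family = fdr_family)
  if (!is.null(out_dir)) {
    prov <- list(seed = seed,
                 config_hash = substr(paste(deparse(fdr_family),
                                            collapse = ""), 1, 64),
                 n_patients = nrow(cohort),
                 package_version = as.character(
                   utils::packageVersion("dcekinetics")))
    write_study_report(report, out_dir, provenance = prov)
  }
  invisible(report)
}

#' Run the full study replication end to end
#'
#' Simulate a cohort, fit every patient and produce the comparison
#' report — each stage delegating to its `cmd_*` function.
#'
#' @param out_dir working directory for cohort and report
#' @param n_low,n_high group sizes
#' @param seed master seed for simulation and fitting
#' @param noise_snr baseline SNR of the synthetic acquisition
#' @param models models to fit
#' @param geometry,roi_voxels synthetic geometry
#' @param n_starts multi-start count
#' @param protocol,config generator configuration
#' @param force overwrite an existing cohort directory
#' @return `study_report`, invisibly
#' @export
run_study <- function(out_dir, n_low = 25, n_high = 26, seed = 1,
                      noise_snr = Inf, models = c("et", "dp"),
                      geometry = c(16, 16, 9), roi_voxels = 40,
                      n_starts = 8, protocol = acquisition_protocol(),
                      config = cohort_config(), force = FALSE) {
  cohort_dir <- file.path(out_dir, "cohort")
  cmd_simulate(cohort_dir, n_low, n_high, seed, protocol = protocol,
               config = config, geometry = geometry,
               roi_voxels = roi_voxels, noise_snr = noise_snr,
               force = force)
  medians <- cmd_fit(cohort_dir, protocol, models = models,
                     n_starts = n_starts, seed = seed)
  cmd_compare(medians, file.path(cohort_dir, "clinical.csv"),
              out_dir = file.path(out_dir, "report"), seed = seed)
}
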