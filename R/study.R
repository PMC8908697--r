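# Assembly of the full low- vs high-risk study comparison from a cohort
# table of per-patient median kinetic parameters and clinical data.

# parameter -> (model family, pretty name) registry
.param_registry <- data.frame(
  column = c("ktrans", "vp_et", "ve_et", "kep",
             "f", "mtt_s", "vp_dp", "ve_dp", "ps", "e_pct"),
  model = c(rep("et", 4), rep("dp", 6)),
  label = c("Ktrans", "Vp(ET)", "Ve(ET)", "Kep",
            "F", "MTT", "Vp(DP)", "Ve(DP)", "PS", "E"),
  stringsAsFactors = FALSE)

#' Run the complete low- vs high-risk group comparison
#'
#' Produces the study-report blocks: per-parameter group comparison
#' (medians with distribution-free 95% CIs, Mann-Whitney p, BH-FDR
#' adjusted within model families by default or globally), cross-model
#' agreement for Ve and Vp (Bland-Altman + Wilcoxon + Spearman) plus
#' Ktrans-vs-DP correlations, ROC diagnostics for every parameter and MVD,
#' and McNemar comparisons of the two headline DCE classifiers (Ktrans and
#' F at their Youden cutoffs) against the radiologist DMI/CSI/LNM reads.
#' Patients with missing medians are dropped from the affected analyses
#' with a log message.
#'
#' @param cohort data.frame with columns `id`, `risk` (`"low"`/`"high"`),
#'   parameter-median columns (any of `ktrans, vp_et, ve_et, kep, f,
#'   mtt_s, vp_dp, ve_dp, ps, e_pct`), and optionally `mvd`,
#'   `reader_dmi`, `reader_csi`, `reader_lnm`
#' @param fdr_family `"model"` (default: one family per kinetic model) or
#'   `"global"` (a single family across all parameters)
#' @return object of class `study_report`: list of blocks
#'   `group_comparison`, `agreement`, `roc`, `reader_comparison`,
#'   `n_low`, `n_high`
#' @export
run_group_comparison <- function(cohort, fdr_family = c("model", "global")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(all(c("id", "risk") %in% names(cohort)))
  if (!all(cohort$risk %in% c("low", "high")))
    stop("risk labels must be 'low'/'high'")
  if (length(unique(cohort$risk)) < 2)
    stop("both risk classes must be present; missing: ",
         setdiff(c("low", "high"), unique(cohort$risk)))
  params <- .param_registry[.param_registry$column %in% names(cohort), ]

  ## --- per-parameter group comparison ------------------------------------
  rows <- lapply(seq_len(nrow(params)), function(i) {
    col <- params$column[i]
    v <- cohort[[col]]
    keep <- is.finite(v)
    if (any(!keep))
      message(sprintf("group comparison: dropped %d patient(s) with missing %s",
                      sum(!keep), col))
    lo <- v[keep & cohort$risk == "low"]
    hi <- v[keep & cohort$risk == "high"]
    ci_lo <- median_ci(lo); ci_hi <- median_ci(hi)
    mw <- mann_whitney_u(lo, hi)
    data.frame(parameter = params$label[i], column = col,
               model = params$model[i],
               low_median = ci_lo$median, low_ci_low = ci_lo$ci_low,
               low_ci_high = ci_lo$ci_high,
               high_median = ci_hi$median, high_ci_low = ci_hi$ci_low,
               high_ci_high = ci_hi$ci_high,
               p_raw = mw$p_raw, stringsAsFactors = FALSE)
  })
  tab2 <- do.call(rbind, rows)
  if (!is.null(tab2)) {
    fam <- if (fdr_family == "model") tab2$model else rep("all", nrow(tab2))
    tab2$p_adjusted <- fdr_adjust(tab2$p_raw, fam)
    tab2$significant <- tab2$p_adjusted < 0.05
  }

  ## --- cross-model agreement ---------------------------------------------
  agreement <- list()
  for (pair in list(c("ve_et", "ve_dp", "Ve"), c("vp_et", "vp_dp", "Vp"))) {
    if (all(pair[1:2] %in% names(cohort))) {
      keep <- is.finite(cohort[[pair[1]]]) & is.finite(cohort[[pair[2]]])
      agreement[[pair[3]]] <- list(
        bland_altman = bland_altman(cohort[[pair[1]]][keep],
                                    cohort[[pair[2]]][keep]),
        spearman = spearman_cor(cohort[[pair[1]]][keep],
                                cohort[[pair[2]]][keep]))
    }
  }
  correlations <- list()
  if ("ktrans" %in% names(cohort))
    for (col in intersect(c("f", "ps", "vp_dp"), names(cohort))) {
      keep <- is.finite(cohort$ktrans) & is.finite(cohort[[col]])
      correlations[[paste0("ktrans_vs_", col)]] <-
        spearman_cor(cohort$ktrans[keep], cohort[[col]][keep])
    }

  ## --- ROC diagnostics ----------------------------------------------------
  roc_cols <- c(params$column, intersect("mvd", names(cohort)))
  roc <- stats::setNames(lapply(roc_cols, function(col) {
    keep <- is.finite(cohort[[col]])
    roc_analysis(cohort[[col]][keep], cohort$risk[keep], "high")
  }), roc_cols)

  ## --- McNemar vs radiologist reads ---------------------------------------
  reader_cmp <- NULL
  reader_cols <- intersect(c("reader_dmi", "reader_csi", "reader_lnm"),
                           names(cohort))
  dce_cols <- intersect(c("ktrans", "f"), names(cohort))
  if (length(reader_cols) && length(dce_cols)) {
    truth <- cohort$risk == "high"
    pred <- lapply(stats::setNames(dce_cols, dce_cols),
                   function(col) roc[[col]]$predicted_positive)
    for (rc in reader_cols) pred[[rc]] <- as.logical(cohort[[rc]])
    metric_rows <- lapply(names(pred), function(nm) {
      p <- pred[[nm]]
      correct <- p == truth
      data.frame(predictor = nm,
                 accuracy = 100 * mean(correct),
                 sensitivity = 100 * mean(p[truth]),
                 specificity = 100 * mean(!p[!truth]),
                 stringsAsFactors = FALSE)
    })
    metrics <- do.call(rbind, metric_rows)
    strata <- list(accuracy = rep(TRUE, nrow(cohort)),
                   sensitivity = truth, specificity = !truth)
    tests <- list()
    for (rc in reader_cols) for (dc in dce_cols) for (met in names(strata)) {
      s <- strata[[met]]
      ca <- (pred[[dc]] == truth)[s]
      cb <- (pred[[rc]] == truth)[s]
      tests[[paste(rc, "vs", dc, met, sep = "_")]] <- mcnemar_paired(ca, cb)
    }
    reader_cmp <- list(metrics = metrics, mcnemar = tests)
  }

  structure(list(group_comparison = tab2,
                 agreement = agreement,
                 correlations = correlations,
                 roc = roc,
                 reader_comparison = reader_cmp,
                 fdr_family = fdr_family,
                 n_low = sum(cohort$risk == "low"),
                 n_high = sum(cohort$risk == "high")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d low-risk vs %d high-risk patients\n",
              x$n_low, x$n_high))
  if (!is.null(x$group_comparison)) {
    cat("\nGroup comparison (Mann-Whitney, BH-FDR per", x$fdr_family,
        "family):\n")
    df <- x$group_comparison
    print(data.frame(parameter = df$parameter,
                     low = sprintf("%.3g (%.3g-%.3g)", df$low_median,
                                   df$low_ci_low, df$low_ci_high),
                     high = sprintf("%.3g (%.3g-%.3g)", df$high_median,
                                    df$high_ci_low, df$high_ci_high),
                     p = signif(df$p_raw, 2),
                     p_adj = signif(df$p_adjusted, 2),
                     sig = ifelse(df$significant, "*", "")),
          row.names = FALSE)
  }
  if (length(x$roc)) {
    cat("\nROC (positive = high risk):\n")
    for (nm in names(x$roc)) {
      r <- x$roc[[nm]]
      cat(sprintf("  %-8s AUC %.2f (%.2f-%.2f)  acc %.0f%%  sens %.0f%%  spec %.0f%%\n",
                  nm, r$auc, r$auc_ci_low, r$auc_ci_high,
                  r$accuracy, r$sensitivity, r$specificity))
    }
  }
  invisible(x)
}

#' Serialize a study report to JSON and CSV tables
#'
#' Writes `report.json` (full nested report), `group_comparison.csv`,
#' `roc.csv` and, when present, `reader_comparison.csv` into `out_dir`.
#'
#' @param report `study_report`
#' @param out_dir output directory (created if needed)
#' @param provenance optional list (config hash, seed, versions) stored
#'   under `provenance` in the JSON
#' @return `out_dir`, invisibly
#' @export
write_study_report <- function(report, out_dir, provenance = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- report
  ser$roc <- lapply(report$roc, function(r)
    r[setdiff(names(r), "predicted_positive")])
  ser$provenance <- provenance
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  utils::write.csv(report$group_comparison,
                   file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)
  roc_df <- do.call(rbind, lapply(names(report$roc), function(nm) {
    r <- report$roc[[nm]]
    data.frame(variable = nm, auc = r$auc, auc_ci_low = r$auc_ci_low,
               auc_ci_high = r$auc_ci_high, cutoff = r$cutoff,
               orientation = r$orientation, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  utils::write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)
  if (!is.null(report$reader_comparison))
    utils::write.csv(report$reader_comparison$metrics,
                     file.path(out_dir, "reader_comparison.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
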