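# Group-comparison and diagnostic statistics: risk labeling, rank tests
# with FDR families, agreement analyses, ROC/Youden with DeLong intervals,
# McNemar comparisons against radiologist reads, and two-reader ICC.

#' Classify a patient as low- or high-risk disease
#'
#' Low risk requires grade 1-2 endometrioid histology with none of deep
#' myometrial invasion (DMI), cervical stroma invasion (CSI),
#' lymphovascular space invasion (LVSI) or lymph-node metastasis (LNM)
#' (FIGO 2018 based rule); everything else — grade-3 endometrioid,
#' nonendometrioid, or any positive flag — is high risk.
#'
#' @param subtype `"endometrioid"` or `"nonendometrioid"`
#' @param grade 1, 2 or 3; required for endometrioid tumors
#' @param dmi,csi,lvsi,lnm pathology flags (logical)
#' @return `"low"` or `"high"`
#' @export
classify_risk <- function(subtype, grade = NA, dmi = FALSE, csi = FALSE,
                          lvsi = FALSE, lnm = FALSE) {
  if (!subtype %in% .subtype_tokens)
    stop("unknown subtype: ", subtype)
  if (subtype == "endometrioid") {
    if (is.na(grade)) stop("endometrioid tumors require a grade")
    if (!grade %in% 1:3) stop("grade must be 1, 2 or 3")
  }
  low <- subtype == "endometrioid" && grade %in% c(1, 2) &&
    !isTRUE(dmi) && !isTRUE(csi) && !isTRUE(lvsi) && !isTRUE(lnm)
  if (low) "low" else "high"
}

.test_result <- function(statistic, p, family = NA_character_,
                         degenerate = FALSE) {
  structure(list(statistic = unname(statistic), p_raw = unname(p),
                 p_adjusted = NA_real_, family = family,
                 degenerate = degenerate),
            class = "test_result")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when the pooled sample has at most 12 observations
#' and no ties; otherwise the normal approximation with tie and continuity
#' corrections. The reported statistic is the U of the first sample.
#'
#' @param x,y numeric samples (non-empty)
#' @param family optional family label for later FDR adjustment
#' @return `test_result` with `statistic` (U) and `p_raw`
#' @export
mann_whitney_u <- function(x, y, family = NA_character_) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  if (stats::sd(c(x, y)) == 0)   # all observations identical
    return(.test_result(c(U = length(x) * length(y) / 2), 1, family,
                        degenerate = TRUE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .test_result(ht$statistic, ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up adjustment `p_(i) m / i` with cumulative-minimum monotone
#' enforcement, capped at 1, applied independently within each family
#' label. Missing labels collapse to one global family (logged).
#'
#' @param p_values raw p-values in [0, 1]
#' @param family_labels family label per p-value (e.g. the model name)
#' @return adjusted p-values in the input order
#' @export
fdr_adjust <- function(p_values, family_labels = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (is.null(family_labels) || all(is.na(family_labels))) {
    message("fdr_adjust: no family labels supplied; using one global family")
    family_labels <- rep("all", length(p_values))
  }
  stopifnot(length(family_labels) == length(p_values))
  adj <- p_values
  for (fam in unique(family_labels)) {
    i <- which(family_labels == fam)
    adj[i] <- stats::p.adjust(p_values[i], method = "BH")
  }
  adj
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zeros are dropped (Wilcoxon convention); exact null distribution when
#' at most 25 non-zero differences with untied magnitudes, otherwise the
#' normal approximation with tie and continuity corrections. All-zero
#' input is degenerate with p = 1.
#'
#' @param differences numeric vector of paired differences
#' @param family optional family label
#' @return `test_result` with `statistic` (V) and `p_raw`
#' @export
wilcoxon_signed_rank <- function(differences, family = NA_character_) {
  d <- differences[differences != 0]
  if (!length(d))
    return(.test_result(c(V = 0), 1, family, degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && length(d) <= 25
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  .test_result(ht$statistic, ht$p.value, family)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y` against means `(x + y)/2`: bias = mean(d),
#' limits of agreement = bias +/- 1.96 sd(d) (sample sd), a Wilcoxon
#' signed-rank p for systematic difference, and a Spearman trend
#' correlation of difference versus mean (a negative trend flags
#' proportional disagreement). Constant differences make the trend
#' undefined (NA, flagged).
#'
#' @param x,y paired measurements, length >= 3
#' @return object of class `bland_altman_result`
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("Bland-Altman needs at least 3 pairs")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  trend <- if (s == 0 || stats::sd(m) == 0)
    list(rho = NA_real_, p = NA_real_, flagged = TRUE)
  else c(spearman_cor(d, m), flagged = FALSE)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 wilcoxon_p = wilcoxon_signed_rank(d)$p_raw,
                 trend_rho = trend$rho, trend_p = trend$p,
                 trend_flagged = isTRUE(trend$flagged)),
            class = "bland_altman_result")
}

#' Spearman rank correlation
#'
#' Mid-rank rho; exact permutation p-value for n <= 8 without ties,
#' otherwise the t approximation. Constant input yields NA with a flag.
#'
#' @param x,y numeric vectors, n >= 3
#' @return list with `rho`, `p`, `flagged`
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("Spearman needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flagged = TRUE))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- !ties && length(x) <= 8
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ht$estimate), p = ht$p.value, flagged = FALSE)
}

# DeLong variance of the empirical AUC via placement values.
.delong_ci <- function(s_pos, s_neg, auc, conf = 0.95) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(s_pos, function(a) mean(psi(a, s_neg)), numeric(1))
  V01 <- vapply(s_neg, function(b) mean(psi(s_pos, b)), numeric(1))
  v <- stats::var(V10) / length(s_pos) + stats::var(V01) / length(s_neg)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
}

#' ROC analysis with Youden-index cutoff
#'
#' Empirical ROC over all observed thresholds. The orientation is chosen
#' so that AUC >= 0.5: if the positive-class values are lower, a patient
#' is called positive when `value <= cutoff` (orientation `"<="`),
#' otherwise `">="`. The AUC is the tie-corrected pairwise concordance
#' (equivalently the trapezoidal area; equal to U/(n1 n2) for tie-free
#' data), with a DeLong confidence interval. The cutoff maximizes the
#' Youden index J = sensitivity + specificity - 1; ties are broken toward
#' higher specificity. Sensitivity, specificity and accuracy are reported
#' in percent at the chosen cutoff and recompute exactly from the
#' confusion table.
#'
#' @param values biomarker value per patient
#' @param labels class label per patient
#' @param positive_class label treated as positive (default `"high"`)
#' @return object of class `roc_result`
#' @export
roc_analysis <- function(values, labels, positive_class = "high") {
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  stopifnot(all(is.finite(values)))
  # concordance AUC with orientation ">=" (higher value -> positive)
  psi <- outer(values[pos], values[!pos],
               function(a, b) (a > b) + 0.5 * (a == b))
  auc_ge <- mean(psi)
  orientation <- if (auc_ge >= 0.5) ">=" else "<="
  auc <- max(auc_ge, 1 - auc_ge)
  s_pos <- if (orientation == ">=") values[pos] else -values[pos]
  s_neg <- if (orientation == ">=") values[!pos] else -values[!pos]
  ci <- .delong_ci(s_pos, s_neg, auc)
  # candidate cutoffs: every observed value
  cand <- sort(unique(values))
  stats_at <- function(cut) {
    pred <- if (orientation == ">=") values >= cut else values <= cut
    sens <- mean(pred[pos]); spec <- mean(!pred[!pos])
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }
  tab <- vapply(cand, stats_at, numeric(3))
  best_j <- max(tab["j", ])
  at_best <- which(abs(tab["j", ] - best_j) < 1e-12)
  pick <- at_best[which.max(tab["spec", at_best])]
  cutoff <- cand[pick]
  sens <- unname(tab["sens", pick]); spec <- unname(tab["spec", pick])
  pred <- if (orientation == ">=") values >= cutoff else values <= cutoff
  acc <- mean(pred == pos)
  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
                 cutoff = cutoff, orientation = orientation,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 accuracy = 100 * acc, youden = best_j,
                 predicted_positive = pred),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%.3f-%.3f), cutoff %s %.4g, sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$orientation, x$cutoff,
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' McNemar test on paired classifier correctness
#'
#' Takes per-patient correctness indicators of two classifiers; with
#' discordant counts `b` (A correct, B wrong) and `c` (converse), the
#' exact two-sided binomial p-value `min(1, 2 P(X <= min(b,c)))` is used
#' when `b + c <= 25`, otherwise the chi-squared approximation with
#' continuity correction. `b + c = 0` is degenerate with p = 1.
#'
#' Stratified performance comparisons restrict the pairs before calling:
#' sensitivity to truly positive (high-risk) patients, specificity to
#' truly negative ones, accuracy to all.
#'
#' @param correct_a,correct_b logical vectors of equal length
#' @return `test_result` with discordant counts attached
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- b + cc
  if (n == 0) {
    res <- .test_result(c(b = 0), 1, degenerate = TRUE)
  } else if (n <= 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    res <- .test_result(c(b = b), p)
  } else {
    chi <- (abs(b - cc) - 1)^2 / n
    res <- .test_result(c(chi2 = chi), stats::pchisq(chi, 1, lower.tail = FALSE))
  }
  res$b <- b; res$c <- cc
  res
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measurement ICC from the two-way ANOVA mean
#' squares, with the conventional agreement categories: < 0.40 poor,
#' 0.40-0.75 good, > 0.75 excellent.
#'
#' @param reader1,reader2 paired measurements, n >= 3
#' @return object of class `icc_result` with `icc` and `category`
#' @export
icc_two_reader <- function(reader1, reader2) {
  stopifnot(length(reader1) == length(reader2))
  n <- length(reader1)
  if (n < 3) stop("ICC needs at least 3 subjects")
  X <- cbind(reader1, reader2)
  k <- 2
  if (stats::sd(as.vector(X)) == 0)
    return(structure(list(icc = NA_real_, category = NA_character_,
                          flagged = TRUE), class = "icc_result"))
  row_m <- rowMeans(X); col_m <- colMeans(X); g <- mean(X)
  MSR <- k * sum((row_m - g)^2) / (n - 1)
  MSC <- n * sum((col_m - g)^2) / (k - 1)
  MSE <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2) / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  category <- if (icc < 0.40) "poor" else if (icc <= 0.75) "good" else "excellent"
  structure(list(icc = icc, category = category, flagged = FALSE),
            class = "icc_result")
}

#' Confidence interval of the median by binomial order statistics
#'
#' Distribution-free interval from the order statistics `x_(l)`, `x_(n+1-l)`
#' with `l` the largest rank keeping each tail at or below
#' `(1 - conf)/2` under Binomial(n, 1/2); actual coverage is at least
#' `conf`.
#'
#' @param x numeric sample
#' @param conf nominal coverage (default 0.95)
#' @return list with `median`, `ci_low`, `ci_high`, `coverage`
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) return(list(median = stats::median(x), ci_low = NA_real_,
                         ci_high = NA_real_, coverage = NA_real_))
  alpha <- (1 - conf) / 2
  l <- 0
  while (stats::pbinom(l, n, 0.5) <= alpha) l <- l + 1
  # l is now the smallest rank with P(X < l) > alpha; use order stat x_(l)
  if (l < 1) l <- 1
  list(median = stats::median(x), ci_low = x[l], ci_high = x[n + 1 - l],
       coverage = 1 - 2 * stats::pbinom(l - 1, n, 0.5))
}

#' Apply the study's exclusion flow to a recruitment roster
#'
#' Exclusion categories, applied in order so each patient is excluded at
#' most once: lesion not evaluable on MRI, consent refused, change of
#' therapy, final pathology not the target diagnosis, noisy images /
#' arterial input not sampleable. Expects logical columns `lesion_ok`,
#' `consented`, `therapy_unchanged`, `diagnosis_confirmed`, `aif_ok`.
#'
#' @param roster data.frame with `id` and the five eligibility columns
#' @return list with `kept` (data.frame), `excluded` (id + reason),
#'   `counts` (named vector per reason), `n_kept`
#' @export
apply_exclusions <- function(roster) {
  need <- c("id", "lesion_ok", "consented", "therapy_unchanged",
            "diagnosis_confirmed", "aif_ok")
  missing <- setdiff(need, names(roster))
  if (length(missing))
    stop("roster lacks column(s): ", paste(missing, collapse = ", "))
  reasons <- c("lesion_not_evaluable", "consent_refused", "therapy_changed",
               "diagnosis_not_confirmed", "aif_failure")
  checks <- cbind(!roster$lesion_ok, !roster$consented,
                  !roster$therapy_unchanged, !roster$diagnosis_confirmed,
                  !roster$aif_ok)
  first_fail <- apply(checks, 1, function(r) if (any(r)) which(r)[1] else 0L)
  excluded <- data.frame(id = roster$id[first_fail > 0],
                         reason = reasons[first_fail[first_fail > 0]],
                         stringsAsFactors = FALSE)
  counts <- stats::setNames(
    vapply(seq_along(reasons), function(i) sum(first_fail == i), integer(1)),
    reasons)
  list(kept = roster[first_fail == 0, , drop = FALSE],
       excluded = excluded, counts = counts,
       n_kept = sum(first_fail == 0))
}
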