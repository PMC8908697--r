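#' Steady-state spoiled gradient-echo signal
#'
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Vectorised over `M0` and `T1_ms`.
#'
#' @param M0 equilibrium signal (a.u.)
#' @param T1_ms longitudinal relaxation time (ms), > 0
#' @param flip_deg flip angle (degrees), in (0, 90] (0 allowed, giving S = 0)
#' @param TR_ms repetition time (ms)
#' @return signal (a.u.)
#' @export
spgr_signal <- function(M0, T1_ms, flip_deg, TR_ms) {
  if (any(T1_ms <= 0)) stop("T1 must be positive")
  a <- flip_deg * pi / 180
  E1 <- exp(-TR_ms / T1_ms)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Variable-flip-angle T1/M0 estimation
#'
#' Linearises the SPGR equation as `y = E1 x + M0 (1 - E1)` with
#' `y = S/sin(a)`, `x = S/tan(a)` and fits by least squares across flip
#' angles; `T1 = -TR / log(slope)`. Voxels with a nonphysical slope outside
#' (0, 1), non-positive signals, or degenerate regressors are marked
#' invalid (T1 and M0 set to NaN) rather than raising an error.
#'
#' `mean_signals` may be a vector (one voxel) or a matrix with one row per
#' voxel and one column per flip angle.
#'
#' @param mean_signals per-flip mean signal; vector or (voxel x flip) matrix
#' @param flips_deg flip angles (degrees), length >= 2, distinct
#' @param TR_ms repetition time (ms)
#' @return list with `T1_ms`, `M0`, `valid` (per voxel)
#' @export
fit_vfa_t1 <- function(mean_signals, flips_deg, TR_ms) {
  if (length(unique(flips_deg)) < 2)
    stop("need at least 2 distinct flip angles")
  S <- if (is.matrix(mean_signals)) mean_signals else matrix(mean_signals, nrow = 1)
  if (ncol(S) != length(flips_deg))
    stop("one signal column per flip angle required")
  a <- flips_deg * pi / 180
  y <- sweep(S, 2, sin(a), "/")
  x <- sweep(S, 2, tan(a), "/")
  n <- length(a)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n
  valid <- is.finite(slope) & slope > 0 & slope < 1 &
    apply(S, 1, function(r) all(is.finite(r)) && all(r > 0)) &
    abs(denom) > .Machine$double.eps * pmax(1, n * sxx)
  T1 <- rep(NaN, nrow(S)); M0 <- rep(NaN, nrow(S))
  T1[valid] <- -TR_ms / log(slope[valid])
  M0[valid] <- intercept[valid] / (1 - slope[valid])
  bad <- valid & (T1 <= 0 | M0 <= 0)
  T1[bad] <- NaN; M0[bad] <- NaN; valid[bad] <- FALSE
  if (is.matrix(mean_signals)) list(T1_ms = T1, M0 = M0, valid = valid)
  else list(T1_ms = T1[1], M0 = M0[1], valid = valid[1])
}

#' VFA T1 map from precontrast flip-angle stacks
#'
#' Averages the repeats of each flip-angle stack, then runs [fit_vfa_t1()]
#' voxelwise.
#'
#' @param vfa_stacks list of 4D arrays (x, y, z, repeats), one per flip angle
#' @param flips_deg flip angles matching `vfa_stacks`
#' @param TR_ms repetition time (ms)
#' @return object of class `t1m0_map`: list with 3D `T1_ms`, `M0`, `valid`
#' @export
fit_vfa_t1_map <- function(vfa_stacks, flips_deg, TR_ms) {
  stopifnot(length(vfa_stacks) == length(flips_deg))
  means <- lapply(vfa_stacks, function(a) {
    stopifnot(length(dim(a)) == 4L)
    apply(a, 1:3, mean)
  })
  shape <- dim(means[[1]])
  S <- do.call(cbind, lapply(means, as.vector))
  fit <- fit_vfa_t1(S, flips_deg, TR_ms)
  structure(list(T1_ms = array(fit$T1_ms, shape),
                 M0 = array(fit$M0, shape),
                 valid = array(fit$valid, shape)),
            class = "t1m0_map")
}

# Invert the SPGR equation for E1 given the normalised signal s = S/M0.
# Returns NaN outside the invertible domain E1 in (0, 1).
.spgr_invert_e1 <- function(s, flip_deg) {
  a <- flip_deg * pi / 180
  E1 <- (sin(a) - s) / (sin(a) - s * cos(a))
  E1[!(is.finite(E1) & E1 > 0 & E1 < 1)] <- NaN
  E1
}

#' Convert dynamic SPGR signal to contrast-agent concentration
#'
#' Per voxel: M0 is rescaled so the modeled baseline signal matches the
#' mean of the first `baseline_frames` dynamic frames (this absorbs
#' receive-gain differences between the VFA and dynamic scans); each frame
#' is then inverted for `T1(t)`, and `C(t) = (R1(t) - R1(0)) / r1` with
#' `R1` in s^-1 and the relaxivity `r1` in s^-1 mM^-1 (linear-relaxivity,
#' fast-water-exchange assumption). Frames whose signal falls outside the
#' invertible SPGR range are set to NaN and counted. Concentration is
#' clipped at zero only on the baseline frames (where it is zero by
#' construction); post-baseline noise excursions below zero are kept so
#' fitting residuals stay unbiased.
#'
#' @param series `dynamic_series`
#' @param t1m0 `t1m0_map` from [fit_vfa_t1_map()]
#' @param protocol `acquisition_protocol` (dynamic flip, TR, r1)
#' @param baseline_frames number of precontrast dynamic frames (>= 1)
#' @return object of class `concentration_series`: list with 4D `data`
#'   (mM), `frame_times_s`, `n_invalid_frames`
#' @export
signal_to_concentration <- function(series, t1m0, protocol,
                                    baseline_frames = 10) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(t1m0, "t1m0_map"),
            baseline_frames >= 1)
  arr <- series$data
  shape <- dim(arr)[1:3]
  nt <- dim(arr)[4]
  nv <- prod(shape)
  S <- matrix(arr, nrow = nv, ncol = nt)
  T10 <- as.vector(t1m0$T1_ms)
  ok <- as.vector(t1m0$valid) & is.finite(T10) & T10 > 0
  S0 <- rowMeans(S[, seq_len(baseline_frames), drop = FALSE])
  # rescale M0 so modeled baseline matches observed baseline
  a <- protocol$dyn_flip_deg
  Smodel0 <- spgr_signal(1, pmax(T10, .Machine$double.eps), a, protocol$TR_ms)
  M0r <- S0 / Smodel0
  ok <- ok & is.finite(M0r) & M0r > 0
  C <- matrix(NaN, nv, nt)
  if (any(ok)) {
    s <- S[ok, , drop = FALSE] / M0r[ok]
    E1 <- .spgr_invert_e1(s, a)
    T1t <- -protocol$TR_ms / log(E1)          # ms
    R1t <- 1000 / T1t                         # s^-1
    R10 <- 1000 / T10[ok]
    C[ok, ] <- (R1t - R10) / protocol$r1_relaxivity
  }
  n_invalid <- sum(ok) * nt - sum(is.finite(C[ok, , drop = FALSE]))
  if (n_invalid > 0)
    message(sprintf("signal_to_concentration: %d frame value(s) outside the invertible SPGR range set to NaN",
                    n_invalid))
  bl <- seq_len(baseline_frames)
  C[, bl] <- pmax(C[, bl, drop = FALSE], 0)
  structure(list(data = array(C, c(shape, nt)),
                 frame_times_s = series$frame_times_s,
                 n_invalid_frames = n_invalid),
            class = "concentration_series")
}

#' Extract an arterial input function from an artery ROI
#'
#' The blood concentration curve is the voxelwise median over the artery
#' ROI; the plasma curve is `Cp(t) = C_blood(t) / (1 - Hct)`. Baseline
#' frames are anchored at zero. A peak plasma concentration below
#' `min_peak_mM` raises a low-quality-AIF warning (mirroring exclusion of
#' cases whose AIF could not be sampled).
#'
#' @param conc `concentration_series`
#' @param artery_mask `voxel_mask` over the same grid
#' @param hematocrit fraction in [0, 1)
#' @param baseline_frames frames forced to zero at the start
#' @param min_peak_mM quality floor for the plasma peak (default 1 mM)
#' @return object of class `aif`: list with `times_s`, `Cp` (mM)
#' @export
extract_aif <- function(conc, artery_mask, hematocrit = 0.42,
                        baseline_frames = 10, min_peak_mM = 1) {
  stopifnot(inherits(conc, "concentration_series"),
            inherits(artery_mask, "voxel_mask"))
  idx <- which(artery_mask$data)
  nt <- dim(conc$data)[4]
  nv <- prod(dim(conc$data)[1:3])
  Cm <- matrix(conc$data, nv, nt)[idx, , drop = FALSE]
  Cb <- apply(Cm, 2, stats::median, na.rm = TRUE)
  Cb[!is.finite(Cb)] <- 0
  # negative noise excursions carry no kinetic meaning in an input function
  Cp <- pmax(Cb, 0) / (1 - hematocrit)
  Cp[seq_len(min(baseline_frames, nt))] <- 0
  if (max(Cp) < min_peak_mM)
    warning(sprintf("low-quality AIF: plasma peak %.3f mM below floor %.3f mM",
                    max(Cp), min_peak_mM))
  aif(conc$frame_times_s, Cp)
}

#' Construct an arterial input function object
#'
#' @param times_s time grid (s), strictly increasing
#' @param Cp plasma concentration (mM), non-negative
#' @return `aif`
#' @export
aif <- function(times_s, Cp) {
  stopifnot(length(times_s) == length(Cp))
  if (any(diff(times_s) <= 0)) stop("AIF times must be strictly increasing")
  if (any(Cp < -1e-9)) stop("AIF concentration must be non-negative")
  structure(list(times_s = as.numeric(times_s), Cp = pmax(as.numeric(Cp), 0)),
            class = "aif")
}
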