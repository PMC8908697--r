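# Voxelwise bounded nonlinear least-squares fitting of the ET and DP
# models, with seeded Latin-hypercube multi-start and ROI aggregation.

#' Default fitting bounds
#'
#' Generous supersets of values reported for pelvic tumors: Ktrans in
#' [0, 3] min^-1, Ve in [0, 60] and Vp in [0, 20] mL/100 mL, F in
#' (0, 200] mL/min/100 mL, Tc in [0.5, 60] s, PS in [0, 100] mL/min/100 mL.
#'
#' @param model `"et"` or `"dp"`
#' @return list with named `lower` and `upper` vectors
#' @export
default_bounds <- function(model = c("et", "dp")) {
  model <- match.arg(model)
  if (model == "et")
    list(lower = c(ktrans = 0, ve = 1e-3, vp = 0),
         upper = c(ktrans = 3, ve = 60, vp = 20))
  else
    list(lower = c(f = 0.1, tc_s = 0.5, ve = 1e-3, ps = 0),
         upper = c(f = 200, tc_s = 60, ve = 60, ps = 100))
}

.model_curve <- function(model, par, aif, times_s, oversample = 5) {
  if (model == "et")
    et_forward(list(ktrans = par[["ktrans"]], ve = par[["ve"]],
                    vp = par[["vp"]]), aif, times_s)
  else
    dp_forward(list(f = par[["f"]], tc_s = par[["tc_s"]], ve = par[["ve"]],
                    ps = par[["ps"]]), aif, times_s, oversample = oversample)
}

#' Fit one tissue concentration curve
#'
#' Bounded Levenberg-Marquardt least squares (SSR objective) from
#' `n_starts` Latin-hypercube start points drawn over the bounds with the
#' given seed; the start with the smallest SSR wins, ties broken by the
#' smaller parameter-vector norm so refits are deterministic. Derived
#' parameters (Kep for ET; Vp, MTT, E, Te for DP) are computed from the
#' fitted primitives, never fitted independently. An all-zero curve
#' returns the all-zero boundary solution directly.
#'
#' @param curve tissue concentration (mM), finite
#' @param aif `aif` with positive peak
#' @param times_s frame times (s)
#' @param model `"et"` or `"dp"`
#' @param bounds list with `lower`/`upper` (see [default_bounds()])
#' @param n_starts Latin-hypercube multi-start count
#' @param seed RNG seed for the start design
#' @param oversample convolution refinement for the DP model
#' @return object of class `voxel_fit`: list with `model`, `params`
#'   (primitives + derived), `SSR`, `converged`, `n_starts_used`,
#'   `boundary` flag
#' @export
fit_voxel <- function(curve, aif, times_s, model = c("et", "dp"),
                      bounds = default_bounds(model), n_starts = 8,
                      seed = 1, oversample = 5) {
  model <- match.arg(model)
  stopifnot(all(is.finite(curve)), length(curve) == length(times_s))
  if (max(aif$Cp) <= 0) stop("AIF peak must be positive")
  lower <- bounds$lower; upper <- bounds$upper
  pnames <- names(lower)

  if (max(abs(curve)) < 1e-12) {
    par <- lower * 0
    names(par) <- pnames
    fit <- structure(list(model = model, params = derived_params_vec(model, par),
                          SSR = 0, converged = TRUE, n_starts_used = 0L,
                          boundary = TRUE), class = "voxel_fit")
    return(fit)
  }

  resid_fn <- function(par) {
    names(par) <- pnames
    .model_curve(model, par, aif, times_s, oversample) - curve
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(pnames))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  starts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  colnames(starts) <- pnames

  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (!is.finite(ssr)) next
    cand <- list(par = res$par, ssr = ssr, info = res$info)
    if (is.null(best) || cand$ssr < best$ssr - 1e-15 ||
        (abs(cand$ssr - best$ssr) <= 1e-15 &&
         sum(cand$par^2) < sum(best$par^2)))
      best <- cand
  }
  if (is.null(best)) {
    par <- stats::setNames(rep(NaN, length(pnames)), pnames)
    return(structure(list(model = model,
                          params = derived_params_vec(model, par),
                          SSR = NaN, converged = FALSE,
                          n_starts_used = n_starts, boundary = FALSE),
                     class = "voxel_fit"))
  }
  par <- stats::setNames(as.numeric(best$par), pnames)
  structure(list(model = model, params = derived_params_vec(model, par),
                 SSR = best$ssr,
                 converged = best$info %in% 1:4,
                 n_starts_used = n_starts,
                 boundary = any(abs(par - lower) < 1e-10) ||
                            any(abs(par - upper) < 1e-10)),
            class = "voxel_fit")
}

# Primitives + derived quantities as a flat named vector.
derived_params_vec <- function(model, par) {
  if (model == "et") {
    kep <- if (is.finite(par[["ve"]]) && par[["ve"]] > 0)
      100 * par[["ktrans"]] / par[["ve"]] else NaN
    c(par, kep = unname(kep))
  } else {
    f <- par[["f"]]; tc <- par[["tc_s"]]; ve <- par[["ve"]]; ps <- par[["ps"]]
    vp <- f * tc / 60
    e <- if (is.finite(f) && f > 0) 100 * (1 - exp(-ps / f)) else NaN
    te <- if (is.finite(ps) && ps > 0) ve / ps else NaN
    c(par, vp = unname(vp), mtt_s = unname(tc), e_pct = unname(e),
      te_min = unname(te))
  }
}

#' Derived kinetic parameters of a fitted voxel
#'
#' ET: `Kep = 100 Ktrans / Ve` (min^-1). DP: `Vp = F Tc / 60` (mL/100 mL),
#' `MTT = Tc` (s), `E = 100 (1 - exp(-PS/F))` (%), `Te = Ve / PS` (min).
#' Divisions by zero yield NaN.
#'
#' @param fit `voxel_fit`
#' @return named numeric vector of primitive and derived parameters
#' @export
derived_params <- function(fit) {
  stopifnot(inherits(fit, "voxel_fit"))
  fit$params
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("voxel_fit [%s] %s  SSR=%.3g\n", toupper(x$model),
              if (x$converged) "converged" else "FAILED", x$SSR))
  print(round(x$params, 4))
  invisible(x)
}

#' Fit every voxel in an ROI and aggregate medians
#'
#' Runs [fit_voxel()] for each masked voxel; parameter maps carry NaN at
#' failed voxels, and the per-parameter ROI median is computed over
#' converged voxels only (failed fits are excluded, not zeroed). More than
#' 50% voxel failures raises a quality warning.
#'
#' @param conc `concentration_series`
#' @param mask `voxel_mask` on the same grid
#' @param aif `aif`
#' @param model `"et"` or `"dp"`
#' @param bounds,n_starts,seed,oversample passed to [fit_voxel()]
#' @return object of class `roi_fit_result`: list with `maps` (named list
#'   of 3D arrays), `medians` (named vector), `n_fitted`, `n_failed`
#' @export
fit_roi <- function(conc, mask, aif, model = c("et", "dp"),
                    bounds = default_bounds(model), n_starts = 8, seed = 1,
                    oversample = 5) {
  model <- match.arg(model)
  stopifnot(inherits(conc, "concentration_series"),
            inherits(mask, "voxel_mask"))
  shape <- dim(conc$data)[1:3]
  stopifnot(identical(as.integer(dim(mask$data)), as.integer(shape)))
  idx <- which(mask$data)
  nt <- dim(conc$data)[4]
  Cmat <- matrix(conc$data, prod(shape), nt)
  pnames <- names(derived_params_vec(model, default_bounds(model)$lower * 0))
  maps <- stats::setNames(
    lapply(pnames, function(p) array(NaN, shape)), pnames)
  vals <- matrix(NaN, length(idx), length(pnames),
                 dimnames = list(NULL, pnames))
  ok <- logical(length(idx))
  for (i in seq_along(idx)) {
    curve <- Cmat[idx[i], ]
    if (any(!is.finite(curve))) next
    fit <- fit_voxel(curve, aif, conc$frame_times_s, model,
                     bounds = bounds, n_starts = n_starts,
                     seed = seed + i - 1, oversample = oversample)
    if (fit$converged) {
      ok[i] <- TRUE
      vals[i, ] <- fit$params
    }
  }
  for (p in pnames) {
    m <- maps[[p]]
    m[idx[ok]] <- vals[ok, p]
    maps[[p]] <- m
  }
  n_failed <- sum(!ok)
  if (n_failed > length(idx) / 2)
    warning(sprintf("quality: %d of %d ROI voxels failed to fit",
                    n_failed, length(idx)))
  medians <- apply(vals[ok, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  structure(list(model = model, maps = maps, medians = medians,
                 n_fitted = sum(ok), n_failed = n_failed),
            class = "roi_fit_result")
}

#' @export
print.roi_fit_result <- function(x, ...) {
  cat(sprintf("roi_fit_result [%s]: %d fitted, %d failed\n",
              toupper(x$model), x$n_fitted, x$n_failed))
  print(round(x$medians, 4))
  invisible(x)
}
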