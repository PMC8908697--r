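# Tracer-kinetic forward models: extended Tofts and the
# distributed-parameter (Sangren-Sheppard) capillary-tissue model.
#
# Unit conventions (the conventional DCE-MRI reporting units):
#   Ktrans, Kep        min^-1
#   Ve, Vp             mL/100 mL  (percent-style fractional volumes)
#   F, PS              mL/min/100 mL
#   Tc (= MTT)         s
#   concentrations     mmol/L (mM); time integrals carried out in minutes.

# Cumulative trapezoidal integral of y over x (same length), from x[1].
.cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0 * y)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Convolution of a piecewise-linear input c(t) with exp(-k t), exact for
# the linear interpolant: y(t_i) = int_0^{t_i} c(u) exp(-k (t_i - u)) du.
# Uniform grids use a recursive filter; k == 0 reduces to cumtrapz.
.expconv <- function(t, c, k) {
  n <- length(t)
  if (n < 2) return(0 * c)
  if (k <= 1e-12) return(.cumtrapz(t, c))
  h <- diff(t)
  E <- exp(-k * h)
  c0 <- c[-n]; c1 <- c[-1]
  # segment integral for linear c from c0 to c1 over step h
  b <- c0 * (1 - E) / k + (c1 - c0) * (h - (1 - E) / k) / (k * h)
  if (max(h) - min(h) < 1e-9 * max(h)) {
    y <- stats::filter(b, E[1], method = "recursive")
    return(c(0, as.numeric(y)))
  }
  y <- numeric(n)
  for (i in 2:n) y[i] <- y[i - 1] * E[i - 1] + b[i - 1]
  y
}

# Interpolate an AIF onto an arbitrary time grid (s); zero before support.
.aif_on <- function(aif, times_s) {
  stats::approx(aif$times_s, aif$Cp, xout = times_s,
                yleft = 0, rule = 2)$y
}

#' Extended Tofts forward model
#'
#' Tissue concentration
#' `Ctiss(t) = (Vp/100) Cp(t) + Ktrans int_0^t Cp(u) exp(-Kep (t-u)) du`
#' with `Kep = 100 Ktrans / Ve` (min^-1) and the integral in minutes. The
#' vascular term uses the plasma AIF directly; the interstitial term is an
#' exponential convolution evaluated exactly for a piecewise-linear AIF.
#'
#' @param params named vector/list with `ktrans` (min^-1), `ve`, `vp`
#'   (mL/100 mL)
#' @param aif `aif` object (plasma concentration, mM)
#' @param times_s output time grid (s)
#' @return tissue concentration (mM) on `times_s`
#' @export
et_forward <- function(params, aif, times_s) {
  p <- as.list(params)
  ktrans <- p$ktrans; ve <- p$ve; vp <- p$vp
  if (any(c(ktrans, ve, vp) < 0)) stop("ET parameters must be non-negative")
  if (ktrans > 0 && ve <= 0)
    stop("Ve must be positive when Ktrans > 0")
  Cp <- .aif_on(aif, times_s)
  t_min <- times_s / 60
  ct <- (vp / 100) * Cp
  if (ktrans > 0) {
    kep <- 100 * ktrans / ve
    ct <- ct + ktrans * .expconv(t_min, Cp, kep)
  }
  ct
}

# Diffuse (interstitial-return) component of the Sangren-Sheppard outflow
# density h(tau), tau = t - Tc > 0, all rates per minute:
#   g(tau) = exp(-kp Tc - ke tau) sqrt(kp ke Tc / tau) I1(2 sqrt(kp ke Tc tau))
# Evaluated with the exponentially scaled Bessel I1; the tau -> 0 limit is
# kp ke Tc exp(-kp Tc).
.dp_diffuse <- function(tau_min, kp, ke, Tc_min) {
  a <- kp * ke * Tc_min
  if (a <= 0) return(0 * tau_min)
  g <- numeric(length(tau_min))
  z <- tau_min > 1e-14
  x <- 2 * sqrt(a * tau_min[z])
  g[z] <- sqrt(a / tau_min[z]) *
    exp(-kp * Tc_min - ke * tau_min[z] + x) *
    besselI(x, 1, expon.scaled = TRUE)
  g[!z] <- a * exp(-kp * Tc_min)
  g
}

#' Distributed-parameter residue function
#'
#' Sangren-Sheppard impulse residue of the two-region capillary-tissue
#' system: `R(t) = 1` during the vascular phase `t < Tc`; thereafter the
#' unextracted bolus fraction `exp(-PS/F)` leaves at `t = Tc` and the
#' extracted fraction returns from the interstitium with density
#' `exp(-kp Tc - ke tau) sqrt(kp ke Tc / tau) I1(2 sqrt(kp ke Tc tau))`,
#' `kp = PS/Vp`, `ke = PS/Ve`, `tau = t - Tc`. `Vp = F Tc / 60`. The area
#' under R equals `(Vp + Ve)/F` (minutes).
#'
#' @param params named vector/list with `f` (mL/min/100 mL), `tc_s` (s),
#'   `ve` (mL/100 mL), `ps` (mL/min/100 mL)
#' @param t_s times (s) at which to evaluate R
#' @return dimensionless residue values in [0, 1]
#' @export
dp_residue <- function(params, t_s) {
  p <- as.list(params)
  f <- p$f; tc_s <- p$tc_s; ve <- p$ve; ps <- p$ps
  if (f <= 0) stop("dp_residue requires F > 0")
  if (any(c(tc_s, ve, ps) < 0)) stop("DP parameters must be non-negative")
  Tc_min <- tc_s / 60
  vp <- f * Tc_min
  R <- numeric(length(t_s))
  t_min <- t_s / 60
  vasc <- t_min < Tc_min
  R[vasc] <- 1
  if (any(!vasc)) {
    tau <- t_min[!vasc] - Tc_min
    if (ps == 0 || ve == 0) {
      R[!vasc] <- if (ps == 0) 0 else 0  # no return path
    } else {
      kp <- ps / vp; ke <- ps / ve
      # integrate the diffuse density on the (sorted) tau grid
      o <- order(tau)
      ts <- tau[o]
      grid <- unique(c(0, ts))
      g <- .dp_diffuse(grid, kp, ke, Tc_min)
      G <- .cumtrapz(grid, g)
      Gi <- stats::approx(grid, G, xout = ts)$y
      Rv <- 1 - exp(-kp * Tc_min) - Gi
      R[!vasc][o] <- pmax(Rv, 0)
    }
  }
  R
}

#' Distributed-parameter forward model
#'
#' `Ctiss(t) = (F/100) int_0^t R(u) Cp(t-u) du` with time in minutes.
#' Evaluated on an oversampled uniform grid (default 5x the frame spacing)
#' to resolve the capillary transit: the residue is split into a continuous
#' part plus an exact rectangle of height `exp(-PS/F)` on `[0, Tc)`, so the
#' trapezoidal convolution never straddles the discontinuity at `Tc` — the
#' rectangle term reduces to a difference of cumulative AIF integrals.
#' The `Tc = 0` limit (vanishing vascular volume) falls back to the
#' one-compartment extraction model with `Ktrans = F E / 100`.
#'
#' @param params named vector/list with `f`, `tc_s`, `ve`, `ps`
#' @param aif `aif` object (plasma concentration, mM)
#' @param times_s output time grid (s)
#' @param oversample fine-grid refinement factor for the convolution
#' @return tissue concentration (mM) on `times_s`
#' @export
dp_forward <- function(params, aif, times_s, oversample = 5) {
  p <- as.list(params)
  f <- p$f; tc_s <- p$tc_s; ve <- p$ve; ps <- p$ps
  if (any(c(f, tc_s, ve, ps) < 0)) stop("DP parameters must be non-negative")
  if (f == 0) return(numeric(length(times_s)))
  if (tc_s <= 0) {
    E <- 1 - exp(-ps / f)
    return(et_forward(list(ktrans = f * E / 100, ve = max(ve, 1e-9), vp = 0),
                      aif, times_s))
  }
  dt_fine <- min(diff(times_s)) / oversample
  tmax <- max(times_s)
  tg <- seq(0, tmax + dt_fine, by = dt_fine)
  Cp <- .aif_on(aif, tg)
  t_min <- tg / 60
  Tc_min <- tc_s / 60
  J <- exp(-ps / f)               # rectangle height (= exp(-kp Tc))
  # continuous residue part: R_c = R - J * 1{t < Tc}
  Rc <- dp_residue(params, tg)
  Rc[tg < tc_s] <- Rc[tg < tc_s] - J
  # trapezoid-weight convolution of Rc with Cp on the uniform fine grid
  n <- length(tg)
  dt_min <- dt_fine / 60
  conv <- stats::convolve(Cp, rev(Rc), type = "open")[seq_len(n)] * dt_min
  conv <- conv - 0.5 * dt_min * (Rc[1] * Cp + Cp[1] * Rc)
  # rectangle term: J * (I(t) - I(t - Tc)), I = cumulative AIF integral
  I <- .cumtrapz(t_min, Cp)
  Ishift <- stats::approx(t_min, I, xout = t_min - Tc_min, yleft = 0,
                          rule = 2)$y
  ct_fine <- (f / 100) * (conv + J * (I - Ishift))
  stats::approx(tg, ct_fine, xout = times_s, rule = 2)$y
}

#' Finite-difference oracle for the distributed-parameter model
#'
#' Independently solves the two-region convection-exchange system
#' `dcp/dt = -(1/Tc) dcp/dx - (PS/Vp)(cp - ce)`,
#' `dce/dt = (PS/Ve)(cp - ce)` on `x` in [0, 1] by first-order upwind
#' finite differences with explicit Euler sub-stepping under the CFL
#' condition, and returns the space-averaged tissue concentration
#' `(Vp mean(cp) + Ve mean(ce)) / 100`. This routine shares no code with
#' [dp_forward()] and serves as its numerical ground truth.
#'
#' @param params named vector/list with `f`, `tc_s`, `ve`, `ps`
#' @param aif `aif` object
#' @param times_s output time grid (s)
#' @param n_segments spatial cells (>= 100)
#' @return tissue concentration (mM) on `times_s`
#' @export
dp_pde_oracle <- function(params, aif, times_s, n_segments = 200) {
  stopifnot(n_segments >= 100)
  p <- as.list(params)
  f <- p$f; tc_s <- p$tc_s; ve <- p$ve; ps <- p$ps
  if (f <= 0 || tc_s <= 0) stop("oracle requires F > 0 and Tc > 0")
  Tc_min <- tc_s / 60
  vp <- f * Tc_min
  kp <- if (vp > 0) ps / vp else 0
  ke <- if (ve > 0) ps / ve else 0
  dx <- 1 / n_segments
  v <- 1 / Tc_min                      # advection speed (x per min)
  # CFL plus exchange-rate stability, with margin
  dt <- 0.8 * min(dx / v,
                  if (kp > 0) 1 / kp else Inf,
                  if (ke > 0) 1 / ke else Inf)
  tmax_min <- max(times_s) / 60
  nstep <- ceiling(tmax_min / dt)
  dt <- tmax_min / nstep
  cp <- numeric(n_segments)
  ce <- numeric(n_segments)
  out_t <- numeric(nstep + 1)
  out_c <- numeric(nstep + 1)
  tnow <- 0
  for (k in seq_len(nstep)) {
    inlet <- .aif_on(aif, tnow * 60)
    upwind <- (cp - c(inlet, cp[-n_segments])) / dx
    exch <- cp - ce
    cp_new <- cp + dt * (-v * upwind - kp * exch)
    ce_new <- ce + dt * ke * exch
    cp <- cp_new; ce <- ce_new
    tnow <- tnow + dt
    out_t[k + 1] <- tnow
    out_c[k + 1] <- (vp * mean(cp) + ve * mean(ce)) / 100
  }
  stats::approx(out_t * 60, out_c, xout = times_s, rule = 2)$y
}
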