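---
title: "Tracer-kinetic modeling of DCE-MRI: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-kinetic modeling of DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekinetics)
```

This vignette is the package's account of its science: the signal and
kinetic models it implements, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, and the
numerical and design decisions taken where the problem left genuine
freedom.

## From signal to concentration

Dynamic contrast-enhanced MRI acquires a T1-weighted spoiled
gradient-echo (SPGR) series while a gadolinium bolus passes through the
tissue. The steady-state SPGR signal is

$$S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1},$$

and the contrast agent shortens $T_1$ in proportion to its concentration
(fast-water-exchange, linear-relaxivity assumption):
$R_1(t) = R_1(0) + r_1\,C(t)$ with $R_1 = 1/T_1$.

The precontrast $T_1$ is estimated per voxel from the variable-flip-angle
(VFA) series — here 6°, 12° and 18°, ten repeats each, averaged before
fitting — by the standard linearization $y = E_1 x + M_0(1-E_1)$ with
$y = S/\sin\alpha$, $x = S/\tan\alpha$. A regression slope outside
$(0, 1)$ is nonphysical; such voxels are marked invalid (NaN) rather
than raising an error, because isolated noise voxels must not abort a
whole-volume map. Before inverting the dynamic series, $M_0$ is rescaled
so the modeled baseline matches the mean of the first 10 dynamic frames;
this absorbs receive-gain differences between the VFA and dynamic scans
and anchors $C = 0$ at baseline by construction. Dynamic frames whose
signal leaves the invertible SPGR range become NaN with a logged count;
concentration is clipped at zero only on baseline frames, so
post-baseline noise stays zero-mean for the fit.

Two physics constants cannot be recovered from a study description and
are explicit configuration with prominent defaults: the relaxivity
$r_1 = 4.5$ L mmol⁻¹ s⁻¹ (a representative 1.5 T value for small
gadolinium chelates; source studies are often ambiguous about the exact
agent) and the large-vessel hematocrit 0.42 used to convert blood to
plasma concentration, $C_p = C_b/(1-\mathrm{Hct})$. The arterial input
function (AIF) is the voxel-median concentration curve over an iliac
artery ROI, using the same per-voxel VFA $T_1$; a plasma peak below
1 mM flags the AIF as unusable, mirroring the exclusion of cases whose
AIF could not be sampled.

## The two kinetic models

**Extended Tofts (ET).** Primitives Ktrans (min⁻¹), Ve, Vp (mL/100 mL):

$$C_{tiss}(t) = \frac{V_p}{100} C_p(t) +
K^{trans}\int_0^t C_p(u)\,e^{-k_{ep}(t-u)}\,du,
\qquad k_{ep} = \frac{100\,K^{trans}}{V_e}.$$

The exponential convolution is evaluated exactly for a piecewise-linear
AIF (recursive filter on uniform grids), so the forward model introduces
no quadrature error of its own.

**Distributed-parameter (DP).** The capillary is a plug-flow tube
exchanging with a well-mixed interstitium. Primitives are flow F
(mL/min/100 mL), capillary transit time Tc (s), Ve and PS; Vp = F·Tc/60
and MTT ≡ Tc are derived, never fitted — fitting (F, Tc, Ve, PS) makes
the reported MTT an estimated primitive and keeps the Vp identity exact
on every record. Reported group medians are consistent with this
convention (Vp/F ≈ 14 s against a printed MTT of about 15 s). The
impulse residue is the Sangren–Sheppard solution: $R(t) = 1$ for
$t < T_c$; at $t = T_c$ the unextracted fraction $e^{-PS/F}$ exits; the
extracted fraction returns with density
$e^{-k_pT_c - k_e\tau}\sqrt{k_pk_eT_c/\tau}\,I_1(2\sqrt{k_pk_eT_c\tau})$,
$\tau = t - T_c$, $k_p = PS/V_p$, $k_e = PS/V_e$. Useful identities used
as tests: $\int_0^\infty R = (V_p+V_e)/F$, extraction
$E = 1 - e^{-PS/F}$, and the compartmental limit
$V_p \to 0,\ PS/F \to 0$ in which DP collapses to Tofts with
$K^{trans} = PS/100$ (the factor 100 carries the per-100-mL volume
convention).

### Numerics

* The Bessel product $\sqrt{1/\tau}\,I_1(2\sqrt{a\tau})$ is evaluated
  with the exponentially scaled `besselI`; the combined exponent is
  provably ≤ 0, so no overflow occurs, and the $\tau \to 0$ limit
  $a\,e^{-k_pT_c}$ is substituted analytically.
* $R$ is discontinuous at $T_c$. The convolution splits $R$ into a
  continuous part plus an exact rectangle of height $e^{-PS/F}$ on
  $[0, T_c)$; the rectangle term reduces to a difference of cumulative
  AIF integrals, so the trapezoidal convolution never straddles the jump.
  The convolution runs on a 5× oversampled grid (0.5 s at the default
  2.5 s frame spacing).
* `dp_pde_oracle()` is a deliberately independent ground truth: upwind
  finite differences on the two-region convection–exchange PDE with CFL
  sub-stepping. Agreement (max deviation < 1% of the curve peak across
  the reported parameter range) is asserted in the tests; refining the
  grid shrinks the gap, confirming convergence.
* `Tc = 0` (vanishing vascular volume) falls back to the one-compartment
  extraction limit $K^{trans} = F\,E/100$ rather than dividing by zero;
  fitting bounds keep Tc ≥ 0.5 s so the guard never activates in fits.

### Fitting

Each tumor voxel's concentration curve is fitted by bounded
Levenberg–Marquardt least squares (SSR objective) from a seeded
Latin-hypercube of start points over the bounds (default 8 starts);
the best SSR wins, ties broken by the smaller parameter norm so refits
are bit-reproducible. Bounds are generous supersets of reported pelvic
values: Ktrans ∈ [0, 3] min⁻¹, Ve ∈ [0, 60], Vp ∈ [0, 20] mL/100 mL,
F ∈ (0, 200] mL/min/100 mL, Tc ∈ [0.5, 60] s, PS ∈ [0, 100]
mL/min/100 mL. An all-zero curve short-circuits to the zero boundary
solution; failed voxels carry NaN in the maps and are excluded from the
ROI median (never zero-filled, never trimmed — plain medians are
reported). A bolus-arrival delay term is deliberately not fitted by
default: with 2.5 s sampling a grid-searched delay mostly absorbs noise,
and the generator places the bolus on the frame grid.

## Cohort statistics

The per-patient medians feed the diagnostic battery: Mann–Whitney tests
per parameter with Benjamini–Hochberg FDR correction applied **within
each model family** (4 ET tests, 6 DP tests; a global-family switch
exists). The per-model family structure is the one consistent with the
published corrected values; standard monotone (step-up) enforcement is
kept. Note BH is *not* idempotent — re-adjusting adjusted values changes
them — so only monotonicity and the step-up definition are asserted.
Median CIs are distribution-free binomial order-statistic intervals
(coverage ≥ 95% by construction, verified ≥ 93% empirically at n = 25).
Small-sample rank tests use exact enumeration (Mann–Whitney: pooled
n ≤ 12 tie-free; signed-rank: n ≤ 25; Spearman: n ≤ 8), otherwise
normal/t approximations with tie and continuity corrections — matched
against brute-force enumeration oracles in the tests.

ROC analysis orients each marker so AUC ≥ 0.5 (kinetic parameters are
*lower* in high-risk disease, so "positive if value ≤ cutoff"), computes
the tie-corrected concordance AUC (= U/(n₁n₂) on tie-free data), a
DeLong confidence interval, and the Youden-index cutoff with ties broken
toward higher specificity — in a surgical-triage setting false positives
mean overtreatment. McNemar comparisons of classifier correctness
against radiologist reads are stratified the only way the three printed
metric rows can be: accuracy over all patients, sensitivity over
high-risk patients, specificity over low-risk patients; exact binomial
for ≤ 25 discordant pairs. Inter-reader agreement uses ICC(2,1)
(two-way random effects, absolute agreement) with the conventional
poor/good/excellent categories at 0.40 and 0.75.

## The synthetic cohort

The generator emulates the acquisition and statistical structure the
analysis assumes: TR 4.4 ms, flips 6/12/18° with 10 precontrast repeats,
115 dynamics at 2.5 s; a gamma-variate-plus-recirculation population AIF
(peak ≈ 5 mM at 15 s after arrival, tail ≈ 1 mM at 4 min; bolus arrival
30 s so the 10 baseline frames are contrast-free); log-normal
patient-level parameter draws (log-sd 0.3) whose group medians default
to the published low/high-risk values; tissue T1 1000 ms, blood 1400 ms.
Tissue curves are DP-generated by default so that ET fitting exhibits
realistic model mismatch; a `truth_model = "et"` switch enables pure
recovery tests. Noise is added on the *signal* (Gaussian,
sd = baseline/SNR; Rician optional) so the relaxometry inversion is
genuinely exercised. Clinical tables are built to satisfy the risk rule
by construction, and reader calls are simulated conditional on the true
risk group at the published radiologist operating points (DMI 58%/68%,
CSI 19%/100%, LNM 31%/96% sensitivity/specificity).

What it does **not** emulate: anatomy, motion, partial-volume mixing at
ROI edges, B1 inhomogeneity, water-exchange effects, signal drift, or
between-patient AIF variability. Passing tests therefore demonstrate
correctness of the estimation chain under the stated model, not
robustness to those real-world effects.

Group sizes default to 25/26 (a 51-patient cohort; the split is an
assumption, as only the total is published). The deliberately small test
problems — ROIs of 6–10 voxels, 2–4 patients for image-level round
trips, 100 voxels per model for noisy-recovery statistics, parameter-
level simulation for the 51-patient comparison — were chosen as the
smallest sizes at which each property is meaningfully exercised.

## Known limitations

* The ET/DP cross-model coherence in the generator (shared Ve draw,
  fixed Vp scale factor 0.34, Ve factor 1.3) reproduces the published
  cross-model median ratios but not their full joint distribution.
* The DP fit can trade F against Tc on noisy, coarsely sampled curves
  (a known identifiability limit of distributed models at 2.5 s
  resolution); the multi-start design mitigates but does not remove it.
* No B1 correction: at 1.5 T with small flip angles the induced T1 bias
  is modest but systematic; all concentrations inherit it on real data.
* Exact FDR family definitions and the median-CI method of the original
  analysis software are unknowable; both are explicit, documented
  choices here (per-model families; order-statistic CIs).
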