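# dcekinetics

Tracer-kinetic analysis of dynamic contrast-enhanced MRI (DCE-MRI) for
preoperative tumor risk assessment, built around the comparison of two
pharmacokinetic models in endometrial carcinoma: the widely used
**extended Tofts (ET)** compartment model and the richer
**distributed-parameter (DP)** model, which resolves blood flow and
capillary permeability separately. The package covers the entire analysis
chain — signal physics, voxelwise model fitting, per-patient aggregation,
and the full low- vs high-risk diagnostic statistics — plus a synthetic
cohort generator so every stage can be exercised without patient data.

## Who this is for

Imaging scientists and quantitative-MRI researchers who want a tested,
scriptable reimplementation of a perfusion-analysis pipeline that is
usually locked inside commercial software: variable-flip-angle T1
mapping, concentration conversion, individual-AIF model fitting, and the
statistics used to evaluate kinetic parameters as diagnostic biomarkers.

## The models

Tissue concentration is driven by the plasma arterial input function
Cp(t). The ET model lumps flow and permeability into a single transfer
constant:

    Ctiss(t) = (Vp/100) Cp(t) + Ktrans ∫₀ᵗ Cp(u) exp(−Kep (t−u)) du,
    Kep = 100 Ktrans / Ve

with Ktrans, Kep in min⁻¹ and Ve, Vp in mL/100 mL. The DP model treats
the capillary as a spatially distributed exchange unit
(Sangren–Sheppard): tracer transits the vascular space in time Tc, and a
fraction E = 1 − exp(−PS/F) exchanges with the interstitium,

    Ctiss(t) = (F/100) ∫₀ᵗ R(u) Cp(t−u) du,

where the impulse residue R(t) is 1 during the vascular phase (t < Tc)
and thereafter follows the Bessel-function return solution with rates
kp = PS/Vp, ke = PS/Ve. Primitives are (F, Tc, Ve, PS); Vp = F·Tc/60 and
MTT ≡ Tc are derived. The DP implementation is validated against an
independent upwind finite-difference solution of the underlying
two-region convection–exchange PDE (`dp_pde_oracle()`).

Signal physics uses the steady-state spoiled gradient-echo equation
S = M0 sin α (1−E1)/(1−E1 cos α), E1 = exp(−TR/T1), with linearized
variable-flip-angle T1 estimation and linear relaxivity
C = (R1(t) − R1(0))/r1.

## Worked example

Simulate a 51-patient cohort with the group structure the package is
designed around (25 low-risk / 26 high-risk, group medians at published
values) and run the complete comparison:

```r
library(dcekinetics)
tab <- simulate_cohort_table(n_low = 25, n_high = 26, seed = 1)
report <- run_group_comparison(tab)
print(report)
```

```
Study report: 25 low-risk vs 26 high-risk patients

Group comparison (Mann-Whitney, BH-FDR per model family):
 parameter                  low                   high       p   p_adj sig
    Ktrans 0.097 (0.0866-0.115) 0.0498 (0.0432-0.0596) 7.7e-09 1.5e-08   *
    Vp(ET)    0.989 (0.935-1.1)    0.491 (0.442-0.579) 4.9e-09 1.5e-08   *
    Ve(ET)      8.17 (6.6-10.3)         9.32 (7.74-13) 2.7e-01 2.7e-01
       Kep    1.23 (0.854-1.59)    0.498 (0.415-0.608) 1.1e-06 1.5e-06   *
         F       12.4 (11-14.6)       7.96 (7.09-9.18) 6.7e-08 1.8e-07   *
       MTT     15.5 (11.6-17.8)       10.9 (9.19-15.8) 3.1e-02 4.6e-02   *
    Vp(DP)     2.91 (2.75-3.22)         1.45 (1.3-1.7) 4.9e-09 2.9e-08   *
    Ve(DP)     6.28 (5.07-7.89)         7.17 (5.95-10) 2.7e-01 2.7e-01
        PS     8.18 (7.22-9.83)       4.23 (3.92-5.47) 9.2e-08 1.8e-07   *
         E     49.7 (44.1-53.6)       40.6 (32.7-53.5) 1.7e-01 2.0e-01

ROC (positive = high risk):
  ktrans   AUC 0.97 (0.93-1.00)  acc 94%  sens 100%  spec 88%
  ...
  f        AUC 0.94 (0.88-1.00)  acc 92%  sens 92%  spec 92%
  mvd      AUC 0.81 (0.69-0.93)  acc 78%  sens 73%  spec 84%
```

Each row gives the group medians with distribution-free 95% CIs, the
Mann–Whitney p and its BH-FDR correction within the model family. The
high-risk group shows significantly lower Ktrans, Kep and Vp (ET) and
lower F, Vp and PS (DP) — a more hypovascular microenvironment — while
the interstitial volume Ve separates the groups in neither model. The ROC
block reports the AUC with a DeLong interval and the operating point at
the Youden-index cutoff; Ktrans and F are the strongest classifiers,
comfortably above microvessel density (`mvd`).

The image-level pipeline (NIfTI volumes rather than a parameter table)
runs the same way at any scale:

```r
report <- run_study("study_out", n_low = 2, n_high = 2, seed = 5,
                    noise_snr = 20, roi_voxels = 40)
```

which simulates SPGR acquisitions (10 precontrast scans at each of
6°/12°/18°, 115 dynamics at 2.5 s, TR 4.4 ms), fits T1 maps, converts
signal to concentration, extracts the individual AIF from the artery ROI,
fits both models voxelwise and writes medians, fit logs and the report.
A shell wrapper with the same stages lives at `inst/cli/dce_study.R`
(subcommands `simulate`, `fit`, `compare`, `run-all`).

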