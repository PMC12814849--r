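# qpcmr — quantitative perfusion CMR by model-based deconvolution

`qpcmr` quantifies myocardial blood flow (MBF, mL/min/g) from first-pass
gadolinium perfusion cardiovascular magnetic resonance, and provides the
complete statistics suite used to compare a quantitative imaging method
against a reference modality such as ¹⁵O-water PET. It is aimed at
researchers developing or validating pixel-wise perfusion mapping: every
stage of the pipeline is exercised end to end on synthetic phantoms and
simulated paired cohorts with known ground truth, so the methodology can be
tested without any patient data.

## The model

Under linear time-invariant tracer kinetics the myocardial tissue
concentration is the arterial input function (AIF) convolved with a tissue
impulse response function (IRF):

C_t(t) = [C_a(· − δ) ⊛ IRF](t)

with bolus-arrival delay δ. Three IRFs are supported:

| Model          | IRF                                  | flow read-out (MBF)        |
|----------------|--------------------------------------|----------------------------|
| Tofts          | K_trans · exp(−(K_trans/V_e) t)      | K_trans / 1.05             |
| modified Tofts | Tofts + V_p δ(t)                     | K_trans / 1.05             |
| Fermi          | F / (exp(k (t − MTT)) + 1)           | IRF(0) = F/(1+e^(−k·MTT))  |

K_trans (min⁻¹) is the plasma-to-interstitium transfer constant, V_e and
V_p the extravascular-extracellular and plasma volume fractions, F the
Fermi amplitude, k the clearance rate (s⁻¹) and MTT the transit-time
offset (s). The Tofts-family read-out converts per-mL-tissue to per-gram
with density 1.05 g/mL; the Fermi read-out is the initial IRF amplitude,
the identifiable flow quantity (see the methods vignette). Per pixel, MBF
is estimated by constrained Levenberg–Marquardt least squares with an
exhaustive bolus-delay grid search; myocardial perfusion reserve (MPR) is
stress MBF / rest MBF.

Around the core sit: saturation-recovery signal↔concentration conversion
(dual-sequence TD 25/110 ms), proton-density normalisation, 10-mm
blood-pool AIF extraction with hematocrit correction, AHA 16-segment
labelling with LAD/RCA/LCX territories, segment exclusion rules
(poor registration; thickness < 5 mm), and the agreement suite: Pearson +
regression, Bland–Altman, absolute-agreement ICC(A,1) with F-based CI,
paired TOST equivalence (margins 0.90/0.98 participant, 1.43/2.80
vessel/segment), Mann–Whitney ROC AUC against PET-defined abnormality
(stress MBF ≤ 2.3 mL/min/g, MPR ≤ 2.5), DeLong AUC comparison, and
ICC-based sample-size planning.

## Worked example

```r
library(qpcmr)

aif <- gamma_variate_aif(aif_model_params(), seq(0, 59), hematocrit = 0.42)
tissue <- simulate_tissue_curve(aif, "tofts",
                                list(K_trans = 0.8, Ve = 0.15), delay = 2)
fit_curve(tissue, aif, "tofts", list(delay_max = 6))
#> <kinetic_fit:tofts> MBF 0.762 mL/min/g, delay 2.0 s, R2 1.0000 (converged)
```

The fit recovers the generating parameters exactly: K_trans = 0.8 min⁻¹
gives MBF = 0.8/1.05 = 0.762 mL/min/g, and the 2-s bolus delay is found by
the grid search. On the agreement side:

```r
co <- simulate_paired_cohort(cohort_spec(n_subjects = 5000,
        cmr_bias = 0.31, cmr_noise_sd = 0.70 / sqrt(2),
        pet_noise_sd = 0.70 / sqrt(2), seed = 77))
bland_altman(cohort_pairs(co, "stress"))[c("bias", "sd")]
#> $bias
#> [1] 0.2995824
#> $sd
#> [1] 0.6871697
```

— a cohort with an injected CMR-vs-PET bias of 0.31 mL/min/g and
paired-difference sd 0.70 is recovered by Bland–Altman analysis to within
Monte-Carlo error.

The `analysis/` directory holds the narrative workflow
(`01_simulate_phantom.R` → `04_roc_delong.R`): phantom simulation,
pixel-wise mapping with all three models, cohort agreement analysis, and
ROC/DeLong model comparison, each writing its tables under `results/`.

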