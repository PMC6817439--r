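# hp13cmri

Multiparametric hyperpolarized (HP) ¹³C MRI analysis for preclinical
prostate cancer, driven by a fully synthetic "digital cohort" so that
every stage of the pipeline is verifiable against known ground truth.

## The problem

Aggressive prostate tumors acidify their extracellular space: lactate
produced by glycolysis is exported (largely via the MCT4 transporter),
depressing extracellular pH (pH_e). A multiparametric MR exam can read
this out in vivo:

* **HP [¹³C] bicarbonate MRI** measures pH_e per voxel from the
  bicarbonate/CO₂ pair via the excitation-ratio-corrected
  Henderson–Hasselbalch equation

      pH = pKa + log10( (S_bic / S_CO2) · κ ),   κ ≈ sin 25° / sin 2.78° = 8.714

  where κ corrects for the two-band excitation pulse that tips CO₂ at
  25° but spares the large bicarbonate pool at 2.78°.
* **HP [1-¹³C] pyruvate MRI** maps the lactate-to-pyruvate signal ratio
  (Lac/Pyr), a surrogate of glycolytic conversion.
* **¹H diffusion MRI** maps the apparent diffusion coefficient (ADC),
  which falls with tumor cellularity.

`hp13cmri` implements the complete analysis chain — CSI reconstruction
and peak integration, SNR-masked pH mapping, slab-matched Lac/Pyr
mapping with asymmetric SNR rules, mono-exponential ADC fitting with
residual/free-water exclusion, histologic-index grading (0–3,
dichotomized at 2), per-lesion ROI summaries, and the statistical
battery (exact Mann–Whitney, Spearman, Cohen's d, nested
random-intercept mixed-effects model) — plus a seeded generator of
digital mice/lesions with known ground-truth fields that feeds all
three simulated acquisitions. It is aimed at researchers developing or
validating HP ¹³C pH imaging analyses who need a tested, reproducible
reference implementation.

## Worked example

```r
library(hp13cmri)

params <- acquisitionParams()            # 8x8x256 CSI, 12x12x16 volumes, b = 0..515
cohort <- generateCohort(5, 7, params, seed = 1)   # 5 low-, 7 high-grade lesions
tables <- processCohort(cohort, params, seed = 1, peakSNR = 30)
report <- writeReport(tables)
```

On this cohort the report prints:

```
meanPH : low 7.52 +/- 0.17, high 7.22 +/- 0.13, U = 33, p = 0.0101, d = 2.10
minPH  : low 7.43, high 7.07, p = 0.0051
Lac/Pyr: low 0.80, high 1.80, p = 0.0025
meanADC: low 1.59e-03, high 9.96e-04 mm^2/s, p = 0.0025
mixed model: pH slope -0.18 per unit Lac/Pyr (192 voxels)
Spearman meanPH vs Mct4: rho = -0.99
```

Read: low-grade lesions sit near pH_e 7.5 and high-grade near 7.2 with
a large effect size (|d| > 1.5); regional-minimum pH separates the
grades even more cleanly; high-grade lesions show higher Lac/Pyr and
lower ADC; voxelwise pH falls with Lac/Pyr; and pH correlates
negatively with Mct4 expression — the signature of lactate-export
driven acidification.

The methods vignette (`vignettes/digital-cohort-pipeline.Rmd`) details
the measurement model, every threshold (SNR ≥ 3 for bicarbonate/CO₂,
SNR ≥ 4 for lactate, RMS residual ≤ 500, ADC ≤ 3.0 × 10⁻³ mm²/s,
tumor fraction ≥ 50%, grade cutoff 2), and what the simulator does and
does not emulate.

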