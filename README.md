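# darklung

Quantification of ventilation-dependent X-ray dark-field signal in lungs.

Grating-based dark-field radiography measures small-angle X-ray scattering
from sub-resolution microstructure — in the thorax, the alveolar network —
as a reduction of interferometric fringe visibility. Because structural
lung disease alters alveolar microstructure, the logarithmic dark-field
signal −ln *D* is a candidate imaging biomarker, but it also changes with
normal breathing. This package implements the calculation chain that
separates those effects by correlating dark-field radiographs with
CT-derived lung geometry, for researchers working on quantitative
dark-field chest imaging.

The core quantities, in the field's standard notation:

* **Dark-field extinction coefficient** ⟨μ_d⟩ (1/m): the slope of the
  noise-weighted pixelwise regression of −ln *D* against the projected
  lung thickness *d*^lung obtained by cone-beam forward projection of the
  Hounsfield-thresholded, binary-closed lung segmentation *S*
  (*L*^low < HU < *L*^high, strict).
* **Normalized scatter** μ_d/μ: the slope of −ln *D* against the
  water-equivalent height *d*^H2O (projection of
  *M* = *S*·(HU+1000)/1000), divided by the spectrally simulated
  effective water attenuation coefficient μ_eff^H2O of the acquisition
  spectrum.
* **CNR ratio** CNR(ln *D*)/CNR(ln *T*): normalized scatter divided by the
  shot-noise ratio σ(ln *D*)/σ(ln *T*) = √[1 + 2(1 + 1/(*T D*²)) /
  ((*V*^r)²(1 + 1/*T*))] — the relative ability of the two modalities to
  detect a small difference in lung thickness.

Before regression, measured visibility reduction is corrected for
beam-hardening using polyoxymethylene calibration stacks (per-column
monotone-spline interpolants ν^sec(*T*); *D* = ν/ν^sec), and the constant
regression intercept Δ is modeled as a Compton-background mismatch between
sample and calibration scans. A tungsten-tube spectral model (Kramers
continuum + K lines, CsI detector, bundled attenuation tables) supplies
μ_eff^H2O; a seeded digital thorax phantom generates CT volumes,
registered radiographs and calibration stacks for validation.

## Worked example

```r
library(darklung)
res <- runPipeline(list(
  seed = 1L,
  phantom = list(ventilation_state = "high", noise = TRUE,
                 mu_d_true = 4.0, delta_true = -0.05, flux_ref = 1e4)))
res$summary
#>   x_kind slope_1_m intercept r_squared n_pixels lung_volume_l mu_eff_1_m
#> 1 d_lung     3.962  -0.04245    0.3367    21328         1.369      25.55
#> 2  d_h2o    19.781  -0.04181    0.3358    21328         1.369      25.55
#>   normalized_scatter noise_ratio cnr_ratio
#> 1                 NA        4.81        NA
#> 2             0.7742        4.81    0.1609
```

The phantom was built with μ_d = 4 1/m and Δ = −0.05: the pipeline
segments the generated CT (1.369 l lung volume), forward-projects, applies
the beam-hardening correction and recovers slope 3.962 1/m and intercept
−0.042 from 21 328 lung pixels under shot noise at 10⁴ photons/pixel
(noise-free runs recover 4.000 to better than 0.1%). The d^H2O slope,
19.78 1/m, divided by the simulated 60 kV effective water attenuation
25.55 1/m gives the phantom lung's normalized scatter 0.774; at the median
lung signal levels the theoretical noise ratio is 4.81, so small lung
thickness differences reach only 16% of the attenuation CNR in this
phantom. (Real ventilated lungs show normalized scatter near 0.4–0.56 —
the phantom's uniform 4 1/m extinction at high-inflation density is
deliberately generic.)

Stage functions (`segmentLung`, `forwardProject`, `buildCalibration`,
`correctBeamHardening`, `noiseWeights`, `weightedLinearFit`,
`powerLawFit`, `ventilationSummary`, `shotNoiseRatio`, `cnrRatio`, …) are
exported individually and compose to the same result as `runPipeline`;
see the vignette for the model details and design choices.

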