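# pulseoxmc

Monte Carlo modelling of how skin pigmentation perturbs reflectance pulse
oximetry.

Reflectance pulse oximeters — the sensors in smartwatches and fitness
trackers — estimate arterial oxygen saturation (SpO₂) from light
backscattered out of the skin at 660 nm and 940 nm. The calibration maps
the ratio of ratios

```
R = (AC660 / DC660) / (AC940 / DC940)
```

to saturation through an empirical linear relation `SaO2 = a − b·R`.
Because the backscattered signal is dominated by the superficial layers
where melanin sits, the calibration can shift substantially with skin
pigmentation. `pulseoxmc` is for biomedical-optics researchers and
oximeter algorithm developers who want to study that mechanism in
simulation. It provides:

* a photon-packet Monte Carlo transport engine (Rcpp) for a layered finger
  model — hop–drop–spin with implicit capture, Henyey–Greenstein
  scattering, Fresnel/Snell boundary physics, roulette termination, and an
  azimuthal-symmetry disc-detector estimator at a 3 mm source–detector
  separation;
* a chromophore model composing layer absorption from melanosome fraction
  (`6.6e10·λ^-3.33` power law), water, and arterial/venous whole blood,
  with skin presets at 2.55% / 15.5% / 30.5% melanosomes (light, moderate,
  dark) and a systolic phase that doubles the diastolic blood volume;
* the oximetry pipeline reducing systolic/diastolic reflectance at both
  wavelengths to AC, DC, perfusion index and R over the SaO₂ grid
  70–100% in 5% steps;
* calibration analysis: least-squares curve fitting, skin-type correction
  factors (mean inverted-R-ratio method), and the transmittance-vs-
  reflectance bias/RMSE analysis on a packaged set of published
  calibration equations.

## Worked example

The closed-form calibration-bias analysis on the packaged reference
equations:

```r
library(pulseoxmc)
rc <- reference_curves()
light <- bias_analysis(rc$light_transmittance, rc$light_reflectance)
light
#> bias_report [light]: RMSE 0.3956%
#>  sao2 r_reference bias_percent
#>    95      0.5503      0.69843
#>    96      0.5110      0.51997
#>    97      0.4717      0.34151
#>    98      0.4324      0.16305
#>    99      0.3931     -0.01541
#>   100      0.3538     -0.19387
```

Bias is the difference between what the transmittance and reflectance
calibrations predict at the same measured R (R generated from the
light-skin transmittance reference over the healthy 95–100% range). For
light skin it stays within ±0.7%; the same analysis yields RMSEs of
0.9132% for moderate and 8.4111% for dark skin — the reflectance-mode
penalty of pigmentation. Correction factors rescale R to align the
moderate and dark reflectance curves with the light-skin baseline:

```r
correction_factor(rc$dark_reflectance, rc$light_reflectance)
#> correction_factor [dark]: 2.1665
```

A Monte Carlo run producing a simulated dark-skin calibration curve:

```r
curve <- ratio_curve("dark", settings = engine_settings(detected = 2e4),
                     base_seed = 1)
fit_curve(curve$sat_a, curve$r, skin_type = "dark")
#> calibration_curve [dark, NA]: SaO2 = 113.5 - 31.02 * R
```

(the fitted slope and intercept vary by a few percent with the seed at
this packet count). The same pipeline is scriptable from a shell via
`exec/pulseoxmc` with subcommands `simulate`, `calibrate`, `bias-report`
and `full-run`.

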