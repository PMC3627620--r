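# cmrT2map

Quantitative myocardial T2 mapping with T2-prepared single-shot sequences:
a simulation and analysis toolbox for studying why apparently healthy
myocardium can map to edema-like T2 values.

T2 mapping detects myocardial edema without contrast agents: a T2
preparation module imposes the weighting `S(TEprep) = S0 * exp(-TEprep/T2)`
before a fast single-shot readout, and repeating the acquisition at several
preparation times (here 0, 24 and 55 ms) allows a pixel-wise fit of T2.
In practice the fitted values are biased by three mechanisms that this
package simulates with known ground truth:

* **Partial volume** — myocardial T2 is near 50 ms, but blood (~200 ms) and
  pericardial fat (~80 ms) border the wall on both sides; a voxel containing
  a blood admixture fits far too high (a 50/50 myocardium/blood voxel fits
  to ~91 ms). Thin walls at coarse resolution are affected most.
* **Residual diastolic motion** — the single-shot images are acquired in
  different heartbeats; in-plane displacement between them mixes tissues
  across the prep-time series and inflates (or deflates) the fit near wall
  edges.
* **Readout transients** — the recorded contrast is the k-space-center
  signal of a transient readout. A Bloch simulation of the shot train
  (including incomplete T1 recovery between shots) reproduces the
  characteristic ordering: spoiled-gradient-echo (FLASH, centric) maps read
  slightly *below* a spin-echo reference while balanced-SSFP (linear) maps
  read well *above* it.

The package is organized around a digital cardiac phantom
(`phantom_spec()`, `render_phantom()`, `simulate_prepared_series()`,
`make_cine()`), the map fit (`fit_t2_map()`, returning a classed `t2map`
object with `print`/`summary`/`plot` methods; `fit_t2_multiecho()` for the
32-echo spin-echo reference), motion correction (`motion_correct()`), AHA
6-segment analysis (`segment_myocardium()`, `roi_stats()`,
`edema_vs_remote()`), cine-based motion metrics (`mmode_projection()`,
`diastolic_motion()`, `wall_thickness()`), agreement statistics
(`bland_altman()`, `cov_interscan()`, `tolerance_interval()`,
`paired_compare()`), and end-to-end experiment designs (`run_experiment()`).
A thin command-line front-end lives in `inst/cli/t2map.R`.

## Worked example

A short-axis phantom with a thin (2.5 mm) anteroseptal sector imaged with
the FLASH-based protocol at the standard 2.7 x 2.1 mm resolution:

```r
library(cmrT2map)
spec <- phantom_spec(thin_thickness_mm = 2.5, noise_sigma = 0.02)
fr   <- render_phantom(spec)
ser  <- simulate_prepared_series(fr,
          protocol = acquisition_protocol(readout = "flash_centric"),
          seed = 1)
map  <- fit_t2_map(ser)
labels <- segment_myocardium(annulus_contours(spec), spec$grid_shape,
                             spec$pixel_size_mm)
roi_stats(map, labels)
```

```
segmental T2 report (flag threshold 70 ms)
 id         label mean_t2_ms sd_t2_ms n_pixels abs_dev_from_global_ms flagged
  1      anterior       56.0     13.3       15                    1.5   FALSE
  2  anteroseptal       60.5     16.4       12                    6.0   FALSE
  3  inferoseptal       57.4     13.0       15                    2.8   FALSE
  4      inferior       53.1      9.0       27                    1.4   FALSE
  5 inferolateral       51.9      9.0       34                    2.6   FALSE
  6 anterolateral       54.1     10.9       27                    0.4   FALSE
  0        global       54.5     11.3      130                    0.0   FALSE
```

The true myocardial T2 is 50 ms everywhere: the thin anteroseptal sector
reads 60.5 ms purely through partial volume with adjacent blood, while the
thick inferolateral wall stays near truth. Adding residual diastolic motion
and thinner walls drives such segments past the 70 ms outlier flag
(`flagged = TRUE`), the false-edema mechanism the cohort experiment
(`run_experiment(experiment_config("volunteer_cohort"))`) quantifies.

The readout-bias experiment reproduces the phantom ordering:

```r
run_experiment(experiment_config("phantom_bias"))$summary$fitted_t2_ms
#> $flash_centric  60.78
#> $ideal          62.00
#> $ssfp_linear    68.73
```

against a ground-truth T2 of 62 ms (the multi-echo spin-echo reference fit
also returns 62.00).

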