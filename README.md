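# kymovel

Unbiased red-blood-cell (RBC) size and velocity from laser line-scan
kymographs.

## The problem

Blood flow in individual brain vessels is routinely measured with a
scanning microscope by sweeping the laser focus repeatedly along a vessel
segment. Stacking the sweeps gives a space–time (Xt) image — a kymograph —
in which every unlabeled RBC leaves an oblique dark stripe against the
fluorescent plasma. The classic analysis treats each line as if it were a
camera snapshot: the apparent cell size is the stripe width, and the
apparent velocity is the per-line stripe displacement over the line period,
`v_app = dx / T_line = cot(alpha)` in scaled axes.

A scanning system, however, acquires the pixels of each line *sequentially*
at the scan speed `V_scan`. The focal spot closes on a cell at the relative
speed between scanner and cell, so for a cell moving at true speed
`V_real`:

    T_RBC  = D_real / (V_scan − V_real)               (traversal time)
    D_app  = D_real · V_scan / (V_scan − V_real)      (shadow size)
    V_AA   = V_scan · V_real / (V_scan − V_real)      (anterograde apparent speed)
    V_AR   = V_scan · V_real / (V_scan + V_real)      (retrograde apparent speed)

with the signs resolved by the scan direction relative to flow
(anterograde = with the flow). Anterograde scanning stretches shadows and
overestimates speed — by 100 % already at `V_real = V_scan / 2` — and
diverges at `V_real = V_scan`; retrograde scanning compresses and
underestimates, but stays finite at any flow speed. The two apparent speeds
of the same flow obey `1/V_AR − 1/V_AA = 2/|V_scan|`, which makes the model
testable from measurable quantities alone:
`V_AA = |V_scan|·V_AR / (|V_scan| − 2·V_AR)` has `V_scan` as its only
parameter.

`kymovel` provides, for anyone analysing line-scan blood-flow data:

* the closed-form bias model and its inversions (`apparent_velocity`,
  `real_velocity`, `apparent_size`, `real_size`, `relative_error`,
  `bidirectional_residual`, `vaa_from_var`), with explicit direction
  handling and hard errors at the anterograde pole;
* a first-principles line-scan simulator (`simulate_kymograph`) built only
  from per-pixel acquisition timing — the independent oracle for the closed
  forms, and a fixture factory with known ground truth (bidirectional
  sweeps, PSF blur, Poisson/Gaussian noise, seeded);
* apparent-velocity extraction from kymographs (`estimate_apparent_velocity`,
  SVD-separability or Radon criteria with windowing and quality flags),
  bidirectional splitting (`split_bidirectional`), shadow-size and
  vessel-diameter measurement (`measure_apparent_size`,
  `measure_vessel_diameter`);
* the validation machinery (`fit_vscan`: single-parameter
  Levenberg–Marquardt recovery of `V_scan` from paired apparent speeds,
  with robust confidence intervals; `run_validation_experiment`: full
  synthetic replication of the bidirectional validation;
  `generate_theory_curves`; `linear_fit`);
* TIFF + JSON/YAML sidecar I/O (`read_kymograph`, `write_kymograph`) and a
  command-line interface (`kymovel_cli`, launcher in `inst/cli/kymovel`).

## Worked example

Simulate a capillary-like acquisition (scan speed 10 mm/s, anterograde,
60 µm segment, cells at 2 mm/s), extract the apparent velocity, and correct
it:

```r
library(kymovel)

scan <- scan_parameters(v_scan = 10, direction = "anterograde",
                        t_line = 6.3, x_pixel = 0.5, n_pixels = 120)

k <- simulate_kymograph(kymo_config(scan,
       rbc_train(spacing = 30, d_real = 6, v_real = 2, segment_length = 60,
                 duration = 120 * 6.3),
       n_lines = 120, psf_fwhm = 1, noise = "poisson", background = 200,
       seed = 1))

res <- estimate_apparent_velocity(k, window_s = 0.75)
res
#> Apparent velocity (svd method): 2.5 mm/s
#>   1 window(s), 1 used, 0 flagged low-quality

real_velocity(res$v_app_mean, scan)
#> [1] 2.000022
```

The stripes move at 2.5 mm/s in the image — a 25 % overestimate that the
camera model would report as the flow speed — and the scan-speed-aware
inversion recovers the true 2 mm/s. The magnitude of that bias grows with
`V_real/V_scan`; at half the scan speed it reaches 100 %:

```r
relative_error(5, scan)   # (V_real − V_AA) / V_real at V_real = 5, V_scan = 10
#> [1] -1
```

The bidirectional consistency fit, on synthetic paired apparent speeds with
2 % measurement noise, recovers the scan speed it cannot see directly:

```r
tab <- simulate_bidirectional_pair_table(1:8, 10, noise_cv = 0.02, seed = 2)
fit_vscan(tab)
#> Scan-speed recovery fit  v_aa ~ v_scan * v_ar / (v_scan - 2 v_ar)
#>   v_scan = 9.777 mm/s  [7.172, 12.38] at 95% confidence
#>   chi-square 154.6 on 8 pairs
```

and the full synthetic validation (38 vessels, scan speeds 5–40 mm/s)
checks that correcting the anterograde and the retrograde measurement of
the same vessel gives the same answer:

```r
run_validation_experiment(noise_cv = 0.02, seed = 99)
#> Bidirectional validation on 38 synthetic vessels (noise cv 0.02)
#>   recovered vs true v_scan:   slope 0.992 +/- 0.009 (R^2 0.9998)
#>   corrected-velocity match:   slope 0.993 +/- 0.008 (R^2 0.9978)
```

Both slopes sit at the identity: the model is self-consistent and the
corrections agree.

## Command line

```sh
Rscript inst/cli/kymovel correct --v-app 10 --v-scan 10 --direction anterograde
# v_real = 5 mm/s
Rscript inst/cli/kymovel simulate --config demo.yaml --seed 1 --out demo
Rscript inst/cli/kymovel extract --image demo.tif --window-s 1 --out windows.csv
Rscript inst/cli/kymovel validate --noise-cv 0.02 --seed 7 --out report.json
```

CSV outputs use the package-wide units: µm for lengths, mm/s for speeds,
ms for times (window tables additionally report window start/length in
seconds). Every simulated image carries a JSON sidecar with the full
generating parameter set and seed.

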