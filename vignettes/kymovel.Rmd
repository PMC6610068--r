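---
title: "Scan-speed-aware RBC velocimetry: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-speed-aware RBC velocimetry: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymovel)
```

## The acquisition model

A line-scan acquisition sweeps the laser focus along a vessel segment at
speed $V_{scan}$ and repeats the sweep every $T_{line}$ milliseconds
($T_{line}$ includes the sweep itself plus any dead time and the fly-back,
so $T_{line} \ge n_{pixels} \cdot T_{pixel}$ with
$T_{pixel} = X_{pixel}/V_{scan}$). Unlabeled RBCs exclude the fluorescent
plasma dye and appear as dark stripes in the resulting space–time image.

Because pixels within a line are acquired sequentially, the time at which
the shadow of a moving cell is sampled depends on where the cell is. The
scanner closes on a cell at the *relative* speed between the two, which
gives the traversal time $T_{RBC} = D_{real}/(V_{scan} - V_{real})$ for
scanning with the flow (anterograde) and $D_{real}/(V_{scan} + V_{real})$
against it (retrograde). Everything else follows from that one fact:

* shadow size $D_{app} = V_{scan} T_{RBC}$, i.e. stretched anterograde,
  compressed retrograde, equal to $D_{real}$ only for a resting cell;
* apparent velocity (camera model, stripe slope)
  $V_{AA} = V_{scan}V_{real}/(V_{scan}-V_{real})$ and
  $V_{AR} = V_{scan}V_{real}/(V_{scan}+V_{real})$;
* the measurable consistency identity
  $1/V_{AR} - 1/V_{AA} = 2/|V_{scan}|$, equivalently
  $V_{AA} = |V_{scan}| V_{AR}/(|V_{scan}| - 2 V_{AR})$, which has the scan
  speed as its only parameter.

The anterograde forms have a pole at $V_{real} = V_{scan}$: the scanner
never overtakes the cell, the shadow stretches without bound, and no
anterograde observation exists. `kymovel` treats inputs within $10^{-6}$
relative distance of a pole as *at* the pole and raises an error rather
than returning infinities that would silently poison a pipeline.
Velocities are stored as magnitudes with an explicit direction enum —
mixing signed velocities with absolute-value formulas is the classic way to
get these corrections wrong.

Units are fixed package-wide: µm, mm/s, ms. Since 1 mm/s = 1 µm/ms, no
conversion constants appear in any formula.

One published form of the displacement-time relation reads as if the time
to move by $\Delta X$ were $T_{line} + \Delta X \cdot V_{scan}$; that is
dimensionally inconsistent, and the package follows the consistent version
$T_{line} + \Delta X / V_{scan}$, which is also what the reformulated
apparent-velocity equations above imply.

## The simulator: oracle, not mirror

`simulate_kymograph()` renders images from nothing but the acquisition
geometry: pixel $(i, j)$ samples position $x_j = (j + 0.5) X_{pixel}$ at
time $t(i,j)$ from `acquisition_time_map()`, and is darkened when any cell
interval $[x_0 + v t - d/2,\; x_0 + v t + d/2]$ covers $x_j$. The
closed-form equations appear nowhere in the renderer, so the emergent
shadow widths and stripe slopes are an *independent* check of them — the
test suite verifies agreement within one pixel (sizes) and 2 % (slopes)
across a grid of velocities, scan speeds and directions.

Modelling choices, and what they imply about real data:

* Cells are 1-D top-hat occupancy intervals along the vessel axis. A
  line-scan only samples the axis and the size model is purely axial, so
  nothing is lost for the quantities modelled here — but cell shape,
  tumbling, and deformation dynamics are out of scope.
* The optional point-spread function is a 1-D Gaussian blur of the
  occupancy profile (FWHM in µm); its contribution to shadow *width* is
  deliberately not modelled or corrected.
* Noise is Poisson (photon counting) or additive Gaussian, applied last;
  the test suite checks the Poisson variance–mean identity on the
  simulator's output.
* Bidirectional acquisition renders each line as a forward sweep
  immediately followed by a backward sweep over the same segment (stored in
  raw detector order: second half in reverse position order), with an
  optional turnaround dead time (default 0; no published value exists).
  Scanner acceleration at the turnarounds is handled the way practitioners
  do — by discarding a configurable fraction of each sweep's columns in
  `split_bidirectional()` — rather than by simulating the transient.
* Retrograde images are stored in position order (columns = increasing
  position along the flow axis), so the time map runs right-to-left within
  each line. This keeps stripe slopes positive in both directions and makes
  the two halves of a split bidirectional image directly comparable.
* `rbc_train()` places cells at a fixed spacing. Real capillary traffic is
  irregular and hematocrit-dependent; a passing test on regular trains
  shows the estimator works on well-sampled images, not that it is robust
  to cell crowding.

**Sampling limits are physical, not implementation details.** Two of them
shape both the tests and what users should expect on real data:

* *Aliasing.* A periodic train whose apparent spacing (real spacing scaled
  by $V_{scan}/(V_{scan} \mp V_{real})$) is smaller than the per-line
  displacement produces an image in which the true slope is mathematically
  indistinguishable from the slope modulo the spacing. No estimator can
  undo this; fixtures and acquisitions must keep apparent spacing above
  roughly $1.3 \times$ displacement plus a shadow width.
* *Anterograde range.* A cell stays inside the segment for about
  $V_{scan}/V_{app}$ line periods (the line period is at least the sweep
  time), so once $V_{AA} \gtrsim V_{scan}/2$ — i.e.
  $V_{real} \gtrsim V_{scan}/3$ — it appears on fewer than ~2 lines and the
  image simply contains no multi-line correspondence to measure. This is
  the quantitative form of the advice that retrograde scanning accesses a
  larger velocity range ($V_{AR} < V_{scan}/2$ always, so retrograde
  stripes always span $\ge 2$ lines). End-to-end recovery is therefore
  tested for anterograde $V_{real}$ up to $\approx 0.4\,V_{scan}$ and
  retrograde up to 20 mm/s, where it holds within 3 % noiseless and 10 % at
  shot-noise SNR ≈ 5.

## Extracting the apparent velocity

`estimate_apparent_velocity()` works per window (default 1 s of recording;
incomplete trailing windows are dropped) and uses two regimes, switched
automatically:

*Shallow stripes (≤ 4 px displacement per line).* The window is resampled
along candidate stripe directions — a rectangle whose long axis follows the
candidate angle, so steep and shallow candidates are treated uniformly —
and scored either by SVD separability ($\sigma_1^2 / \sum_k \sigma_k^2$ of
the mean-subtracted resampled patch; the mean is removed because the DC
component otherwise dominates $\sigma_1$ at every angle) or by a
Radon-style criterion (variance of the across-stripe projection profile,
normalised by total variance). The search runs a 1024-candidate grid over
$(0, \pi/2]$ with golden-section refinement to $10^{-4}$ rad, and the
angle maps to speed via the axis scaling,
$V_{app} = (X_{pixel}/T_{line}) \cot \alpha$.

*Steep stripes (> 4 px/line).* Angle resampling assumes consecutive rows
overlap along the stripe; once the per-line displacement exceeds the shadow
width, consecutive-line shadow segments are disjoint and interpolating
between rows mixes unrelated cells (empirically, the separability at the
true angle collapses and degenerate vertical/horizontal interpretations
win). The displacement is instead measured directly: mean normalised
cross-correlation between rows 1–3 lines apart (after per-row mean removal,
which suppresses the background-induced correlation plateau), sub-pixel
parabolic peak interpolation, and a consistency rule — a real displacement
peak at lag $c$ must replicate at $2c$ and $3c$; ties between
self-consistent candidates (the aliases of a periodic train) go to the
smallest lag, and lag 0 competes so that static patterns fall through to
the angle search.

*Quality flags.* Each window's score is compared with the best score of a
surrogate in which pixels are permuted independently *within* each row —
this destroys stripes of every orientation, including vertical ones
(shuffling whole rows would leave a resting cell's vertical stripe intact
and misflag it). Windows whose margin is below 0.1 are excluded from the
mean; if all windows are flagged the function errors rather than returning
a number from noise.

`measure_apparent_size()` thresholds at the midpoint of the two intensity
modes (2-means seeded at the extremes, deterministic), takes the longest
interior below-threshold run per row (border-touching runs are truncated
shadows) and reports the median across rows times the pixel size.

`measure_vessel_diameter()` applies the conventional 3×3 median filter,
averages along the vessel axis and reports the full width at half maximum
between the background level and the profile maximum, with linear
interpolation of the crossings. FWHM was chosen because "width of the
fluorescent plasma" is not otherwise operationalised; note that the median
filter erases a band one pixel wide, so the thinnest measurable vessel is
two pixels across.

## The scan-speed fit

`fit_vscan()` fits $V_{AA} = V_{scan} V_{AR}/(V_{scan} - 2 V_{AR})$ to
paired apparent speeds by Levenberg–Marquardt minimisation of the
unweighted chi-square (no per-point error model is available), started at
the closed-form value $2/\mathrm{median}(1/V_{AR} - 1/V_{AA})$ and bounded
below by $2\max(V_{AR})$, past which the model is undefined. Pairs with
$V_{AR} \ge V_{AA}$ are impossible under the model and are reported and
excluded. The test suite cross-checks the minimiser against a
$10^5$-point brute-force grid search on every random instance it tries.

Two statistical refinements proved necessary, both validated by seeded
coverage simulations (400 replicates, n = 30 pairs, 2 % multiplicative
noise on both coordinates):

* *Errors-in-variables bias.* $V_{AR}$ is measured too, and the model is
  convex in it, so the raw minimiser is biased upward (~0.5 % at 2 %
  noise). The reported estimate subtracts the first-order curvature bias,
  $\Delta = \sum_i J_i \,(-\tfrac12 f''_i \hat{cv}^2 x_i^2) / \sum_i J_i^2$,
  with the noise scale $\hat{cv}$ estimated from the relative residual
  scatter de-inflated by the local log–log slope. The raw minimiser is kept
  as `v_scan_lm`.
* *Interval calibration.* With multiplicative noise the residual variance
  spans orders of magnitude and leverage concentrates in the few near-pole
  pairs; the model-based covariance covered the truth only ~50 % of the
  time at nominal 95 %. The CI therefore uses a leverage-corrected
  (HC3-style) sandwich standard error with a Satterthwaite-style effective
  df (typically ~4 at n = 30). Measured coverage: 95.3 %.

`run_validation_experiment()` replays the whole bidirectional validation on
synthetic vessels: true velocities uniform on 0.5–15 mm/s, each vessel
assigned a scan speed from {5, 10, 15, 20, 40} mm/s restricted to
$V_{scan} \ge V_{real}/0.8$ (an experimenter picks a scan speed that can
sample the vessel; this also avoids the anterograde pole), 2 %
multiplicative noise on each apparent speed. It reports the
recovered-vs-true scan-speed slope and the slope between the two
corrected-velocity estimates of each vessel; both sit at the identity when
the model is right. Analyses use free-intercept ordinary least squares and
report slope ± standard error, mirroring how such validations are usually
summarised. The corrected-vs-corrected slope runs ~1–2 % below 1 on
average: ordinary least squares with noise on both axes attenuates, and
the corrections are mildly nonlinear in the noisy inputs. The effect is
well inside the ±0.02 band the synthetic experiment is checked against.

## Degenerate inputs and numerical conventions

* Column $j$ is centred at $x = (j + 0.5) X_{pixel}$ (0-based); rows are
  line sweeps.
* Near-pole inputs (within $10^{-6}$ relative) error out; retrograde
  observations with $V_{app} \ge V_{scan}$ are rejected as inconsistent
  with any real velocity.
* All randomness flows through explicit integer seeds; the RNG state of the
  caller is saved and restored, and identical seeds give bit-identical
  images (the TIFF writer biases integer counts by half a quantisation step
  so 16-bit storage round-trips exactly).
* Golden-section refinement stops at $10^{-4}$ rad; at the stationary
  boundary ($\alpha = \pi/2$) the cotangent correctly returns ~0.
* Windows smaller than 10×10 px, recordings shorter than one window, flat
  images, and degenerate regressors all raise informative errors.

## Problem sizes used in the checks

The automated checks run simulations sized for a single CPU: kymographs of
120–300 pixels × 4–120 lines, grids of 30 velocity/scan-speed/direction
combinations for the simulator-oracle comparison, 100 seeded replicates of
the n = 30 fit for accuracy and coverage, 20 random instances for the
minimiser-vs-grid-search cross-check, and a 38-vessel synthetic
bidirectional experiment. These sizes are the package's reference
conditions; all scale linearly if larger studies are wanted.

## Known limitations

* The model assumes constant scan speed; acquisitions with long
  acceleration phases need those columns discarded
  (`split_bidirectional(discard_fraction = ...)`) or a scanner-specific
  kinetic model, which is out of scope.
* PSF broadening of shadow widths is not corrected; apparent sizes of cells
  comparable to the PSF are biased accordingly.
* Aliasing and the anterograde visibility limit (above) bound what any
  extraction can recover; the package flags low-quality windows but cannot
  detect a cleanly aliased periodic train.
* The simulator does not model hematocrit-dependent cell interactions,
  3-D vessel geometry, photobleaching, or flux/hematocrit estimation.
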