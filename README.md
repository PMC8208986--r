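# leukoflow

Coupled hemodynamics and leukocyte adhesion in stenotic coronary
arteries, in R.

`leukoflow` is for cardiovascular-biomechanics researchers who want to
test the low-shear adhesion hypothesis against longitudinal imaging: it
simulates pulsatile incompressible blood flow in artery geometries built
from lumen contour frames (IVUS-style pullbacks) or idealized stenosis
specifications, extracts wall shear stress (WSS) on the lumen surface,
transports leukocyte concentration with a WSS-thresholded adhesion sink,
and correlates the predicted adhesion profile with the
baseline-to-follow-up change in lumen area. Because clinical pullback
datasets are rarely shareable, a synthetic-study generator emulates the
whole acquisition so every stage is testable end to end.

## Model in brief

* Flow: incompressible Navier–Stokes on a uniform staggered Cartesian
  grid; the lumen wall is a direct-forcing immersed boundary; a periodic
  triphasic waveform (period T = 0.8 s, mean bulk velocity 0.384 m/s by
  default) drives a parabolic inlet, with a radiative outlet.
* Transport: for each species *l*,
  `d rho_l/dt + U . grad(rho_l) = -R_l(WSS)` with
  `R_l = k_l(WSS) * rho_l`, where `k_l` is zero above the species
  threshold `WSS_th` (1.2 Pa for neutrophils) and ramps to `k_max` at
  zero shear. A uniform-concentration comparison mode records the sink
  without depleting the field.
* Averages: `<WSS>` is the time average at a wall point;
  `WSSbar(s) = (1/C) * integral <WSS> r dtheta` is the sectional
  average over each lumen contour of perimeter C.
* Analysis: `Delta A(s_j) = A_baseline - A_followup` (positive =
  narrowing), correlated with the adhesion profile `Rbar_l(s_j)` by a
  Pearson coefficient with population (1/N) moments.

See `vignettes/methods.Rmd` for the full account (numerics, design
decisions, limitations).

## Worked example

```r
library(leukoflow)

# a synthetic pullback: 40 frames at 0.5 mm, stenosis at s = 10 mm
spec  <- synthetic_study_spec(n_frames = 40, contour_noise = 0.02, seed = 1)
study <- synth_baseline(spec)

# a follow-up whose lumen loss tracks a known adhesion signal + noise
rbar <- exp(-((study$s - 10) / 4)^2)
spec_fu <- synthetic_study_spec(n_frames = 40, contour_noise = 0.02,
                                seed = 1, growth_gain = 0.8,
                                growth_noise = 0.05)
fup    <- synth_followup(study$frames, rbar, spec_fu, seed = 2)
series <- delta_lumen(study$frames, fup)
correlate_adhesion(rbar, series)
#> correlation rho = 0.9837 (N = 40)
#>   adhesion: mean 0.3543, sigma 0.3537 (1/N)
#>   delta A:  mean 0.2884, sigma 0.2988 (1/N)
summarize_change(series)   # mean and max lumen loss, mm^2
#> $mean_delta
#> [1] 0.2883527
#> $max_delta
#> [1] 0.904541
```

The recovered correlation (0.98) is the planted signal attenuated by the
growth noise; `mean_delta`/`max_delta` are the average and maximum lumen
loss along the vessel in mm². A full coupled run goes through
`run_simulation()` with a JSON configuration (see `?read_run_config`),
or the command line:

```sh
inst/cli/leukoflow simulate --config=run.json --out=results/ --seed=1
inst/cli/leukoflow validate            # fast analytic self-checks
```

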