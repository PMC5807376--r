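# posturePM

Principal movement analysis of postural control kinematics.

## What it does, and for whom

Balance research traditionally summarizes postural sway in a handful of
center-of-pressure variables, implicitly treating the postural control
system as a single unit. posturePM implements the alternative,
decomposition-based view for motion-capture data: all marker coordinates at
one instant form a *posture vector*, and principal component analysis of
the pooled, normalized posture vectors of a cohort splits whole-body sway
into orthogonal *principal movements* PM_k (eigenvectors PC_k, eigenvalues
EV_k, score series PP_k(t)). Per subject and component the package then
computes

- **rSTD_k** = 100 · σ(PP_k) / Σ_j σ(PP_j) — the component's share of the
  subject's overall postural motion,
- **N_k** — the number of zero crossings of the principal acceleration
  PA_k(t) = d²PP_k/dt², a measure of how *tightly* the neuro-muscular
  system controls the component (every crossing is a reversal of the net
  intervention), and
- **σ_k** — the SD of the time between successive zero crossings, a
  measure of how *regularly* it is controlled,

and tests age × gender group differences per component (type III two-way
ANOVA, partial η², observed power, Sidak-corrected simple effects). A
leave-one-subject-out cross-validation flags which components are robust
(eigenvector orientation change ≤ 15° across folds). It is aimed at
movement scientists analyzing quiet-stance or balance-task marker
recordings, and at methodologists who want a fully testable reference
implementation of these zero-crossing control endpoints.

Because the endpoints are novel, the package ships a synthetic
motion-capture cohort generator with planted orthonormal movement modes,
controllable oscillation regularity ("jitter"), measurement noise,
occlusion gaps, and configurable group effects — every pipeline stage is
validated by parameter recovery against this ground truth.

## Worked example

Simulate a small cohort under the default study conditions (two age
groups, 17 F / 8 M cells scaled down to 5 subjects per cell, 20 s trials
at 240 Hz, 37 markers, five planted modes, an age effect on mode 2:
control frequency ×0.9, jitter ×1.15) and run the full pipeline:

```r
library(posturePM)
cfg <- syntheticConfig(nSubjectsPerCell = 5, duration = 20, seed = 42)
res <- runPipeline(runConfig(synthetic = cfg, r = 9, seed = 42))

res$model
#> PCAModel: 9 principal movements in 108-dimensional posture space
#>   EV% : 57.76 25.23 11.30 3.42 2.27 0.00 0.00 0.00 0.00
#>   fitted on 20 subjects, 96000 pooled frames

res$crossval
#>   k    max_deg   mean_deg robust
#> 1 1  1.6538058  0.5017865   TRUE
#> 2 2  1.7038649  0.5465527   TRUE
#> 3 3  0.8004362  0.3540468   TRUE
#> 4 4  1.0200401  0.3208688   TRUE
#> 5 5  1.0227326  0.4038048   TRUE
#> 6 6 46.5313228 12.9566431  FALSE
#> ...

an <- res$stats$anova
an[an$p < 0.05 & an$effect != "age:gender", ]
#>  variable k effect     F df1 df2        p eta_p2 power pct_change
#>         N 2    age 29.72   1  16 5.32e-05  0.650 0.999     -11.01
#>     sigma 2    age 22.52   1  16 2.20e-04  0.585 0.994      46.66
#>  ...
```

Reading the output: the five planted modes are recovered as the first five
eigenvalues (the trailing components are measurement noise), the
cross-validation flags exactly those five as robust at the 15° threshold,
and the planted age effect appears where it was planted — the older group
crosses zero about 11% less often in PM 2 (lower N_2 = less tight
control) with a markedly larger crossing-interval SD (less regular
control). `pct_change` is relative to the younger (or male) group.
Results are also written as CSV tables plus a checksummed `manifest.json`
to the run's output directory.

Individual stages are exported (`generateCohort`, `fillGaps`,
`mirrorLeftFront`, `normalizeAndWeight`, `fitPCA`, `projectSubject`,
`computeKinematics`, `zeroCrossings`, `looCrossval`, `twoWayAnova`,
`filterSensitivitySweep`, ...) and documented; the methods vignette
(`vignettes/principal-movement-analysis.Rmd`) describes the model,
filtering choices, and the generator's assumptions.

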