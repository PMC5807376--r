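---
title: "Principal movement analysis of postural control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal movement analysis of postural control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturePM)
```

## The model

posturePM analyzes whole-body balance recordings by treating all marker
coordinates at one time instant as a single *posture vector* — a point in a
high-dimensional posture space. A trial of a subject standing in tandem
stance is then a trajectory through that space, and pooling the normalized
trajectories of a cohort and applying principal component analysis
decomposes the sway into orthogonal, one-dimensional whole-body movement
components, the *principal movements* (PMs). The eigenvector $PC_k$ is the
movement direction of $PM_k$; the projection of a subject's posture
trajectory onto $PC_k$ is the *principal position* series $PP_k(t)$, the
component's position coordinate over time.

Three families of endpoints are computed per subject and component:

* $rSTD_k = 100\,\sigma(PP_k) / \sum_j \sigma(PP_j)$ — the component's share
  of the subject's overall postural motion (population SD over the trial;
  the denominator spans the retained basis, so the values sum to 100%).
  Standard deviations, not variances, are used so the endpoint scales
  linearly with movement amplitude.
* $N_k$ — the number of zero crossings of the principal acceleration
  $PA_k(t) = \ddot{PP}_k(t)$ over the trial. In quiet stance the only
  forces that change the posture are gravity (constant) and muscle action,
  so $PA_k$ reflects the net neuro-muscular intervention along $PM_k$; each
  zero crossing is a reversal of that intervention, and $N_k$ measures how
  *tightly* the component is controlled.
* $\sigma_k$ — the standard deviation of the time between successive zero
  crossings of $PA_k$, measuring how *regularly* the component is
  controlled.

Group differences (age, gender, and their interaction) in these endpoints
are tested per component with type III two-way ANOVA, reported with partial
$\eta^2$, observed power, and percent change relative to the younger or
male group.

## Preprocessing chain

Each subject's marker data pass through:

1. **Gap filling.** Occlusion gaps are imputed by iterative low-rank
   reconstruction: linear interpolation initializes the missing entries,
   then the rank-$r$ PCA reconstruction of the frames × coordinates matrix
   replaces them until the imputed values change by less than `tol`
   (defaults: rank 10, tol $10^{-8}$ m, 100 iterations). Observed samples
   are never altered. Convergence is linear, so tight accuracy targets may
   need a larger iteration cap than the default.
2. **Marker selection.** Bilaterally symmetric markers are kept; asymmetric
   mid-segment markers (the single scapula marker `RBAK` in the full-body
   template) are dropped. Selection runs *before* mirroring because an
   asymmetric marker has no contralateral partner to swap with.
3. **Mirroring.** Trials performed with the left foot in front are
   reflected (lateral coordinate negated, left/right labels swapped) so
   every dataset describes a right-foot-front tandem stance.
4. **Normalization and weighting.** Each frame's posture vector is centered
   by the subject's own mean posture, divided by the subject's height
   (dimensionless coordinates), and each marker's three coordinates are
   multiplied by the marker's share of body mass. Mass shares follow
   Winter-style segment fractions (head+neck 0.081, trunk 0.497, each
   thigh 0.100, each shank 0.0465, each foot 0.0145, each upper arm 0.028,
   each forearm+hand 0.022), split equally among a segment's markers and
   renormalized to sum to 1 over the selected set. The linear weighting
   $w_i x_i$ is used; a kinetic-energy-motivated $\sqrt{w_i}$ variant
   exists in the literature but the linear form matches the verbal
   definition this package implements.
5. **Pooling.** Subjects are concatenated row-wise; because each subject is
   centered on their own mean posture, the pooled matrix has (numerically
   exactly) zero column means and is *not* re-centered before the PCA.

The PCA itself uses the singular value decomposition of the pooled matrix
(numerically preferable to forming the covariance), population ($1/N$)
variance convention, and a deterministic sign convention (the
largest-magnitude coefficient of each eigenvector is made positive), which
makes fits bit-reproducible. By default the first 9 components are retained
for reporting; the rSTD denominator spans the retained basis, and the
choice is recorded with the results.

## Kinematics and filtering

The score series are lowpass filtered with a 5th-order Butterworth at 7 Hz
before differentiation, because the dominant sway power sits around 2–3 Hz.
The Butterworth is applied zero-phase (forward–backward) — consistent with
choosing a linear-phase differentiator to avoid phase distortion — with
odd-reflection padding and endpoint anchoring so that a constant series
passes through exactly.

Derivatives use an order-50 linear-phase FIR lowpass differentiator
(passband edge 5 Hz, stopband edge 7 Hz), applied twice: positions →
velocities → accelerations. The design is weighted least squares on a
dense frequency grid for the type III (antisymmetric, even-order)
structure: the passband error is weighted by $1/\omega^4$ so the *percent*
error of the derivative stays flat across the sway band (measured: <0.5%
at 1–3 Hz for first derivatives, <1% for second derivatives), and the
stopband by $1/\omega^2$, concentrating suppression just above the
transition where residual signal power sits. With an order of 50 and a
2 Hz transition at a 240 Hz sampling rate, deep broadband stopband
attenuation is not achievable; the upstream 7 Hz Butterworth carries most
of the broadband noise rejection. The convolution output is shifted by the
group delay (25 samples), so derivatives are time-aligned with the input;
the 25 incomplete samples at each edge are `NA`.

Each trial's first and last 0.5 s are trimmed before computing crossings —
this covers both filter transients and the differentiator edges — and the
window length is always reported alongside $N_k$ (an 80 s trial yields a
79 s window). Zero crossings are sign changes between consecutive non-zero
samples; runs of exact zeros bracketed by opposite signs collapse to a
single crossing at the run center (preventing double counts in noise-free
synthetic signals), and crossing times are interpolated linearly between
the bracketing samples. $\sigma_k$ uses the sample ($n-1$) SD convention
and requires at least three crossings, otherwise it is `NaN`.

## Robustness of the decomposition

Leave-one-subject-out cross-validation refits the PCA once per held-out
subject and measures the sign-invariant angle between each fold eigenvector
and the full-data eigenvector ($\arccos |u \cdot v|$; eigenvector sign is
arbitrary). A component is robust when its worst-case angle across folds
stays at or below 15°. Components are matched by eigenvalue rank rather
than re-paired by similarity, so eigenvalue degeneracy — where two
components' variances are so close that their eigenvectors can rotate
freely — shows up as large angles, which is exactly what the diagnostic
should flag. Fold bases are computed by eigendecomposition of the pooled
cross-product matrix minus the held-out subject's contribution; this is
numerically equivalent to the SVD route (verified in the tests) and makes
the 50-fold analysis cheap.

## Group statistics

The ANOVA uses sum-to-zero effect coding and type III sums of squares,
which is well-defined for the unbalanced gender cells (17 women / 8 men per
age group in the emulated design; $df_2 = n - 4$). Partial
$\eta_p^2 = SS_e/(SS_e + SS_{err})$, and observed power comes from the
noncentral F distribution with $\lambda = F \cdot df_1$ at $\alpha = 0.05$ —
the convention of the common GLM packages. Normality is checked per cell
with Shapiro–Wilk and the Lilliefors-corrected Kolmogorov–Smirnov test
(plain KS with estimated parameters would be anticonservative), and
variance homogeneity with the mean-centered Levene test. When the
interaction is significant, the post-hoc family is the four pairwise
simple-effects comparisons of the 2×2 design (age within each gender,
gender within each age), Sidak-corrected with $m = 4$; the family size is
recorded in the output. Missing endpoint values are excluded casewise with
logged counts. No correction is applied across the variable × component
families.

## The synthetic cohort generator

Because the endpoints are novel, every stage is validated by parameter
recovery on synthetic cohorts with planted ground truth. The generator
inverts the preprocessing chain: orthonormal modes (Gram–Schmidt on seeded
Gaussian vectors) are planted in the weighted, height-normalized posture
space, driven by oscillatory score series, mapped back to lab coordinates
per subject (un-weight, un-normalize by the subject's height, add a
plausible standing posture scaled to that height), and then degraded with
measurement noise and occlusion gaps. Modes are planted only on the markers
the default policy retains, so the planted basis is exactly recoverable.
Left-foot-front subjects are stored mirrored, exercising the mirroring
stage.

A score series is $s(t) = A\sin\phi(t)$ with a uniformly random initial
phase, where the phase advances by $\pi$ per half-cycle and half-cycle
durations are drawn from a mean-preserving log-normal with mean $1/(2f)$
and relative SD equal to the *jitter* parameter. This gives direct,
independent control of the endpoints: the acceleration of a jitter-free
mode crosses zero $2fT$ times over a window of length $T$, and the
crossing-interval SD grows directly with jitter ($\approx$ jitter/2f).
Defaults emulate the study conditions: 50 subjects (17 F / 8 M per age
group), 80 s at 240 Hz, 37 markers, five modes whose amplitudes follow the
square roots of a realistic eigenvalue spectrum (53:25:11:3:2) and whose
dominant frequencies lie in the 2–3 Hz band, 1 mm marker noise, and an age
effect on mode 2: the older group's control frequency ×0.9 and jitter
×1.15, matching the direction of the reported age differences (lower
$N_2$, higher $\sigma_2$) with round default magnitudes.

Choices the data do not pin down, fixed once here: between-subject
log-normal variability of amplitude (CV 0.10) and frequency (CV 0.05), so
subject-level endpoints have realistic between-subject variance for the
ANOVA stage; heights uniform on [1.55, 1.90] m; gaps injected as
geometric-length runs (mean 0.25 s) per marker; baseline jitter 0.1 per
mode. The modes are geometric, not biomechanical — there is no
musculoskeletal or feedback-control simulation — so passing recovery tests
demonstrates the correctness of the analysis chain, not the physiological
validity of the endpoints on real data. Real postural sway is broadband
and non-stationary, marker noise can be correlated, and real eigenvalue
spectra need not be as well separated as the planted ones.

Two cohort flavors appear in the validation suite. The *study-conditions*
cohort uses the defaults above. The *basis-recovery* cohort used to verify
eigenvector recovery is deliberately clean: jitter-free modes at
well-separated frequencies and no between-subject parameter scatter, so
the only discrepancy between planted and recovered bases is the sampling
cross-covariance of finite trials. With jittered, spectrally overlapping
scores the empirical mode cross-correlations rotate the eigenvectors by a
few degrees even without measurement noise — a property of any
finite-sample PCA, not an implementation error — and the clean cohort
keeps that nuisance below the tolerance being tested.

Simulation problem sizes in the test-suite: detection-rate simulations use
20 s trials, 8 markers and 3 modes (50 subjects as in the emulated
design); recovery and robustness checks use 20 s trials with the full
37-marker set. These sizes keep the whole validation suite comfortably
reproducible on a laptop while leaving every estimate's expected value
unchanged.

## Numerical and degenerate-input conventions

* Rank-deficient pooled matrices retain only the nonzero components, with
  a warning; requesting more components than the rank is not an error.
* All-zero score series give `NaN` rSTD with a warning; components whose
  acceleration never crosses zero report $N = 0$ and `NaN` $\sigma$.
* Cross-validation folds with rank below $r$ report 90° for the missing
  components (maximally non-robust) with a warning.
* Constant series pass the Butterworth unchanged (exact DC anchoring);
  differentiator edges are `NA` rather than silently inaccurate values.
* Exact-zero ties in the crossing detector follow the run-collapse rule
  above; this is the only place ties can occur.

## Known limitations

* The decomposition is linear; PMs form a coordinate system and individual
  components should be interpreted jointly.
* $N_k$ and $\sigma_k$ are computed from doubly differentiated data and
  inherit sensitivity to the filter settings; `filterSensitivitySweep()`
  exists precisely to check that group effects are stable across a grid of
  settings before interpreting them.
* C3D input is not supported; marker data are exchanged as long-format CSV
  (`frame,label,x,y,z` with `# key: value` metadata headers, meters).
* The crossing counts are reported per valid window, not normalized per
  second; compare only trials of equal duration.
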