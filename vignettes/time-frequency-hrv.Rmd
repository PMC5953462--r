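---
title: "Time-frequency HRV analysis of exercise testing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency HRV analysis of exercise testing: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfhrv)
```

## The problem

Heart rate variability (HRV) during a graded exercise test is strongly
non-stationary: the RR series falls monotonically with workload and
rebounds during recovery, while the respiratory rate — the carrier of the
vagally mediated high-frequency (HF) component — can climb from ~0.25 Hz
at rest to 0.7 Hz near peak effort, far above the classic 0.15–0.4 Hz HF
band. Classic stationary spectral indices are therefore unreliable under
exertion. `tfhrv` implements a time-frequency pipeline that (i) estimates
the instantaneous spectrum of the RR series with a smoothed pseudo
Wigner-Ville distribution (SPWVD), (ii) tracks the instantaneous
respiratory frequency from the R-peak amplitude modulation of the ECG
(ECG-derived respiration, EDR) and re-centres the HF band on it, and
(iii) summarises the resulting marker series into a per-patient feature
vector that feeds an imbalanced-class classification workflow
(standardisation, ADASYN oversampling, ReliefF + floating-LDA feature
selection, repeated cross-validated LDA). The motivating application is
risk stratification in Brugada syndrome, where symptomatic status is the
class label, but every stage is generic.

## Signal model and preprocessing

Beat annotations (times, RR intervals, R amplitudes) are the input; QRS
detection is out of scope. RR and amplitude channels are interpolated
with a **natural cubic spline** and evaluated on a **4 Hz** grid clipped
to the support of the beats (no extrapolation). The RR value of a beat is
anchored at the time of the beat that *ends* the interval; the
interval-end convention is stated because nothing in the data fixes it.
Natural boundary conditions mean the interpolant is exact on polynomials
of degree ≤ 1 globally and reproduces smooth signals to high accuracy in
the interior, but not cubics near the free ends — the property tests are
written accordingly.

The RR series is high-pass filtered at **0.03 Hz** and the EDR band-pass
filtered to **0.15–0.7 Hz**, both with 4th-order Butterworth filters
applied forward and backward. R's `signal::filtfilt` does no edge
handling, so the package implements the zero-phase pass itself:
odd-reflective padding of three filter lengths, steady-state initial
conditions for each pass, and — because a causal cascade is only
approximately symmetric under time reversal — the two pass orders are
averaged, which makes the operator *exactly* time-reversal symmetric
without changing its magnitude response.

Manual beat editing is not reproducible, so an optional automatic rule
(`correct_rr_artifacts()`, off by default) replaces RR values deviating
more than 30 % from their 11-beat local median.

## The smoothed pseudo Wigner-Ville distribution

The Wigner-Ville distribution of the analytic signal has excellent
time-frequency resolution but severe cross-terms. The SPWVD filters the
ambiguity function $A(\tau, \nu)$ with a radially compressed exponential
kernel before transforming to the time-frequency plane:

$$\Psi(\tau,\nu) = \exp\!\left\{-\pi\left[\left(\frac{\nu}{\nu_0}\right)^2
  + (\tau\,\tau_0)^2\right]^{2\lambda}\right\},\qquad
  C(t,f) = \iint \Psi A\, e^{j2\pi(t\nu - \tau f)}\,d\nu\,d\tau .$$

Parameter choices, with units made explicit because they matter:

* `nu0 = 0.06` (Hz) is the doppler half-width; its reciprocal sets the
  **temporal smoothing scale ≈ 16.7 s**.
* `tau0 = 0.03` (Hz) is parameterised as the *reciprocal* of the lag
  window scale, so it directly sets the **spectral resolution ≈ 0.03 Hz**
  (equivalent-width measures computed by `kernel_resolution()` give
  23 s / 0.041 Hz). Had `tau0` been a lag in seconds, the lag window
  would not survive a single 4 Hz sample and the transform would have no
  frequency resolution at all; the reciprocal reading is the only one
  consistent with both stated resolutions.
* `lambda = 0.3` controls the roll-off; it is exposed in
  `spwvd_kernel()` because different values trade cross-term suppression
  against resolution.

Discretisation choices: the SPWVD is computed on the analytic extension
of the signal (the adaptive HF band can reach 0.825 Hz at 4 Hz sampling,
so negative-frequency images must be suppressed); the lag support is
truncated where the kernel's lag factor falls below $10^{-4}$
(±81.7 s at the defaults); the frequency grid spans 0–1 Hz in 0.005 Hz
steps (oversampled relative to the kernel resolution); the signal is
zero-padded at the recording boundaries and all samples within one lag
half-support (≈ 41 s) of either edge are flagged in a **margin mask**
that every downstream average respects. The kernel is applied in the
ambiguity domain exactly as written — not as a separable
time/frequency-window approximation — and the test suite holds the FFT
implementation to $10^{-6}$ relative agreement with a literal
DFT-matrix evaluation of the defining sums.

Band powers are per-time trapezoidal integrals over the band, with
linear interpolation at band edges. Negative local excursions (inherent
to quadratic distributions) are *kept*, not clipped; instants where the
total power is non-positive are masked and counted rather than patched.

## Respiratory tracking and the adaptive HF band

The instantaneous respiratory frequency is the constrained spectral peak
of the EDR's SPWVD. The first pick searches the standard HF band
(0.15–0.4 Hz); each subsequent pick searches only
$[f_r(t_k)-\delta,\,f_r(t_k)+\delta]$ with $\delta = 0.01$ Hz, where the
reference $f_r$ is an exponential average of previous picks with
forgetting factor $\beta = 0.7$. The 0.25 s pick spacing and
$\delta = 0.01$ Hz together bound the trackable slew rate at 0.04 Hz/s,
ample for real breathing. Discrete argmax picks are refined by parabolic
interpolation (the grid is 0.005 Hz; tracking a chirp benefits
measurably). When the constrained pick sits on a window edge for more
than 10 consecutive samples a diagnostic warning is raised; no
re-initialisation is attempted because no principled reset exists.

The HF band is $[f_r(t) - 0.125,\ f_r(t) + 0.125]$ Hz, taken literally:
when $f_r < 0.275$ Hz it overlaps the fixed LF band (0.04–0.15 Hz).
The overlap is reported (`overlaps_lf` attribute, a message) rather than
silently corrected, with an optional `clip_lf` to pin the lower edge at
0.15 Hz — which of the two the original analysis used is not
determinable, so the literal reading is the default.

## Windows, features and univariate comparison

Marker series LF, HF, TP = LF + HF, LFnu = 100·LF/TP,
HFnu = 100·HF/TP and LFHF = LF/HF are averaged over twelve one-minute
windows: WU1–WU2 from warm-up start, EX1–EX3 from exercise start, PE
anchored *backwards* from the peak-effort instant (so inter-patient
comparisons are synchronised at the peak), AR1–AR3 from the peak and
PR1–PR3 from the end of active recovery. Tests shorter than 4 min of
exercise make EX3 and PE overlap; that is allowed with a warning.
Windows with more than half their samples masked (kernel margins,
non-positive TP) are flagged; fully masked windows are an error. Five
markers × twelve windows give the canonical 60 features
(`feature_names()`), named `<MARKER>_<WINDOW>` so selected sets are
comparable as strings. Group differences per feature use the two-sided
Mann-Whitney U test (exact enumeration when both groups ≤ 8 and untied,
tie-corrected normal approximation otherwise), significance at p < 0.05.

## Conditioning, selection and classification

**Standardisation** is z-scoring with the sample SD (n − 1); it is
applied to the full cohort before the train/test split, reproducing the
analysed workflow's order of operations even though it leaks test-set
moments — `standardize_features(test, params = ...)` supports the strict
alternative.

**Balancing**: ADASYN allocates a synthetic budget G across minority
samples proportionally to the majority fraction among each sample's k = 5
nearest neighbours (largest-remainder rounding makes the allocation sum
exactly to G), then interpolates convexly toward random minority
neighbours. Since individual runs are random, 50 realizations are
averaged element-wise at matched generation index under a fixed
minority-visit order — the only convention under which averaging
realizations is well defined. Averaging keeps every synthetic point
inside the minority convex hull and contracts the interpolation noise
roughly as 1/R. The default budget is majority − minority; the
study-reproduction configuration pins G = 55 (24 → 79 symptomatic
against 81, 160 rows in total).

**Selection** is two-step. The ReliefF filter runs on 50 stratified 60 %
subsamples of the training split, averaging weights over neighbour
counts k = 10…19 within each subsample and taking the per-feature median
across subsamples; the top 75 % (⌈0.75·M⌉, i.e. 45 of 60) survive, ties
at the boundary broken by original feature order. The wrapper then runs
50 realizations of a sequential floating forward selection (conditional
backward exclusion, never of the feature just added) with LDA as the
black box, scored by AUC on a stratified 25 % inner holdout; an
add/remove must improve AUC by more than 1e-4 and iterations are capped
at twice the feature count to prevent cycling. Features appearing more
than L times form nested candidate sets; each distinct set is scored by
repeated-CV mean AUC with shared partitions across L, and the chosen L
maximises AUC, resolving ties within 0.005 towards the fewest features.

**Classification**: the LDA is a hand-written regularised Fisher
discriminant — pooled within-class covariance plus a scalar ridge of
1e-6 × mean diagonal (needed with ~22 features on 119 training rows),
scores along $\Sigma^{-1}(\mu_1 - \mu_0)$, equal priors after balancing.
Evaluation uses stratified 5-fold CV repeated 10 times; each repeat
pools its out-of-fold scores into one ROC (via pROC), and the mean ROC
vertically averages TPR on a 101-point FPR grid. The operating point
maximises Youden's J. Because the literature rarely states whether
reported Se/Sp are test-set values at a training-derived threshold or
re-optimised on test scores, `run_study()` reports both.

## The synthetic generator: what it does and does not emulate

`simulate_recording()` produces a beat series
RR(t) = trend + A_LF·sin(2π·0.1·t) + A_HF·sin(2π∫f_r) + noise, with a
warm-up plateau (default 2 min at 800 ms), a linear exercise decline
(8 min at −40 ms/min), an exponential recovery rebound (τ = 90 s over
3 + 3 min), white per-beat RR noise (SD 5 ms), and R amplitudes
modulated at the respiratory phase (depth 0.2, noise SD 0.02). Beats are
placed by cumulative-RR accumulation — simpler than integral
pulse-frequency modulation and adequate for band-power ground truth —
and the HF phase is the *integral* of the programmed trajectory, so the
instantaneous HF frequency equals that trajectory exactly. The default
respiratory trajectory rises 0.25 → 0.55 Hz across exercise and falls
back through recovery, staying within the physiological 0.15–0.7 Hz.
Not emulated: ECG waveforms, respiratory mechanics, ectopy (an injector
can be simulated by editing beats), non-sinusoidal respiration,
LF/HF amplitude non-stationarity. Passing tests therefore validate the
numerical chain, not the physiology of real recordings.

`simulate_cohort()` draws Gaussian class-conditional features with unit
within-class variance and a mean shift on planted informative columns,
under the study-shaped 24/81 imbalance by default; the closed-form
single-feature AUC $\Phi(d/\sqrt 2)$ anchors the classifier checks.

## Validation problem sizes

The test suite and acceptance script run at deliberate desk scales: SPWVD
oracle agreement on 512-sample signals (the shortest the 2-minute
precondition admits), tone/chirp recordings of 8–16 minutes, the
closed-form AUC check at 300 + 300 patients, and the planted-feature
recovery experiment on an 80/120-patient, 40-feature cohort with five
informative columns at a 1.0 SD shift. The recovery cohort is larger
than the motivating study on purpose: with only 24 minority patients, no
selection procedure can reliably distinguish five planted columns from
chance-correlated noise, and a recovery assertion at that size would
test the cohort, not the code. Jaccard overlap ≥ 0.6 between the
selected and planted sets is required at the stated design.

## Known limitations

* The SPWVD is O(N · M) in memory (lag support M = 327 columns); hour-long
  recordings should be processed in segments.
* The respiratory tracker follows a single spectral ridge; biphasic or
  multi-harmonic breathing will confuse it (the edge-run diagnostic
  flags, but cannot fix, a lost track).
* Standardising before the split and oversampling before the split both
  leak information across the evaluation boundary; they are retained as
  defaults because they reproduce the analysed workflow, and the strict
  variants are available.
* Window means near recording edges rest on few unmasked samples (the
  kernel margin covers ~41 s); WU1 and PR3 are routinely flagged.
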