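---
title: "Methods: hyperarousal features of sleep architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperarousal features of sleep architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the choices made where the
design was genuinely open.

## The analysis problem

Chronic insomnia is hypothesized to involve *hyperarousal*: cortical
activity during sleep that resembles wakefulness. Overnight
polysomnography (PSG) gives several complementary windows on this — how
often sleep collapses back into wake (stage-transition dynamics), how much
alpha-range power intrudes into Wake and light sleep (spectral features),
how stable the sleep-protective spindle machinery is (spindle density and
dispersion), and how "wake-like" short EEG segments look to a classifier
trained to tell wake from sleep (the Wake EEG Similarity Index, WESI).
`sleeparch` computes all four families from C3/C4 EEG plus a 30-s AASM
hypnogram and compares them between an insomnia and a non-insomnia group
with mixed-effects models.

## Preprocessing

All features consume one harmonized signal. The fixed order —
contralateral mastoid re-reference (C3−M2, C4−M1), resample to 200 Hz,
0.5 Hz high-pass, 50 Hz band limit — is enforced by making
`preprocess_recording()` the only public entry point that sets the
`preprocessed` flag the feature modules require.

* **Resampling** uses polyphase rational-rate resampling with a
  Kaiser-window low-pass FIR (60 dB stopband, cutoff at 0.9 × the smaller
  Nyquist, transition width 20% of cutoff). Up-sampling therefore
  introduces no content above the original Nyquist frequency.
* **Filtering** is zero-phase throughout: symmetric (linear-phase) FIR
  taps applied by FFT convolution with exact group-delay compensation, so
  event timestamps (spindle peaks, SO zero-crossings) are never shifted.
  The source method does not state phase handling; zero-phase keeps
  timestamps aligned across modules. FIR orders follow the standard Kaiser
  design formula from the requested attenuation (60 dB) and transition
  width (equal to the cutoff for the high-pass); both are configurable.
* **Artifact mask**: each 3-s segment (grid anchored at lights-off,
  partial trailing segment dropped) is flagged when its RMS amplitude is
  ≤ 1 µV (flat) or ≥ 250 µV (gross artifact). Masking is deterministic,
  idempotent, and independent of the hypnogram. No whole-recording
  rejection is performed on the artifact fraction; it is logged.

## Spectral features

Band powers come from DPSS multitaper spectra. The method's source fixes
the window grid (2-s windows, 1-s hop) but not the taper parameters; the
default is NW = 2 with K = 3 tapers (a 1 Hz half-bandwidth on a 2-s
window, common EEG practice), configurable via `nw` and `k`. Band edges
are half-open `[low, high)` except the top of beta, so adjacent bands
never double-count a frequency bin.

One stated ambiguity: powers are "summed across C3 and C4" yet relative
power is defined "per channel". We resolve it by summing the two central
channels first and computing a single relative power per 30-s window (the
summed pair treated as one derivation channel); 2-s windows are assigned
to the 30-s epoch containing their start, so an interior epoch aggregates
up to 30 windows. Stage features are the natural log of the mean relative
power over the stage's epochs; the log base is a monotone rescaling and
immaterial to inference. Epochs with no valid (artifact-free) window, and
stages never scored, yield missing features which are excluded from group
models.

## Spindle and slow-oscillation detection

The detector follows the Luna-style wavelet recipe: a 13.5 Hz complex
Morlet (7 cycles — the width is not stated in the source; 7 cycles is the
Luna-compatible default, configurable), magnitude smoothed with a 0.1-s
moving average, thresholds expressed as multiples of the mean over all
accepted N2 epochs.

Two numerical decisions deserve emphasis:

* **Thresholds act on power** (the squared smoothed magnitude). The
  source's wording mixes "magnitude" and "power", but its flank rule is
  stated on power; using power for both the 4.5× core and the 2× flank is
  the coherent reading, and the only one under which bursts at five times
  the spindle-band background are reliably detectable with the printed
  multipliers (the package's own detector-recall suite verifies this).
* **The flank statistic is the mean** over the 0.5-s window centred on the
  core, not the minimum. The strict minimum necessarily fails for any
  burst shorter than ~0.8 s, because the window then reaches into
  background on both sides regardless of burst amplitude. The stricter
  variant remains available as `flank_stat = "min"`.

Event boundaries are expanded outward to the 2× power contour; candidates
separated by ≤ 0.5 s are merged; merged events longer than 3 s are
rejected. Events are classified fast (dominant frequency ≥ 13 Hz) vs slow
(< 13 Hz) by the periodogram peak of the event segment within 9–16 Hz —
the source defines the bands but not the classifier.

SOs are intervals between successive positive-to-negative zero-crossings
of the 4.5 Hz low-passed signal with duration in [0.8, 2] s; crossings are
extracted on the full filtered signal and SOs fully inside accepted N2
epochs are retained. A spindle contributes a phase only when its peak lies
inside a same-channel SO; the phase is the linear map
`360°·(peak − SO start)/(SO duration)`, and per-subject aggregation uses
the circular mean (the source reports group phase differences in degrees
without stating the per-subject aggregator). The per-epoch delta-power
artifact rule (reject epochs > 2.5 × the mean over a centred 15-epoch
window, strict inequality, window truncated at record edges) runs before
detection.

## WESI

Relative band powers are computed per non-overlapping 3-s window with the
same multitaper estimator (a single 3-s window per segment; the source
does not state how these powers were computed) and the same channel-sum
convention. Feature construction follows the printed step order: logit
transform (powers clipped to `[1e-6, 1 − 1e-6]` first — degenerate windows
are otherwise unusable), z-scoring with constants estimated from the
training split only, then interaction/square terms computed from the
z-scored logits and not re-standardized.

The loss is a *Huberized logistic deviance*: with margin
`z = (2y − 1)·η` and logistic deviance `ℓ(z) = log(1 + e^{−z})`, each
window contributes `H_δ(ℓ(z))` where `H_δ` is the Huber function
(quadratic below δ = 3, linear beyond). This is convex (an increasing
convex function of a convex function), reduces the influence of windows
whose labels grossly contradict their spectra — expected, since brief
wake-like segments occur inside scored sleep — and reduces to a smooth
approximation of the usual log-loss for well-classified windows. The exact
objective of the source is not written; `loss = "logistic"` switches to
the plain log-loss, and the test suite verifies that route against
`glmnet` as an independent oracle. The penalty is
`λ·Σ|β_j|` (intercept unpenalized) on the per-observation-mean loss, with
λ = 0.1 on the standardized scale. Optimization uses FISTA with
backtracking; convergence tolerance 1e-9 on the relative objective change,
at most 3000 iterations.

The 80/20 split is subject-wise by default — the source says only "a
random sample of 80% of the data", and window-wise splitting would leak
within-subject information between train and test; `split_by = "window"`
is available. Determinism is guaranteed given the split seed, and
removing the held-out rows entirely reproduces the fitted coefficients
bit-for-bit (the no-leakage invariant in the test suite).

Per-subject stage means are analysed on the logit scale. The linear-scale
summary applies a second-order (delta-method) correction
`E[σ(X)] ≈ σ(µ) + ½·Var(X)·σ″(µ)` with the curvature computed by central
finite differences (step 1e-3); the companion bootstrap validator
resamples subjects 10,000 times and reports the absolute difference. CI
endpoints are mapped the same way and clamped to (0, 1); zero-variance
input returns the plain back-transform with a zero-width CI; fewer than
two finite values triggers a warning fallback.

## Group statistics

Three nested fixed-effect structures are fit by maximum likelihood (never
REML, since the likelihood-ratio tests compare fixed effects):
`feature ~ age_c*sex`, `+ group`, and `age_c*sex*group`, each with random
intercepts for subject and site. Age is centred at 50 years. With one
observation per subject the Gaussian subject intercept and the residual
form an exact variance ridge — the marginal covariance is
`(σ²_subj + σ²_res)·I` — so the likelihood is flat along it;
`fit_model_triplet()` fits the identifiable reparameterization and records
the subject variance as collapsed into the residual. All log-likelihoods,
and hence all LRTs, are unchanged. For the binomial hurdle parts a
single-draw-per-subject intercept is genuinely unidentifiable and is
dropped by default (`include_subject_re = TRUE` restores it). A site
random effect requires ≥ 2 sites; otherwise the model degrades to `lm`
/ `glm` with a recorded note.

FDR adjustment is Benjamini–Hochberg computed as if the full exploratory
family had been tested (spectral 180, spindle 14, WESI 10, transition 25):
absent tests enter as placeholders at p = 1, which is conservative.
Transition counts are routed by prevalence — < 1.5% of recordings:
not modelled; 1.5–98.5%: hurdle; > 98.5%: a single binomial GLMM. The
hurdle's count part models the transition count as binomial out of the
recording's total transitions leaving the source stage with a logit link;
the source's "logistic function as the link" wording is ambiguous between
this and a truncated-count model, and the binomial reading keeps both
parts in one family. The combined null-vs-main LRT adds both parts
(df = 2). Per-coefficient significance is a two-sided Wald z-test at 0.05
(the source does not name the per-coefficient test). A transition is
declared significant only when the FDR-adjusted LRT p-value is < 0.05
*and* at least one insomnia coefficient (zero- or count-part) is
individually significant — both conditions are required.

## The synthetic cohort generator

The source provides no generative model; everything here is
artifact-internal and should not be read as a claim about the original
datasets.

* **Hypnograms** are first-order Markov chains over (W, N1, N2, N3, R)
  starting in W, with group base matrices calibrated so whole-night
  descriptives land near the published cohort (control sleep efficiency
  ≈ 92%, insomnia ≈ 63%, insomnia WASO and sleep latency far beyond the
  30-min/20-min objective screening thresholds). Because a
  time-homogeneous chain cannot jointly produce a ~75-min sleep-onset
  latency and a realistic WASO, each night prepends a lognormal
  sleep-onset wake bout (median 55 min insomnia / 8 min control, σ_log
  0.55/0.5). Per-subject heterogeneity is multiplicative lognormal jitter
  (σ = 0.10) on the matrix entries, renormalized.
* **EEG** is a sum of four band-limited Gaussian noise processes whose
  per-epoch variances are scaled to the stage's band fractions (total
  background 30 µV RMS) — chosen over autoregressive models because it
  gives direct control of relative band power, the quantity under test.
  Epoch boundaries switch gains discretely; the resulting broadband edge
  leakage is negligible at 30-s epochs.
* **Events**: N2 epochs receive Poisson numbers of 13.5 Hz Hann-windowed
  spindle bursts (0.5–1.5 s; default peak amplitude 45 µV = 5 × the
  spindle-band background RMS) and slow oscillations (one full
  negative-going sine cycle, 1.0–1.6 s, 75 µV). When coupled, a spindle's
  peak sits at the requested phase of a host SO; each SO hosts at most one
  spindle and planted events keep ≥ 0.7 s clearance so the detector's
  0.5-s merge rule cannot fuse distinct planted events — otherwise
  recall/precision against ground truth would be ill-defined.
* **Group effects** are planted only through the documented effect sizes
  (to-Wake probability shift, Wake/N1 relative-alpha shifts, spindle
  density deficit, WESI logit shift). A configuration with all effects
  zero is a true null cohort: both groups are drawn from the control law,
  including the sleep-onset bout.
* **Between-subject spreads** the source never states were fixed once from
  typical sleep-EEG ranges before any acceptance run: Wake relative alpha
  SD 0.06, spindle density SD 0.8 min⁻¹ (population mean 2.4), WESI
  logit-scale SD 0.3 (subject stage-means aggregate hundreds of windows,
  so their spread is far smaller than single-window variability).
* **The fast path** (`simulate_feature_cohort()`, and
  `run_pipeline(signal = FALSE)`) draws per-subject *features* from this
  same generative law without synthesizing EEG. Statistical calibration
  over hundreds of cohorts is only feasible this way; it exercises the
  full modelling stack but not the detectors, which are tested on
  signal-level fixtures separately.

What the generator does **not** emulate: physiological EEG morphology
(K-complexes, eye movements, EMG, 1/f aperiodic structure), NREM–REM
cycling, first-night effects, apnea. A green end-to-end test therefore
establishes that the pipeline recovers effects *of the planted kind at the
planted SNR*, not that it would behave identically on clinical data.

## Known limitations

* The published effect sizes and per-dataset WESI accuracies/AUCs are not
  reproduction targets: they require ~3,165 clinical recordings that are
  not available. Directions and structural counts are verified instead.
* The hurdle likelihood-ratio test is conservative in the calibration
  suite (rejection below nominal under the null); group contrasts on
  transition counts are therefore, if anything, understated.
* Band-edge leakage of the 2-s multitaper window caps extreme relative
  powers (a stage synthesized at alpha fraction 0.97 measures ≈ 0.86);
  relative comparisons between groups are unaffected.
* EDF support covers continuous EDF with one-second records — the subset
  the generator writes; EDF+ annotations, discontinuous records and
  per-signal sampling-rate mixtures are out of scope.
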