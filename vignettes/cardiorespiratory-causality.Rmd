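---
title: "Temporal causality analysis of cardiorespiratory signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal causality analysis of cardiorespiratory signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocause)
```

## The problem

Breathing and heart rhythm are coupled: inspiration transiently accelerates
the heart (respiratory sinus arrhythmia, RSA), breathing depth modulates
the magnitude of that acceleration, and posture shifts the autonomic
balance that mediates both. `cardiocause` quantifies these couplings as
*directed, parameterized links* estimated from a two-channel recording —
a single-lead ECG and an uncalibrated thoracic-impedance (impedance
pneumography) signal, both at 250 Hz, with one ~5-minute session per
posture (supine, standing).

From the raw channels the package derives three representations per
recording:

1. a 25 Hz signal set — tidal-volume-related impedance (TV),
   instantaneous respiratory rate (iRR) and instantaneous heart rate
   (iHR);
2. the same set further decimated to 2.5 Hz, for spectral analysis;
3. beat-by-beat sequences — RR-interval lengths, impedance amplitude at
   each R peak, iRR at each R peak and a breathing-phase code
   (+1 inspiration, −1 expiration, 0 pause).

Four causal frameworks are then applied: time-domain pairwise-conditional
Granger causality (representation 1), spectral Granger causality
(representation 2), an extended Granger variant with a zero-lag term, and
additive-noise (TiMINo-style) causal discovery (both on representation 3).
Cohort-level summaries, rank tests and random-forest recursive feature
elimination sit on top.

## Models and statistics

### G-causality and prediction improvement

For channels $x$ and $y$ and model order $p$, the G-causality of $x$ on
$y$ is

$$\mathrm{GC}_{x \to y, p} = \ln
  \frac{\operatorname{Var}(\hat y \mid y^-, z^-)}
       {\operatorname{Var}(\hat y \mid y^-, x^-, z^-)},$$

the log ratio of one-step prediction-error variances of two nested
least-squares models, where $z^-$ is the past of every remaining channel
(the *pairwise-conditional* convention). Nesting guarantees the estimate
is nonnegative up to round-off; small negative finite-sample values are
clipped to zero. Significance is the F test on the nested residual sums
of squares with $p$ added regressors; a link is retained at $\alpha =
0.05$ per link, without multiple-testing correction (a Bonferroni switch
exists but is off, so that cohort NA counts mean the same thing as in the
study design this mirrors). The prediction improvement

$$\mathrm{PI} = 100 \cdot e^{\mathrm{GC}} - 100 \ [\%]$$

restates a link as the per-cent variance reduction gained by adding the
cause's past: PI$(0) = 0$, PI$(\ln 2) = 100\%$.

The VAR order is chosen per recording by BIC over `1:max_order`, with all
candidate orders scored on the common estimation sample. The caps are 20
at 25 Hz and 10 at 2.5 Hz — about 0.8 s and 4 s of lookback — a
tractability bound on smooth oversampled series, stated in
`pipeline_config()`.

### Spectral causality

The spectral variant factorizes the fitted bivariate VAR's transfer
function $H(\omega)$, orthogonalizes the instantaneous innovation
correlation, and reports at each frequency the log ratio of the effect
channel's total power to its intrinsic part. Geweke's integral identity —
the average of the spectrum over $[0, f_s/2]$ equals the time-domain
G-causality of the same model — is verified in the test suite to 5% on a
bank of simulated VARs, and holds to ~0.2% in practice. The peak
amplitude and its frequency are the reported link parameters; ties
resolve to the lowest frequency, and the grid is 256 uniform points on
$(0, f_s/2]$.

Two design choices deserve a note. First, spectral links are estimated
*bivariately* (pairwise, unconditional): the conditional spectral
decomposition needs a second joint model and its numerical failure modes
did not seem worth the cost for three channels whose conditional and
bivariate answers differ little here; the time-domain estimates remain
fully conditional. Second, smooth interpolated-rate series occasionally
give marginally explosive high-order OLS VARs; `spectral_gc()` then steps
the order down to the largest stable fit rather than failing the subject.
Residual negative spectral values (round-off) are clipped and the clip
magnitude is bounded at $10^{-8}$ in tests.

### Extended (zero-lag) causality on beat sequences

Cardiorespiratory effects can complete within a single heart beat, which
lagged-only models cannot see. On beat-indexed variables the restricted
model uses lags 1..4 of the effect (plus conditioning variables); the full
model adds lags 0..4 of the cause; the F test counts the five added
regressors. The maximum lag of 4 beats covers roughly half to one
breathing cycle at rest. Beat sequences are modeled on beat index, not
resampled to uniform time. The companion `instantaneous_effect_matrix()`
reports the zero-lag coefficient's t test per ordered pair; instantaneous
coupling is direction-ambiguous by nature, so the orientation of those
flags follows the regression convention and both cells of a pair may
fire.

Alignment convention: `rr[i]` spans peaks $i \to i{+}1$ and per-peak
covariates enter the design at peak $i{+}1$, so a cause can precede its
effect within a row; the first per-peak sample is dropped.

### Additive-noise discovery (TiMINo-style)

For a variable pair, each orientation fits an additive model of the
effect on its own lags 1..4 and the cause's lags 0..4 (linear by default;
a polynomial `spline` option adds cause-term squares and cubes — flexible
smoothers overfit sequences of a few hundred beats). The fit's residuals
must be independent of the cause *series*, tested against the cause at
shifts $-4..+4$: dependence of anticausal residuals on the cause's
*future* is precisely the signal that rejects a wrong orientation.
Independence is assessed with a max-statistic distance-correlation
permutation test over the univariate shift blocks (200 permutations,
$\alpha_{ind} = 0.05$); a joint block test was rejected because nine
nuisance dimensions dilute single-shift dependence below detectability.
Distance matrices are $O(n^2)$, so rows are subsampled to at most 350 for
the permutation test. An orientation is accepted only when exactly one
passes; otherwise the pair is *unidentified* — an expected outcome on
physiological data, not an error. Cohort counts follow the two-case
inclusion rule for the graph view, and the deterministically dependent
(breathing-phase, amplitude) pair is excluded from discovery and from
classification features.

### Stationarity screen

Granger analysis presumes stationarity, so each 25 Hz channel passes
through an augmented Dickey–Fuller screen (constant, no trend;
augmentation lag `trunc((n-1)^(1/3))`; p-value by two-way interpolation of
the standard Dickey–Fuller tau table). Following the screening convention
adopted here, p < 0.05 (unit root rejected) flags the series stationary.
A non-stationary flag is *reported, not excluding* — mirroring how such
subjects were handled in the protocol this package reproduces.

### Cohort statistics and classification

`summarize_links()` builds the per-(posture, link) tables: mean, SD,
median and IQR over subjects whose link was significant, plus the count
of non-significant (NA) results — the NA count is itself informative (the
more NAs, the less certain the link). `group_tests()` wraps the exact
two-group Wilcoxon rank-sum test, Kruskal–Wallis for more groups, and
unadjusted pairwise post-hoc Wilcoxon tests (a Holm-adjusted copy is
always attached; unadjusted is the default for comparability with the
replicated analysis). `rfe_classify()` performs recursive feature
elimination with a random-forest kernel and stratified 10-fold CV via
`caret`, reporting accuracy mean ± across-fold SD and Cohen's Kappa at
the best subset size, plus a clearly-labeled exploratory (resubstitution)
accuracy. Non-significant feature entries are imputed as 0 with a
companion missingness indicator, since dropping them would discard
exactly the NA-count information the tables treat as signal.

## The synthetic cohort generator

No public raw recordings exist for this protocol, so the generator is a
first-class module: every pipeline stage is validated against its ground
truth.

A subject is a phase oscillator for respiration — cycle lengths jittered
at 10% CV so iRR is non-degenerate — with per-breath depth varying at
~20% CV (real tidal volumes do), within-cycle flow irregularity (an
AR(1) component with ~1 s correlation time, impedance channel only), a
slow stochastic impedance baseline (vasomotion/posture sway; AR(1), ~0.2
Hz corner, 0.03 Ω), and an 0.01 Hz deterministic drift. Heart rate is
`mean_hr * (1 + rsa_gain * g(t) * osc(t + phase_lead) + lf)`, where `osc`
is the *zero-mean depth-modulated* respiratory oscillation, `lf` is an
Ornstein–Uhlenbeck process (correlation time 10 s, sd 2.5%) standing in
for baro/thermoregulatory variability, and `g(t)` is a slowly wandering
vagal gain (correlation time 15 s, 30% CV) — in real subjects the
volume-to-tachogram mapping is not time-invariant. Beats integrate the rate
(midpoint-referenced) with 1% white RR jitter; the ECG is a stylized
raised-cosine QRS train over drift and noise — morphology realism is a
non-goal, Pan–Tompkins robustness is.

Three generator choices carry the science and were fixed on physiological
grounds, not fitted:

- **RSA is phasic vagal gating.** The heart-rate drive follows the
  oscillatory component of the volume waveform — not its slow depth/DC
  content (which travels slower pathways) and not the measurement-level
  flow noise. This localizes the genuine cardiac-to-volume transfer at
  the breathing frequency, where the spectral peak is observed.
- **RSA amplitude scales with tidal volume**, so the tachogram announces
  both the *timing* and the *depth* of the next breath `phase_lead`
  seconds before the volume curve shows it.
- **The phase lead is positive** (default 1 s): the heart-rate maximum
  precedes the tidal-volume maximum. This is the mechanism that makes
  time-ordered (Granger) analysis read the link as iHR → TV even though
  the generative physiology is respiration-driven — the directionality
  the whole analysis turns on. TiMINo, which is not built on time
  asymmetry alone, instead recovers breathing-phase → RR where it
  identifies at all (mostly standing sessions; strong supine RSA leaves
  residual structure in both orientations and the pairs come back
  unidentified, the behavior expected of this method on physiological
  data).
- **The vagal gain wanders.** Without `g(t)`, the volume waveform
  predicts the tachogram's future too well — the anticausal (TV → iHR)
  regression exploits the time-invariant waveform-to-rate mapping and the
  within-cycle smoothness of the carrier. A wandering gain is both
  physiologically standard (autonomic state is not constant over five
  minutes) and what confines the measured causality to the genuine
  early-information channel.

Posture presets: supine 60 beats/min, 0.23 Hz breathing, `rsa_gain`
0.25; standing 75 beats/min, 0.19 Hz, 0.15 (orthostatic vagal
withdrawal). The gains are athlete-level — RR swings of ~25% peak-to-peak
supine are ordinary in endurance-trained subjects with high vagal tone.
Cohort composition defaults to 20 controls plus 100 athletes over the
Mitchell static/dynamic classes (IIIA 5, IB 24, IIB 9, IIIB 12, IC 5,
IIC 33, IIIC 12); as a synthetic convention the RSA gain rises with the
static component (+0.02 per level over a 0.20 control base, subject sd
0.02), which is what makes group labels recoverable by the classifier.
All randomness derives from one master seed; a cohort materializes
recordings lazily, one subject at a time.

What the generator does *not* emulate: ECG morphology beyond the QRS,
ectopy and artifacts, cardiogenic impedance oscillations, nonlinear or
time-varying coupling, and any dependence of breathing on heart activity.
Passing tests therefore demonstrate that the estimators recover known
mechanisms through the full measurement chain — not that real athlete
data would show the same effect sizes.

## Numerical conventions and known limitations

- Sample indexing is 0-based in time units (`t = (i-1)/fs`); intervals
  are half-open.
- ECG detrending is a two-stage running-median baseline (200 ms, then
  600 ms) — parameter-light and QRS-preserving. Pan–Tompkins runs with
  the textbook constants (5–15 Hz band-pass, derivative, squaring, 150 ms
  integration, adaptive dual thresholds, 200 ms refractory) and refines
  fiducials to the local ECG maximum within ±50 ms.
- The breath-phase dead band defaults to 5% of the interdecile derivative
  range; the derivative uses a ±0.1 s symmetric difference. Inspiratory
  onsets are first samples of maximal +1 runs, with a 1 s refractory
  against threshold chatter.
- Rates are reported in beats/min and breaths/min (interval units are
  available); iHR/iRR interpolate linearly between interval midpoints, so
  values never leave the observed interval range and extrapolation is
  constant.
- Anti-alias filtering is zero-phase (forward–backward Butterworth,
  cutoff 0.4·fs_out, filtered around the mean so constants pass exactly).
  Zero-phase filtering is non-causal by construction; its ±2 s smear at
  2.5 Hz is shared by both channels and by any standard decimation chain,
  but it is one reason signal-domain directionality is weaker than
  beat-domain directionality.
- **Oversampling caveat.** At 25 Hz the interpolated-rate series are far
  smoother than their innovation rate; nested-model F tests on such
  series are anti-conservative (non-white residuals), so signal-domain
  significance flags at 25 Hz should be read qualitatively. The 2.5 Hz
  representation is near-critically sampled and its test calibrates at
  the nominal level — one more reason the spectral analysis lives there.
  The test suite checks F calibration where the assumptions hold (white
  inputs, 2.5 Hz pipeline outputs) and effect-size contrasts elsewhere.
- Problem sizes in the test suite (simulation lengths of 300–10 000,
  seed counts of 50–1000 per property, one full 120-subject cohort pass)
  were chosen as the smallest sizes at which the targeted asymptotics are
  already visible.

## Reading the outputs

Every pipeline output CSV carries a provenance header with the config
hash and seed; reruns with the same config are byte-identical. The
per-link summary tables mirror the three-method reporting layout: six
directed links × two postures for the signal methods (PI for the time
domain, peak amplitude and frequency for the spectral method), twelve
links × two postures for beat sequences, NA counts alongside. The TiMINo
census reports per-stratum link counts and unidentified counts, with the
two-case rule applied to the graph view.
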