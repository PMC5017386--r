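---
title: "Recognising WHO hand-hygiene gestures from dual-armband EMG and IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising WHO hand-hygiene gestures from dual-armband EMG and IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handwashr)
```

## The problem

Proper hand hygiene follows a standardised WHO routine of six basic
movements; the movements performed once per leading hand expand into nine
gestures, `G1` through `G6R`, always executed in the same order. Training
the routine benefits from automatic feedback: two gesture-control armbands
worn on the forearms stream 8-channel surface electromyography (sEMG,
200 Hz, int8 samples) and a 10-channel inertial measurement unit (IMU:
orientation quaternion, acceleration, angular velocity at 50 Hz), and a
recognition chain turns those streams into a per-frame gesture label.

`handwashr` implements that chain end to end:

1. **Feature extraction** — per-frame raw values plus Daubechies wavelet
   log-energies per channel, with EMG features computed at full rate and
   aligned to the IMU frame rate at the feature level;
2. **Classification** — a one-vs-all ensemble of nine small feed-forward
   networks trained by scaled conjugate gradient (SCG) with cross-entropy;
3. **Sequence post-processing** — a fixed left-to-right chain hidden Markov
   model over the routine, decoded by Viterbi, which smooths implausible
   frame-level switching.

Because no public recording set exists for this task, the package ships a
synthetic cohort generator that emulates the acquisition protocol the chain
is designed for (17 subjects, 3 routine repetitions, 5 s per gesture,
armbands re-seated between repetitions), so every stage is testable and the
hyperparameter sweeps are reproducible at desk scale.

## Feature model

For IMU frame $i$ the EMG sample at index $4i$ (the 200/50 rate ratio)
anchors a centered, reflection-padded window of `emg_window = 128` samples
(0.64 s) per EMG channel; each IMU channel gets a centered window of
`imu_window = 32` samples. Per channel the feature block is the
instantaneous centre sample plus, for decomposition depth $L$, one scalar
per wavelet level: $\log_{10}(\varepsilon + \bar{d_\ell^2})$ for detail
levels $\ell = 1..L$ and the same statistic on the final approximation.
With 16 EMG and 20 IMU channels the per-frame dimension is

$$D \;=\; 36 + 36\,(L+1),$$

i.e. 432 at $L = 10$. Choices behind this:

* **One scalar per level.** The only per-channel statistic consistent with
  the printed $16 + 16\times11 + 20 + 20\times11$ layout at level 10 is one
  value per detail level plus one for the approximation. Log mean-square
  energy is scale-aware, robust, and standard for sEMG band descriptors.
* **Orthonormal periodized DWT.** The decomposition is the periodized
  orthonormal Daubechies transform (default `db4`, configurable orders
  1–10), implemented in compiled code because feature extraction runs
  millions of small transforms per cohort. Orthonormality gives a Parseval
  identity — level energies partition window energy — which the test suite
  checks to 1e-6 relative and which pins the transform against an
  independent wavelet reference to 1e-12.
* **Feasibility cap.** A window of $n$ samples supports
  $\lfloor \log_2 n\rfloor$ levels. Levels requested beyond that are filled
  with $\log_{10}\varepsilon$ ($\varepsilon = 10^{-12}$): zero information,
  but the advertised dimensionality formula holds for any $L$, so sweeps
  over $L \in \{0,1,3,10,20\}$ are well-defined with 128-sample windows.
* **Feature-level downsampling.** EMG windows are evaluated at every 4th
  EMG sample position rather than downsampling the raw 200 Hz signal first,
  so high-frequency EMG content reaches the wavelet features intact.
* **No pre-filtering.** Beyond whatever the acquisition hardware does
  upstream, no filtering is applied to the signals before feature
  extraction.

## Classifier

Each gesture gets its own binary network: tanh hidden layers (default one
layer of 25 nodes), a single sigmoid output, mean binary cross-entropy on
targets "frame is this gesture". Features are z-scored with statistics
fitted on the training frames only; the standardizer travels with the
ensemble so prediction can never refit it (no test-fold leakage).
Zero-variance features get unit sd. A frame's label is the gesture whose
network responds most strongly; exact ties go to the earliest gesture in
routine order, making prediction deterministic.

Training uses a Møller-style scaled conjugate gradient: conjugate
directions, curvature along the search direction estimated by a one-sided
finite difference of the gradient (scale `scg_sigma = 1e-4`), and a
Levenberg–Marquardt scale $\lambda$ adapted from the ratio of actual to
predicted decrease. No line searches. Two numerical details matter in
practice: the loss and its gradient use the log-sum-exp form of the
cross-entropy (no overflow for large logits), and when a near-exact step
leaves the next conjugate direction numerically cancelled the optimizer
restarts along steepest descent instead of stalling. Weight initialisation
is uniform in $\pm 1/\sqrt{\text{fan-in}}$, seeded per network, so training
is a pure function of (data, configuration).

## Chain HMM

The routine's fixed order makes the sequence model a nine-state
left-to-right chain: state $i$ may persist with probability
`self_prob = 0.995` or advance to $i+1$; the last state absorbs. The
classifier's hard labels are the observations, emitted through a
confusion-style matrix with `emission_correct = 0.9` on the diagonal and
the remainder spread evenly. With 50 Hz frames these defaults price a state
switch at roughly $\log(0.005/0.995)$, so the decoder demands a couple of
frames of consistent evidence before moving on — isolated misclassified
frames are smoothed away, while true segment boundaries move by at most a
few frames.

Decoding is exact Viterbi in log space. The *possible* probabilities are
floored at `log_floor = 1e-12` before the log so that no reachable event
becomes $-\infty$; the *structurally impossible* transitions (backwards or
skipping in the chain) stay at $-\infty$. This distinction is what makes
the decoded path provably monotone in routine order (hence at most 8 label
switches): if the forbidden transitions were merely floored, a long
adversarial observation sequence could buy a backward jump by saving enough
emission penalty. The state-value recursion itself never contains
$-\infty$, because every state is reachable through the floored emission
and initial probabilities. Ties during backtracking resolve toward the
lower ordinal. The test suite checks decoding against exhaustive
enumeration of all $9^T$ paths for sequences up to length 5.

The initial distribution concentrates on `G1` by default because the
routine starts at palm cleaning; `start_at_first = FALSE` gives a uniform
start for decoding fragments.

## Synthetic cohorts

The generator reproduces the statistical structure the chain has to cope
with, not the physiology:

* **EMG** per channel is amplitude-modulated band-limited noise: subject
  gain × placement-mixed template activation × $(1 + 0.1\sin 2\pi f t)$ ×
  zero-mean unit-variance noise with a 20–95 Hz Butterworth (order 4)
  spectrum — a standard sEMG surrogate — plus an additive noise floor, then
  clipped and quantised to int8. Per-segment RMS therefore tracks
  gain × template RMS (a tested invariant), and clipping stays below 1 % at
  the default amplitudes (base 6, peak 18 EMG units; lognormal channel
  gains with sdlog 0.25; noise floor 1).
* **Placement perturbation.** Re-seating the armband between repetitions is
  modelled as a fractional circular rotation of the 8 electrode positions
  (linear mixing of adjacent channels), drawn per repetition up to
  $\pi/8$ — half the electrode spacing — with repetition 1 at the marked
  position.
* **IMU.** Each gesture drives a small-angle sinusoidal rotation (distinct
  axis, frequency 0.8–2.8 Hz, amplitude ≈ 0.25 rad) emitted as exact unit
  quaternions; the accelerometer sees gravity rotated into the sensor frame
  plus a tangential sinusoid plus Gaussian noise (sd 0.05 m/s²), the
  gyroscope the analytic angular rate plus noise (sd 0.5 rad/s).
* **Separation dial.** `separation` in (0, 1] blends all gesture templates
  toward their common mean; 1 is the nominal well-separated gesture set,
  small values make the task genuinely hard. Frame accuracy rises
  monotonically with separation (a tested property), which is the handle
  the test suite uses to exercise the pipeline away from the easy regime.

What the generator does **not** model: motor-unit physiology, realistic
skeletal kinematics, inter-gesture transition dynamics (gestures are
recorded in isolation by default; an optional linear cross-fade exists for
robustness experiments), electrode-skin impedance drift, or the real
inter-subject variability of sEMG. Passing tests on synthetic cohorts
therefore demonstrate that the chain recovers structure of this kind — they
are not evidence about recognition rates on real recordings, whose
difficulty is unknown without deposited data.

## Problem sizes and runtime choices

The protocol-scale evaluation (17 subjects × 3 repetitions, wavelet level
10, 25 hidden nodes, subject-wise 5-fold cross-validation) runs in a few
minutes on one CPU with two deliberate choices: SCG is capped at 60
iterations per network for these runs (the default `max_iter = 300` is kept
for general use), and training uses every 10th 50 Hz frame
(`train_stride = 10`) while evaluation scores every test frame. Adjacent
frames half a window apart are nearly identical, so the stride costs almost
nothing in fit quality; on the nominal cohort the chain reaches ~98 % frame
accuracy before smoothing and the HMM never degrades a fold. Unit and
property tests run at smaller sizes (2–4 subjects, 1.5–2.5 s gestures) for
the same reason; the scaled-down sizes are stated in the tests themselves.

## Known limitations

* The chain HMM assumes the routine order; free-order performance needs a
  different transition topology (and is out of scope here).
* Recognition rate is frame-level accuracy, the definition consistent with
  confusion matrices; per-gesture or per-session averaging would weight
  boundary frames differently.
* Wavelet level 20 exceeds the dyadic feasibility of the default 128-sample
  window; the extra levels carry no information (they are floor-filled), so
  sweeps beyond level ~7 differ only through the approximation band.
* The raw per-channel feature is the instantaneous centre sample; window
  means would be an alternative reading and are not implemented.
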