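---
title: "Stimulus-triggered averaging of EMG and torque: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-triggered averaging of EMG and torque: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimtune)
```

## The problem

During continuous electrical stimulation of the cervical spinal cord, each
stimulus pulse leaves a small, short-latency trace in the muscles it
recruits. That trace is invisible in raw EMG — it is buried in ongoing
voluntary activity — but emerges when many peristimulus segments are
averaged: the stimulus-triggered average (StTA). `stimtune` implements the
full analysis chain around this idea for experiments in which a subject
performs an isometric, eight-target wrist torque-tracking task while
single stimulus pulses are delivered at a fixed inter-stimulus interval
(197 ms by default):

1. segment the stimulus train by task hold state (center hold and the
   eight peripheral targets),
2. average rectified EMG around each stimulus and detect post-stimulus
   effects (PStEs) — facilitation or suppression,
3. quantify their directional tuning against the voluntary torque
   direction,
4. relate their magnitude to the level of background EMG, and
5. extract stimulus-evoked wrist-torque vectors from detrended torque
   averages.

Because the recordings themselves are not distributable, the package
ships a synthetic-session generator whose statistical structure mirrors
the task, together with closed-form oracles for what every analysis stage
should recover from it. Every claim the test suite makes is a claim about
this generator.

## EMG StTA and PStE detection

Rectified EMG sweeps are compiled over a 100 ms window, 30 ms before to
70 ms after each trigger, for triggers whose full window lies inside one
hold period (a containment rule; a looser trigger-inside-hold rule is
available). The averaged trace's baseline mean $\mu$ and SD $\sigma$ come
from the $[-30, -10)$ ms lags. A facilitation is a maximal run of
consecutive lags with trace $> \mu + 3\sigma$ sustained for at least
1 ms; suppression is the analogue below $\mu - 3\sigma$. The first 2 ms
after the trigger are masked as stimulus artifact and carry no detection.
Effect magnitude is the area (µV·ms) between the trace and the crossed
3 SD bound — the bound, not $\mu$, is the reference, matching the hatched
presentation of such effects between the trace and its threshold lines;
an option measures from $\mu$ instead. Onset is the first lag of the run.
When a muscle shows both facilitation and suppression across targets, the
analysis keeps the first (shortest-latency) effect per target, and the
muscle's output type is labelled by the dominant type — the larger sum of
areas over the eight targets — with a plus symbol.

Numerical conventions worth stating: minimum duration is
`ceiling(min_duration_ms * fs / 1000)` samples (2 samples at 2 kHz);
sample $i$ of a window $[a, b)$ ms covers lag $a + i/f_s$; a zero
baseline SD raises a typed degenerate-baseline error rather than
reporting spurious effects; and the detector is checked sample-for-sample
against an independent brute-force scan in the test suite.

## Directional tuning

Per-direction magnitudes $m_d$ (PStE areas, or mean background EMG) over
the eight target angles are summed as vectors,
$R = \sum_d m_d(\cos\theta_d, \sin\theta_d)$; the preferred direction
(PD) is the angle of $R$ and $\bar r = |R| / \sum_d m_d \in [0, 1]$ its
normalized length. Significance uses a shuffle procedure: direction
labels are permuted across triggers 1000 times and the per-direction
magnitudes and PD recomputed each time. For effect magnitudes, whole
sweeps are permuted and the area re-measured inside the originally
detected effect window with each permuted group's own baseline — freezing
the window keeps the statistic well-defined under permutation
(re-detection per shuffle is deliberately not done).

Two decision rules are offered. The default, `"resultant"`, takes
$p$ as the fraction of shuffles whose $|R|$ reaches the observed one;
this is a standard permutation test and holds its nominal size under a
uniform null. The `"literal"` mode instead flags significance when the
observed PD angle falls outside the central 95% interval of the sorted
null PD angles — the procedure as classically described for this
analysis. We made `"resultant"` the default because the sorted-angle
interval is ill-defined when the null PD distribution is itself uniform:
any angle then sits "inside" some 95% arc, and the answer depends on an
arbitrary choice of arc center (we center on the circular mean of the
null angles). The literal mode is retained for fidelity.

The Normalized Spinal PD is the effect PD minus the background-EMG PD,
wrapped to $(-180, 180]$ (180 maps to 180; the wrap is closed above).
Zero means the stimulus-evoked tuning matches the voluntary tuning.
Population-level angle statistics use the Rayleigh test (with the
standard finite-$n$ series correction to $e^{-Z}$), the V-test (normal
approximation on $u = V\sqrt{2/n}$), and the circular median, defined
here as the data angle minimizing the summed absolute circular distance,
ties broken toward the circular mean.

The shuffle unit is the per-trigger observation (sweep or per-sweep
background), not the per-direction summary: permuting summaries would
leave only 8 exchangeable units and an 8-point null.

## Background-EMG dependence

Per-sweep background (mean rectified EMG over $[-30, -10)$ ms before the
trigger) indexes motoneuron-pool excitability at stimulus arrival. Sweeps
pooled over the eight peripheral targets are sorted by background and cut
into five near-equal-count levels (remainder to the lowest bins; counts
differ by at most one — equal-count was chosen over equal-width for
robustness to skewed background distributions, and is configurable). Each
level is averaged as an StTA in its own right, with its own baseline
statistics, and its effect measured by the same detector. Center-hold
sweeps form a separate point excluded from correlation. The relation is
summarized by a two-sided Pearson correlation between per-level
background and area over the five levels.

One subtlety surfaced during validation: the per-sweep background is a
40-sample estimate, so sorting on it selects, in the extreme bins, sweeps
whose baseline noise was extreme. The bin's own baseline mean is then
biased (regression to the mean) by a fraction of a microvolt — enough, at
large sweep counts where $3\sigma$ of the bin average is itself
sub-microvolt, to create tiny spurious threshold crossings that the blind
first-PStE rule can pick over the actual effect. For a condition whose
effect type is already established from the per-target StTAs,
`bin_by_background(effect_type =)` therefore reports each level's
dominant (largest-area) segment of that type; blind first-PStE detection
remains the default for exploratory use. This also means the measured
level series retains a small bias at the extreme bins even for a
perfectly linear gain, which is why correlations of about 0.97, not 1.0,
are the realistic ceiling for the linear-gain generator.

## Torque StTA and evoked torque

Torque sweeps span $[-30, 150)$ ms. Slow voluntary drifts dominate raw
torque averages, so each axis is detrended by a polynomial of order 1–4
before detection; the order is selected by BIC (with the RSS floored so
numerically exact fits compare by the parsimony penalty alone). The
response window cannot simply be excluded from the fit — outside it only
the 30 ms baseline would remain, far too short to pin a cubic — so the
default fits the full window with redescending robust coefficients
(Tukey bisquare), which give the short evoked transient zero weight
rather than letting it drag the fit — with a monotone loss such as
Huber's the transient still pulls the polynomial and biases recovered
magnitudes downward by several percent; a
pre-trigger-only fit with extrapolation is available as
`fit_window = "baseline"`. Baseline mean and SD are recomputed from the
$[-30, -10)$ ms residual. An evoked torque is significant when either
axis deviates by $\ge 10$ SD (boundary inclusive) anywhere in
$[0, 150)$ ms, and is summarized by the farthest point of the $(x, y)$
trajectory from the baseline average — distance as magnitude, angle as
direction. The farthest-point search is restricted to post-trigger lags.
The Normalized Torque subtracts the voluntary torque direction, taken by
default as the commanded target angle (the measured mean hold-torque
angle is available via `voluntary_direction = "measured"`).

## The synthetic generator and its oracles

Each muscle's rectified EMG is $|\varepsilon(t)| \cdot b_m(t)$ with
$\varepsilon \sim N(0,1)$ i.i.d. and
$b_m = b_0 (1 + d\cos(\theta - \mathrm{pd}))$ during a peripheral hold
toward $\theta$; center holds and rest periods use the floor
$b_0(1 - d)$, and movement epochs (0.3 s) ramp linearly between levels.
Since $E|N(0,1)| = \sqrt{2/\pi}$, the expected background during a hold
is $\sqrt{2/\pi}\, b_m$ — the generator's first closed-form oracle. Each
stimulus adds a raised-cosine facilitation bump of peak amplitude
$\min(g_0 + g_1 b_m, \mathrm{cap})$ (the cap emulates a saturating
recruitment regime) and scales the ongoing EMG by $1 - s\,w(t)$ over a
raised-cosine suppression window. Raised cosines were chosen over
rectangles for smoothness with exact integrability. Torque is the sum of
each muscle's low-pass-filtered EMG (first-order, 10 ms time constant — a
minimal stand-in for musculotendon dynamics) times its pull vector, plus
white noise. Triggers run at the fixed inter-stimulus interval through
all task states; the analysis, not the generator, decides which ones
count.

The effect-magnitude oracle mirrors the detector's measurement: the
baseline of an $n$-sweep average has per-lag SD
$b\sqrt{1 - 2/\pi}/\sqrt n$, so the expected area is the kernel's
excursion beyond $3$ of those SDs, summed on the sampling grid
(`expected_pste_area()`). The expected onset is the first grid lag past
the analytic threshold crossing (`expected_pste_onset()`) — note a
raised-cosine kernel is exactly zero at its nominal latency, so the
detected onset is always at least one sample later; comparing against
the raw kernel latency would sit permanently on the tolerance boundary.
The evoked-torque oracle passes the known mean kernel response through
the same low-pass and sums along pull vectors
(`expected_evoked_torque()`); with muscles at 90° spacing and pull
vectors equal to their preferred directions, the expected evoked
direction equals the target angle exactly, by discrete trigonometric
orthogonality.

What the generator does not emulate: trial-to-trial excitability drift,
motor-unit structure (EMG is continuous rectified noise, not spike
trains), current-spread or direct motor-axon recruitment (current
intensity exists only through $g_0, g_1, s$ and the cap), stimulus
artifacts (the artifact mask is exercised by construction, not by a
simulated artifact), and torque dynamics beyond a first-order filter.
Passing recovery tests therefore validates the analysis chain's
correctness and calibration, not the biophysics of any particular
preparation.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| EMG StTA window | $[-30, 70)$ ms | standard peristimulus window for single-pulse effects |
| Torque StTA window | $[-30, 150)$ ms | torque responses outlast EMG effects |
| Baseline window | $[-30, -10)$ ms | pre-stimulus, clear of the previous response |
| EMG threshold | $3$ SD | conventional detection bound for StTA effects |
| Torque threshold | $10$ SD | torque traces are far smoother after averaging |
| Minimum duration | 1 ms | rejects single-sample noise crossings |
| Artifact mask | $[0, 2)$ ms | stimulus artifact exclusion |
| Shuffles | 1000 | resolution of 0.001 on the permutation $p$ |
| Background levels | 5 | enough points for a Pearson $r$, few enough per-level sweeps remain plentiful |
| ISI | 197 ms | generator's stimulus schedule |
| Sampling rate | 2 kHz | generator default |
| Hold durations | 0.8 s center, 0.75 s peripheral | task timing; at 197 ms ISI a 0.75 s hold contains at least 3 fully-contained EMG windows |

## Problem sizes used in validation

The test suite exercises: detector–oracle equivalence on 1000 random
traces; EMG parameter recovery on 50 generator seeds with ~500 assigned
triggers per target (one muscle, PD 60° — deliberately off the target
grid); suppression-only recovery on 30 seeds at ~180 triggers per target;
type-I calibration of the Rayleigh, V, shuffle-PD, ANOVA and t tests at
10,000 replicates each; background-level correlations on 100 seeds each
for linear and saturating gain; evoked-torque recovery on one session
with ~500 torque-window triggers per target; and byte-level determinism
of the full pipeline. `scripts/acceptance.R` recomputes the same
quantities at somewhat smaller sizes from a user-supplied seed.

## Known limitations

- The literal sorted-angle significance mode is faithful to its
  classical description but inherits its ill-definedness under uniform
  nulls; use the default resultant mode for calibrated inference.
- Background-level series carry the regression-to-the-mean bias
  described above; interpret the extreme bins accordingly.
- The Rayleigh $p$ approximation is accurate for $n \gtrsim 10$; for
  very small samples an exact test would be preferable.
- Session I/O is plain CSV/JSON; acquisition-system formats (NEV/NSx)
  are out of scope.
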