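---
title: "Measuring interpersonal movement coordination in improvising dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interpersonal movement coordination in improvising dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadcoord)
```

`dyadcoord` analyzes the movement of two people improvising together —
here, two seated dancers whose hands stay in contact with a table surface,
filmed from above and tracked with markerless pose estimation. This
vignette explains the measures the package implements, the assumptions
they rest on, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## From coordinates to speed

The unit of analysis is scalar hand **speed** (px/s), not velocity:
interpersonal coordination is operationalized as *temporal alignment* of
movement dynamics — two people speeding up, pausing and flowing together —
which does not require moving in the same direction. Speed is also what
makes *joint stillness* visible as coordination: two hands holding still
together have aligned (near-zero) speed profiles whatever their positions.

Tracker output is conditioned before differentiation. Samples whose
tracking likelihood falls below the **p-cutoff** (default 0.6) are masked
and filled by 1-D linear interpolation between retained neighbors, keeping
the 60 Hz grid intact (dropping frames would silently shift all
rolling-window timestamps). A centered **median filter** (default 5
frames, about 83 ms — the smallest symmetric window that removes
single-frame tracker glitches) cleans the coordinates. The cutoff is
applied before the filter, so confident samples are never contaminated by
interpolated ones inside the median window; the opposite ordering is a
configuration change away but is not the default.

Speed is the frame-to-frame Euclidean displacement divided by the frame
interval, giving n − 1 samples for n frames; sample *i* covers the
interval ((i−1)/fps, i/fps] and is timestamped at its right edge. Speeds
are then preprocessed in three steps, in this order:

1. **Trim** to the nominal session length (54,000 frames = 15 min at
   60 Hz); surplus frames are dropped from the end. Shorter series are an
   error rather than being padded.
2. **Outlier removal**: samples more than 3 local SDs from the local mean
   (centered 1 s window, widened to an odd sample count; MATLAB
   moving-statistics conventions, shrinking endpoints) are replaced by
   linear interpolation between the nearest retained samples. Detection is
   a single pass on the raw series; statistics are not recomputed as
   replacements are made. Zero-variance windows flag nothing (avoiding
   0/0). Leading/trailing outliers take the nearest retained value.
3. **Smoothing** with a centered 0.5 s moving mean (even windows weight
   one extra sample toward the past, again the MATLAB convention;
   endpoints shrink).

Units stay in px/s throughout: the analyses are rank- and
threshold-based, and no pixel-to-centimeter calibration is assumed (the
85 x 85 cm table size is metadata only).

## The maximum correlation vector

Temporal alignment between participants A and B is measured by
rolling-window **Spearman** correlations (window 5 s, step 1 sample,
centered) of speed for each of the four between-participant hand
pairings (A-left/B-left, A-left/B-right, A-right/B-left,
A-right/B-right). Spearman rather than Pearson keeps the measure
invariant to any monotone rescaling of speed and robust to the heavy
right tail of speed distributions. Windows are centered and undefined at
the series edges, which keeps moment boundaries symmetric; windows where
either series has zero variance are undefined rather than 0. Ranks use
average ties.

The **maximum correlation vector** takes, at every time point, the
maximum across the four pairings (recording which pairing won). The max
assigns equal credit to coordination regardless of how many hands carry
it: one hand following one hand scores as highly as all four moving in
concert.

### Significance by data sliding

Rolling correlations of smooth signals produce spuriously large values,
so each rated moment gets its own null distribution by **data sliding**:
both of one participant's hand series (jointly, at a single uniformly
random cut — preserving that participant's intra-body coupling) are cut
and the two pieces swapped, then the MCV is recomputed against the
partner's intact series. Sliding preserves each series' autocorrelation
and value multiset while destroying cross-alignment. All defined shuffled
MCV values across 1,000 slides are pooled and the moment's threshold is
the pool's 95th percentile (linear interpolation between order
statistics, the `quantile()` type-7 default). Pooling values rather than
taking per-slide maxima reads the null as "the distribution of shuffled
correlations"; it yields a stable, slightly less extreme threshold. The
slid participant is configurable (default A) — the construction is
asymmetric in principle but generic in practice.

A session-scale note: a slide is a rotation, so every window of the slid
series that does not straddle the cut is a circular window of the
original. The compiled kernel precomputes circular-window ranks once and
reuses them across all slides, which is why 1,000 slides of a
multi-minute moment take seconds; a test verifies the kernel against the
literal slide-recompute-maximize path.

## Evidence classification of moments

A **moment** is a human-rated interval of sustained (at least 10 s) high
or low coordination; shorter intervals are rejected at parse time. For
each moment the classifier integrates the MCV about the threshold
y = 0.5:

* evidence for high: sum of (MCV − y) · dt over samples with MCV > y,
* evidence for low: sum of (y − MCV) · dt over samples with MCV < y,

with undefined samples skipped. The label with the larger evidence wins;
an exact tie goes to *high*, consistent with preferring over-detection of
candidate moments of connection over missing them. Evidence is measured
in rho-seconds; rescaling time units multiplies both evidences equally
and cannot flip a classification. Predictions are scored against the
human ratings with a confusion matrix (positive class high) reporting
accuracy, precision and sensitivity; metrics with zero denominators are
NA rather than 0. Evaluation is moment-level by default; a sample-level
granularity (every defined MCV sample inside each moment, predicted high
iff MCV ≥ y) is available because interval-level and sample-level scoring
answer subtly different questions and published summary metrics do not
always say which was used.

Each moment also carries its perceptual condition: the 15-minute session
divides into five 3-minute blocks alternating eyes open/closed per
participant, and a moment belongs to the block containing its midpoint
(half-open block intervals; a midpoint exactly on a boundary belongs to
the later block).

## Directed influence: normalized symbolic transfer entropy

Transfer entropy asks how much the source's past improves prediction of
the target's future beyond the target's own past. The package computes it
on **ordinal patterns**: each m-sample delay-embedded vector
(x_t, x_{t+tau}, ..., x_{t+(m−1)tau}) is replaced by the index of its
rank permutation — one of m! symbols (m = 3, so 6). Ties rank the earlier
position lower; this matters only during stillness, where smoothed speeds
can produce runs of equal values. Symbolization makes the estimate
invariant to monotone transforms of either signal and cheap enough to run
in thousands of windows.

The plug-in estimate from the empirical counts of triplets
(target future, target past, source past) with prediction step delta is

STE = Σ p(y', y, x) log2 [ p(y' | y, x) / p(y' | y) ] ≥ 0.

Normalization makes values comparable across windows and signal pairs:

NSTE = (STE − ⟨STE_shuffled⟩) / H(y' | y),

where the bias term averages STE over `n_shuffles` (default 10) random
permutations of the source symbol sequence and H is the target's
conditional entropy of future on past. A constant target (H = 0) yields
NSTE = 0 by convention. NSTE lies in [−1, 1]; small negative values occur
by chance under independence and are reported as computed.

Windowed analysis uses 2 s windows stepped by 0.5 s, the four
between-participant hand pairings (the same set as the MCV), and delays
tau = 6..15 samples (100–250 ms at 60 Hz) with the prediction step delta
tied to tau — one parameter plays both roles, treating tau as the
prediction range. Per direction, the window's value is the **maximum**
over pairings and tau, following the practice of selecting the most
informative delay (a mean aggregation is available via
`nste_params(tau_aggregate = "mean")`). Windows are laid on the session's
time axis (a 15-minute session gives floor((900 − 2)/0.5) + 1 = 1797
windows). The **asymmetry index** (a − b)/(a + b), with both directed
values floored at 0 and 0/0 defined as 0, is positive when A leads;
flooring happens only inside the ratio so that raw NSTE is never
distorted. For display, NSTE and asymmetry traces are typically smoothed
with non-overlapping 3 s bin means.

### A known limitation of the shuffle bias term

Randomly permuting the source symbols destroys not only cross-alignment
but also the source's serial structure. For strongly autocorrelated yet
independent signals — such as smoothed movement during mutually
independent improvisation — the permuted-source bias underestimates the
plug-in bias of the intact source, leaving a positive NSTE offset (about
0.2 on the synthetic generator's independent episodes at these window
sizes). The offset is symmetric in direction and cancels in the asymmetry
index, which is the quantity interpreted for leader–follower structure;
the estimator's null is clean (mean within ±0.05 of 0) on independent
white-noise windows. Users comparing raw NSTE magnitudes across signals
with very different autocorrelation should keep this in mind.

## The synthetic dyad generator

`simulate_dyad()` produces full sessions with known ground truth: two
participants x two hands of (x, y, likelihood) at 60 Hz on a 900 px
square table, driven by an episode script. Design choices:

* **Speeds are generated directly; positions are derived.** Every
  estimator consumes speed, so the scripted coupling lives in the latent
  speeds; positions integrate speed along slowly wandering headings (with
  a gentle pull toward the table center) purely so the coordinate-level
  readers, likelihood conditioning and median filter can be exercised on
  plausible trajectories. Reflections at the table bounds are specular —
  position folds and heading flips — so the step length, and hence the
  recovered speed, is preserved exactly.
* **Latent dynamics.** Per-hand speed is nonnegative smoothed AR(1) noise
  (mean 120 px/s, SD 60), with a movement-unit timescale of roughly
  0.25 s (AR coefficient 0.9 at 60 Hz plus 0.1 s shaping). Lively
  improvised hand movement fluctuates at a few Hz; just as importantly,
  scripted coupling lags of 50–400 ms are only recoverable if the signal
  carries power at comparable periods, which a sluggish (sub-Hz)
  simulator would not provide.
* **Coupled episodes**: each follower hand is
  alpha · (same-side leader hand, delayed by the lag) +
  (1 − alpha) · its own latent speed, alpha = 0.9 and lag 150 ms by
  default.
* **Independent episodes**: all four latent speeds evolve independently.
* **Joint stillness**: all hands share one slow micro-movement component
  (SD 2 px/s) plus small independent jitter. Being still *together* is
  itself coordinated behavior — shared rest and sway dynamics — and this
  is what lets rank correlations of near-constant speeds run high without
  degenerate zero-variance windows (set `stillness_sd = 0` to exercise
  the degenerate path).
* **Likelihoods** sit near 0.95 with occasional dropouts below the 0.6
  cutoff (default probability 0.005 per frame).
* Ground-truth labels: coupled and stillness episodes are *high*,
  independent episodes are *low*; episodes shorter than 10 s are not
  moments.

What the generator does **not** emulate: postural coupling and shared
choreographic vocabulary (which correlate real dancers even in "low
coordination" stretches), rater disagreement and boundary fuzziness,
camera distortion, identity swaps and other structured tracker failures,
and any pixel-to-body-scale calibration. Passing tests on synthetic
sessions therefore demonstrates that the estimators recover the
structures they target under controlled conditions — not that human-rated
moments of real recordings will be classified with the same accuracy.

## Numerical choices and problem sizes

* Rolling statistics follow MATLAB moving-window conventions (centered;
  even windows weight one extra past sample; shrinking endpoints), except
  the rolling correlation, which is undefined rather than shrunken at
  edges.
* Percentiles interpolate linearly between order statistics
  (`quantile()` type 7).
* All RNG-dependent stages (data sliding, NSTE shuffles, simulation) take
  explicit seeds and record them in their outputs; reruns with the same
  seed and configuration are byte-identical.
* Degenerate inputs resolve to explicit conventions, not NaNs: zero
  variance windows are undefined correlations, constant targets give
  NSTE 0, all-degenerate sliding pools raise an error, and evidence over
  a moment with no defined MCV raises an error rather than guessing.
* The test and acceptance runs use sessions of 50–260 s and moments of
  30–40 s — large enough that every window size above fits comfortably
  (a 40 s moment holds 2,400 speed samples against the 300-sample
  correlation window) while keeping the full suite in the minutes range.
  Session-scale defaults (15 min, 54,000 frames) are exercised
  arithmetically rather than by simulating full-length sessions.

## Limitations

Beyond the shuffle-bias note above: the MCV is blind to spatial form
(mirroring vs. matching), reports only the *best* pairing rather than
how many hands coordinate, and its rolling window smears onsets by up to
half a window; the evidence classifier is deliberately biased toward
*high* on ties; transfer entropy on 2 s windows of 6-symbol sequences is
a coarse estimator whose per-window direction calls are noisy — the
package's own synthetic benchmark recovers the leader's sign in roughly
95% of in-episode windows under clear coupling, and less under weaker
coupling or lags outside the 100–250 ms delay range.
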