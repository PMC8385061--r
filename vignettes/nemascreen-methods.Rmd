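---
title: "NemaScreen methods: from image stacks to cohort discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NemaScreen methods: from image stacks to cohort discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NemaScreen)
```

## The assay and its two indices

*C. elegans* discriminates complex odor blends — including diluted human
biofluids — through a handful of amphid chemosensory neurons. NemaScreen
implements the computational side of a two-pronged screening assay:

* **Chemotaxis Index (CI).** Worms placed at the center of a quadrant
  plate distribute between odorant (+) and control (−) areas;
  `computeCI()` evaluates CI = (n₊ − n₋)/n_total ∈ [−1, 1].
* **Neuronal Activation Index (NAI).** The AWC^ON olfactory neuron,
  expressing the calcium indicator GCaMP, depolarizes upon *removal* of
  an attractive odor. Many immobilized worms are imaged at once in a
  microfluidic pulse arena while buffer flows for 10 s, odor for 20 s,
  buffer for 30 s. Each viable animal contributes a binary call —
  activated or not — and `computeNAI()` evaluates
  NAI = 2(N_act/N_tot − 1/2) ∈ [−1, 1], directly comparable with the CI:
  NAI > 0 means a majority of viable animals responded.

Cohort discrimination then asks whether per-subject (NAI, CI) pairs
separate a positive group ("cancer") from matched controls
(`discriminate()`: confusion metrics at the zero threshold, ROC/AUC,
two-variable PCA).

## Trace extraction

`subtractBackground()` removes the pixel-wise mean of 20 stimulus-free
background frames (clipping at 0 by default, the unsigned 16-bit
convention; a float mode keeps negatives). `smoothFrames()` applies a
k×k mean filter (default 3×3; the window is clipped and renormalized at
borders so constant frames are preserved exactly).

`trackNeuron()` propagates the neuron position from a seed at a
reference frame (by default 2 s after odor removal, where activated
neurons are brightest) in both temporal directions. The next position
maximizes the 5×5-pixel mean intensity among candidates within
Chebyshev distance 30 px of the previous position, restricted to the
animal's ROI with a 2 px margin so every scored patch is complete. The
30 px bound is interpreted as a Chebyshev (square window) distance — the
natural shape for a windowed search; ties in the maximum go to the
smallest row-major pixel index, making tracking deterministic and
order-independent. The raw trace F is the 5×5 window mean at the
tracked position ("mean intensity of the segmented object"; a
threshold-above-half-maximum segmentation is available via
`segment = "threshold"`).

`computeDff()` forms I_i = (F_i − F0)/F0 with F0 the mean of the first
10 frames — a quiescent window at the start of the pre-stimulus buffer.
A non-positive baseline marks the trace non-viable ("zero baseline")
rather than producing unusable ratios. Because dF/F0 is a ratio of
intensities, the whole chain is invariant under multiplying the stack by
any positive constant, a property the tests assert.

## The motion criterion, and why it needs a margin parameter

`motionCheck()` computes, for each consecutive frame pair, the sum over
ROI pixels of the absolute frame difference, ID_{i,i+1} (absolute, not
signed: a positional jump moves flux without changing its total, so a
signed sum would cancel exactly the artifact the check exists to catch;
a signed mode is kept behind a flag). A trace is viable only if
ID_{i,i+1} < mean(ID) + sdFactor·sd(ID) for *every* i, with mean and
sample sd taken over the IDs in the inclusive window i−20…i+20, clipped
at the stack edges. Two boundary rules matter:

* **Degenerate windows.** A perfectly static noise-free scene has every
  ID equal to 0, and the strict inequality 0 < 0 would reject it. A
  window with zero spread whose tested ID equals the window mean
  carries no evidence of motion and passes.
* **The margin (`sdFactor`).** At the published margin of one standard
  deviation the rule is an outlier test at standard score 1. On series
  whose IDs fluctuate independently (any realistic camera-noise floor)
  each frame violates it with probability ≈ 0.16, so over a 600-frame
  acquisition essentially every trace is rejected; in the original
  workflow every automated call was additionally validated by eye,
  which absorbs this. An automated pipeline has no such backstop, so
  the margin must do the separating on its own. On the synthetic blob
  scenes the relevant standard scores can be computed in closed form:
  the odor-removal transient's fastest frame-to-frame flux change
  scores ≈ 3.9 against its own ±20-frame window, while a 40 px
  positional jump scores ≈ 6.3. `motionCheck()` therefore defaults to
  `sdFactor = 1` (the published rule, used by every oracle-equivalence
  test), and the pipeline configuration sets `motion_sd_factor = 5`,
  between the two scores: activation transients and noise pass, jumps
  fail. Both numbers come from this analysis, not from fitting.

A single violating frame anywhere voids the whole trace, and the ID
statistics window includes the pair being tested.

## Event calling and rates

`callActivation()` brackets the odor-removal event: I_on is the mean
dF/F0 over the last 10 s of the odor interval, I_off the mean over the
first 10 s after removal, σ_on the sample sd over the on-window. The
neuron is called activated when I_off − I_on > 3σ_on. Window length and
both offsets are configurable (the source material fixes only the 10 s
lengths, not the placement; bracketing the removal is the least
arbitrary choice). Calls on non-viable traces are refused — exclusion
happens upstream and is logged — as are calls whose windows leave the
trace or contain missing frames. The rule is invariant under adding a
constant and under positive rescaling, since the difference and σ_on
scale together.

`activationRate()` is the responded fraction; `doseContrast()` compares
positive and control rates per concentration, by difference (default;
the ratio is a mode) — the difference convention is a labeled
assumption, as no formula is given for the published contrast scan.

## Indices, dispersion, aggregation

`binomialSD()` treats each index as an affine image of a binomial
proportion: v = 2p − 1 estimated from n trials has
sd = 2·sqrt(p(1−p)/n). For the CI the two-outcome trial is
odorant-vs-control among worms that chose a scored area, so neutral-zone
worms reduce the effective n.

`aggregateSubject()` averages per-session NAIs without weighting by
session size (sessions are separate experiment days); a pooled,
worm-weighted mode is available, and because it is genuinely ambiguous
whether a per-sample sd should be the across-session sd or the binomial
sd of the pooled counts, both are always reported side by side
(`nai_sd`, `nai_sd_binomial`). The session policy — at least 2 sessions
of at least 25 worms, hence ≥ 50 worms per subject — is enforced as
warnings, not errors, so partial data remain analyzable but visibly
flagged.

`singleWormScore()` sums the scores of the *distinct* sectors an animal
traversed; re-entries do not count again (a path convention — the
alternative double-counts dithering at a sector boundary). The sector
geometry is a user-supplied mapping; `defaultSectorScores()` documents
a plain symmetric default (+1/+2/+3 toward the odorant, mirrored
negative on the control side, 0 at center).

## Discrimination

`classifyBySign()` predicts "cancer" when the index exceeds 0, with
ties going to control (the conservative direction for sensitivity).
`confusionMetrics()` reports sensitivity TP/(TP+FN), specificity
TN/(TN+FP) and accuracy (TP+TN)/all. `rocCurve()` sweeps the threshold
over all distinct scores and integrates by the trapezoid rule; the AUC
then equals the Mann-Whitney probability estimate with ties counted
half, which the tests verify exactly against an independently coded
rank statistic and against pROC.

`pcaTwoVars()` eigendecomposes the raw 2×2 covariance of (CI, NAI) —
both indices already live on the same natural [−1, 1] scale, so
standardizing would discard real variance structure (a
correlation-matrix mode exists). Reported: the PC1 variance fraction
λ₁/(λ₁+λ₂); the NAI "loading contribution" to PC1, interpreted as the
absolute-loading share |v₁,NAI|/(|v₁,CI|+|v₁,NAI|) (the published
loading percentage is not given a formula; this interpretation is
isolated in one function); and per-subject scores with PC1 oriented so
the positive group's mean score is positive. Degenerate inputs — zero
covariance, fewer than 3 subjects, one-class ROC input — are errors,
not silent answers.

## The synthetic-data module

`generateStack()` renders each animal as an isotropic 2-D Gaussian blob
(σ = 3 px by default; only cropped example images exist, so the blob is
a deliberate idealization) on a flat background, with additive Gaussian
pixel noise and 20 separate background frames. Responders multiply
their blob by 1 + A·k(t), where k is a difference of exponentials
(rise 0.5 s, decay 5 s — GCaMP3-like, configurable) normalized to peak
1 on the discrete frame grid, starting at odor removal; because the
spatial profile and temporal modulation factorize, the true peak dF/F0
equals A exactly in the noise-free case, for any fixed spatial
averaging window. An optional on-stimulus hyperpolarization dip is off
by default so the generator matches the activation caller's assumptions
exactly. Motion is a single instantaneous axis-aligned jump at a
recorded frame (directly probing the frame-difference criterion), with
smooth linear drift as the configurable alternative. The default frame
rate is 10 frames/s, inferred from the 100 ms exposure of the
acquisition setup; neither the true frame rate nor the bit depth is
stated anywhere, so both are configuration, not claims. A ground-truth
sidecar records every stochastic draw — positions per frame, responder
flags, onset times, jump frames and displacements — so downstream
stages can be tested against known truth, and a fixed seed makes stacks
bit-identical.

`generateCohort()` works at the count level: per subject and session,
N_act is binomial with the group's activation probability (defaults
0.8 vs 0.2, 36 subjects per group, 2 sessions × 25 worms — the study
conditions). `generatePlateCounts()` allocates worms multinomially so
the expected CI equals the requested attraction, with a configurable
neutral fraction (default 0, so attraction ±1 gives CI ±1 exactly).

**What the generator does not emulate** — and hence what passing tests
do not show about real recordings: worm bodies and autofluorescent
head tissue around the neuron (the real ROI's flux noise floor, which
is precisely why the published motion margin could be as tight as one
sd there), photobleaching, optics/PSF, flow artifacts during valve
switching, and biological variability in transient kinetics and
amplitudes. Conclusions about the *pipeline's* correctness transfer;
conclusions about biological effect sizes do not.

## Numerical choices and problem sizes

Frames are indexed 0-based in time units and 1-based in R arrays; the
published "frames 1…10" baseline maps to the first 10 frames. Box
means use summed-area tables (exact up to float rounding).
Tie-breaks: row-major smallest index in the tracking argmax; ties at
the classification threshold go to control. Seeds snap to the 2 px
patch margin when an ROI crops them. 16-bit TIFF I/O rounds intensities
to integers; all exactness tests therefore run on in-memory stacks, and
the round-trip test asserts agreement to half an intensity unit.

The test suite generates all fixtures in code. Image-based tests use
96–220 px arenas with 1–4 animals at 5–10 frames/s; Monte-Carlo
equivalence runs use 10,000 replicate traces for the activation caller
and 1,000 replicate noise scenes for the motion check; cohort-level
recovery uses 100 replicate cohorts of 36+36 subjects at 2 sessions ×
25 worms. These sizes were chosen to make sampling error (3-SE bands)
small relative to the effects under test.

## Known limitations

* The motion criterion's published margin is structurally unusable
  without human validation (analysis above); the package makes the
  margin explicit rather than silently alterable.
* The chemotaxis single-worm sector geometry is a convention, not a
  reproduction of the cited protocol's plate layout.
* Headline cohort-level figures reported for assays of this kind
  (imaging accuracies above 95%, PC1 variance fractions near 91%) come
  from raw recordings that are not publicly deposited; nothing in this
  package claims to reproduce a specific cohort result — the
  discrimination machinery is validated on synthetic cohorts and
  closed-form identities instead.
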