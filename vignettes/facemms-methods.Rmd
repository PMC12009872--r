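---
title: "Methods: micro-movement spike signatures of facial kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-movement spike signatures of facial kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemms)
```

# The estimation problem

A 5-second, 30-Hz facial recording tracked with an OpenFace-style model
gives 150 frames of 68 landmark positions. The quantity of interest is
not the mean motion but the *stochastic signature* of moment-to-moment
speed fluctuations: how variable, and how heavy-tailed, the deviations of
landmark speed are around their typical level, region by region. The
pipeline turns a raw landmark table into, per facial subregion, a
two-parameter Gamma fit whose scale is a noise-to-signal ratio (NSR) and
whose shape controls skewness — a compact, comparable description of
facial micro-motility.

The assumptions, in order of application:

1. **Per-frame z-scoring** (`zscore_frames()`) assumes the 68 points of a
   frame have non-degenerate spread on both axes. It removes rigid
   translation (including distance-to-camera changes) and isotropic
   scale. It does *not* compensate head rotation or lens distortion, so
   recordings with large pose changes violate the model.
2. **Spline differentiation** (`compute_speed()`) assumes landmark
   trajectories are smooth enough between frames that an interpolating
   cubic represents them; speed is read off the analytic derivative at
   the original frame times, so each landmark contributes exactly 150
   speed samples and the per-region totals are 26·150 = 3,900 (V1),
   17·150 = 2,550 (V2) and 25·150 = 3,750 (V3).
3. **Gluing** (`glue_region()`) concatenates a region's speed segments in
   fixed ascending landmark order. The analysis treats the glued series
   as a *set* of amplitude fluctuations, not a time series; the peak
   amplitude multiset is insensitive to the glue order except at the
   few segment junctions, which the tests bound explicitly.
4. **Gamma family** for the speed-peak amplitudes and for the MMS peak
   values. Positive, right-skewed, unimodal data with an exponential
   special case (shape 1) — appropriate for amplitude fluctuations; not
   appropriate if the spike distribution were multimodal.
5. **Independence** of peak amplitudes within a region. Peaks of a glued
   series are weakly dependent in reality; the MLE is treated as a
   quasi-likelihood summary and group inference is run on medians and
   rank tests, which are robust to this.

# The trigeminal parcellation

Landmarks 0–67 are split into V1 (ophthalmic) = {17..30, 36..47},
V2 (maxillary) = {31..35, 48..54, 60..64}, V3 (mandibular) =
{0..16, 55..59, 65..67}, with sizes 26/17/25. Two choices were genuinely
open here. Landmark 33 (nose tip) sits anatomically on the maxillary
midline and is assigned to V2; this is also the only assignment that
makes the three region sizes and the three per-region frame totals
mutually consistent. Second, the inner-lip points 60–64 complete V2's 17
points (index 68 does not exist on a 0-based 68-point grid).
`trigeminal_partition()` is the single source of truth; any alternative
partition covering 0–67 exactly once can be passed to every downstream
function.

# Micro-movement spikes

Per region the empirical Gamma mean `Γ_μ = a·b` is estimated by MLE on
the *peak amplitudes* of the glued speed series (not on all samples: the
peaks are the fluctuation events of interest, and 150-frame regions yield
comfortably more than 100 of them). Absolute deviations `|v − Γ_μ|` are
standardized peak-by-peak:

`spike = P / (P + (m_left + m_right)/2)`

with `m_left`, `m_right` the values of the nearest local minima flanking
the peak. Properties forced by the formula, and property-tested:

* spikes lie in (0, 1] for any non-negative deviation series;
* a spike equals 1 exactly when both flanking minima are 0;
* rescaling the whole speed series by `c > 0` multiplies `Γ_μ` by `c`
  and leaves every spike unchanged — the standardization deliberately
  removes amplitude units (and with them anatomical size effects).

Conventions for degenerate shapes: a plateau of equal values flanked by
lower values counts as one peak at its first index; series endpoints are
never peaks; a local minimum is a strict interior minimum or a boundary
sample lower than its first differing neighbor; a minimum shared by two
peaks serves both; a boundary peak with only one flanking minimum uses
that single minimum. Samples exactly equal to `Γ_μ` create zero minima
and hence spikes of 1 — accepted as the formula's limit behavior.

# Gamma MLE, confidence intervals, derived spaces

`fit_gamma_mle()` solves the profile score equation
`log(a) − digamma(a) = log(mean x) − mean(log x)` with a bracketed
`uniroot` (Minka's closed form as the starting bracket center), then
`b = mean(x)/a`. 95% CIs are asymptotic normal intervals from the inverse
observed Fisher information; they are deterministic given the data, and
their coverage and shrinkage with `n` are tested by simulation. A floor
of `n ≥ 30` positive values is enforced — below that the intervals carry
no useful information. Degenerate inputs (any non-positive value, zero
variance) are errors, not silent fixes.

Derived quantities follow the Gamma family: mean `a·b`, sd `√a·b`,
skewness `2/√a`, and `NSR = b`, read as the variance-to-mean ratio
`a·b²/(a·b)` — the identity under which "NSR equals the scale" is exact,
and the convention used throughout. Per participant the regional NSR and
skewness vectors over (V1, V2, V3) are summarized by their Euclidean
norms, giving one point per recording in the NSR-norm/skewness-norm
plane.

# EMD and tree clustering

`emd_1d()` computes the first-order Wasserstein distance between
empirical samples as the integrated absolute ECDF difference; it is
cross-checked in the tests against an exhaustive assignment enumeration
(equal sizes), a quantile-function integral (unequal sizes), and an
external reference implementation. "Tree classifier" is implemented as
agglomerative hierarchical clustering with *average linkage* on the
precomputed distance matrix, cut into the requested subtype count `k`;
average linkage is the standard robust choice for non-Euclidean distance
matrices. Matrix normalization, when requested, divides by the maximum
off-diagonal entry (per matrix, not across tasks). Typical cuts are
`k = 6` (3 regions × 2 groups, one task) and `k = 14` (2 groups × 7
expressions).

# Action units

Presence is decided by the modal full-row pattern across frames (ties:
earliest first occurrence). The "switching" of patterns is quantified
with the edit distance of equal-length binary strings, which reduces to
the Hamming distance: the whole-face index is the mean Hamming distance
between consecutive frame patterns, the per-AU index the fraction of
consecutive pairs in which that AU's bit flips. Intensities at or above
the threshold (default 0.001, boundary *inclusive*) are pooled across a
group's participants; histograms use Freedman–Diaconis bins. Group
presence in summaries means a non-empty pool in at least one participant;
the consensus fraction is reported alongside for finer analysis.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| frame rate / duration | 30 Hz / 5 s | — | shortest window that still yields >100 peaks per region |
| confidence floor for frames | 0.75 | — | OpenFace's conventional usable-frame cutoff |
| failed-frame budget | 10% | of frames | 5-s clips cannot absorb larger gaps; below it, coordinates are linearly interpolated |
| minimum peaks per fit | 30 | peaks | CI floor; regions normally provide hundreds |
| AU intensity threshold | 0.001 | intensity units | inclusive lower bound on saved intensities |
| cluster count `k` | 6 | clusters | 3 regions × 2 groups at one task |
| EMD normalization | off | — | per-matrix max-scaling for cross-figure comparability |

# The synthetic cohort generator

`generate_recording()` emulates what the pipeline consumes, not a face on
video: landmarks start from a schematic 68-point template and perform
random walks whose per-frame step lengths are i.i.d. Gamma draws with
region-specific (shape, scale), directions uniform on the circle and
independent across frames (a deliberately memoryless default); AU
presence follows independent 2-state Markov chains, intensities a Beta
law scaled to [0, 5]. Default group regimes encode the orderings the
pipeline is meant to resolve: TD-like profiles at shape 8 / scale 0.1 per
region, ASD-LS at 1.5 / 0.8, ASD-HS at 1.2 / 1.0, and ASD-HS-apraxia at shape
1.2 with regional scales (1.0, 1.0, 2.0) — the V3 scale doubled — i.e.
low-noise,
light-tailed typical motion versus broader, heavier-tailed autistic
motion with mandibular dominance in the apraxia profile. These constants
are the generator's definition of the study conditions and are not tuned
per experiment.

What the generator does **not** emulate: head pose and rotation, lens
compression, tracker noise correlated across landmarks, temporal
autocorrelation of motion, asymmetric or task-specific facial synergies.
Passing tests on synthetic cohorts therefore demonstrates that the
estimator chain is correct and that injected distributional regimes
survive the pipeline — not that real TD/ASD faces follow these exact
laws.

Seeding: every cohort is a pure function of its master seed; recording
`i` uses `(seed · 1000003 + i) mod (2^31 − 1)`.

# Parameter recovery and its honest limits

Smoothing, differentiation, vector-norm speeds and MMS standardization
transform the injected step-length law nonlinearly, so exact parameter
recovery is asserted only where it is well-posed: Gamma fits to the
*injected step lengths themselves* recover the generating (shape, scale)
to within ~10% median relative error at the default sizes. Pipeline
outputs are judged on *regime ordering* instead (ASD above TD in NSR and
skewness; apraxia's V3 dominating its other regions).

One consequence of the MMS scale-invariance deserves emphasis: a profile
that differs only by an amplitude rescaling (the apraxia V3 doubling) is
*invisible* to the MMS-stage signatures by construction. The recovery
experiment therefore reads its orderings from the speed-amplitude-stage
Gamma fits (`mu_signature`), where amplitude information lives, while the
MMS-stage signatures drive the EMD clustering and the signature-space
planes. Shape-driven group differences appear at both stages.

Problem sizes used by the test suite: recovery orderings over 20
replicate cohorts of 5 + 5 + 5 participants; cluster purity on one
10 + 10 cohort at `k = 6`; EMD oracle comparisons over 200 random small
instances; CI coverage over 100 replicates of n = 1000. These sizes give
stable verdicts at interactive runtimes.

# Known limitations

* Pose and perspective distortions pass through the z-scoring untouched;
  the signatures conflate them with facial motion.
* The Gamma CIs are asymptotic; at the enforced floor of 30 peaks they
  are approximate (coverage is tested at realistic peak counts).
* Peak dependence within a glued series is ignored by the likelihood;
  group-level inference uses medians and rank tests partly for this
  reason.
* The temporal structure of spikes (widths, intervals, binarized trains)
  is out of scope; the pipeline analyzes amplitude statistics only.
* `emd_1d()` is exact for 1-D empirical distributions but nothing here
  addresses multi-dimensional transport.
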