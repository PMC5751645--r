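---
title: "Micro-expression spotting and recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-expression spotting and recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mexpress)
```

# The problem and the model

Micro-expressions (MEs) are involuntary facial movements lasting a fraction
of a second with very low amplitude. Two tasks are addressed: *spotting*
(which frames of a video contain a ME, and the apex frame where it peaks)
and *recognition* (positive / negative / surprise). Both build on one
motion descriptor, computed per pixel at frame $t$:

$$ MM_t = \frac{|f_t - f_{t-\lfloor\tau/2\rfloor}| + 1}
               {|f_t - f_{t-\varepsilon}| + 1} $$

with $\tau$ the average ME duration in frames and $\varepsilon$ a gap so
short that no facial motion can occur across it at high frame rates. The
numerator contrasts a potential apex frame with a potential onset frame
half a ME earlier; the denominator is a noise normalizer: sensor noise and
flicker affect both differences similarly, while genuine slow facial motion
contributes to the numerator only. The `+1` regularizers act on the 0–255
intensity scale; intensities are deliberately *not* rescaled to $[0,1]$,
which would change the relative weight of the regularizer. Color frames
are reduced to BT.601 luma before the descriptor, which is scalar per
pixel.

Only ten square facial cells are analyzed, anchored to 68 iBUG-ordered
landmarks after roll normalization: two frontalis cells above the mid-brow
points, the procerus above the inner brow ends, the two eye (orbicularis
oculi) centroids, two cells lateral to the nose wings (zygomatic region),
the two mouth corners, and the mentalis below the lower lip. The common
cell side is half the mouth width, so the layout is equivariant under
translation and uniform scaling of the face. Only the in-plane (roll)
angle — estimated from the outer eye-corner line — is corrected; yaw and
pitch are out of scope, as all current ME datasets are near-frontal.

## Spotting

Frame $t$ is summarized by the per-cell mean of $MM$, and by the
20-vector of per-cell minima and maxima of that signal over the
$\tau$-frame window centered on $t$. A discrete AdaBoost ensemble of 35
depth-1 decision trees (stumps, fit by `rpart` under instance weights,
stage weight $\frac12\log\frac{1-e}{e}$) classifies frames as ME /
non-ME. Ground-truth labels mark $t$ as ME iff $|t - t_{apex}| <
\delta\tau$ (strict, real-valued threshold, $\delta = 0.25$); training
balances classes by subsampling non-ME frames to the ME count.

Raw labels are post-processed: maximal ME runs become intervals; adjacent
intervals with gap $< 2\tau$ are merged to a fixpoint; intervals with
$\mathrm{end}-\mathrm{start} < \tau/4$ are dropped; the apex is the middle
frame of each survivor. An alternative merge condition that compares
interval *length differences* instead of gaps is available as
`mergeRule = "printed"`; the gap rule is the default because the merge
parameter is explicitly a distance between clusters. Scoring is
apex-based: a detection is a true positive iff it can be matched
one-to-one (greedy nearest-first) to a truth apex within $\delta\tau$;
the false-positive rate divides unmatched detections by the total number
of true MEs.

## Recognition

A $\tau$-frame window centered on the apex is resampled to $n$ indices by
half-up rounding (no temporal interpolation), and in every cell the
intensity-weighted centroid of $MM$ is computed at each resampled frame;
the feature is the list of centroid displacements relative to the first
resampled frame. Training pools the $n-1$ pairs of every training
sequence per cell as i.i.d. observations and fits a bivariate Gaussian
(sample mean, unbiased covariance + ridge $\lambda I$); classification
sums the standard bivariate normal log-densities over cells and pairs and
takes the argmax class, with ties broken deterministically in the order
positive, negative, surprise. Summing per-pair log-densities (rather than
scoring the mean displacement once) is the default; the alternative is
`pooling = "mean"`. The density includes the full normalizing constant
$((2\pi)^k\det\Sigma)^{-1/2}$; a monotone distortion common to all classes
would not change the argmax, but the standard form keeps scores
interpretable as log-likelihoods.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 37 | frames | average ME duration at ~100 fps (65 at 200 fps); window size everywhere |
| `eps` | 3 | frames | noise-normalizer gap; must satisfy $\varepsilon < \tau/2$ |
| `delta` | 0.25 | — | labeling and scoring half-width factor |
| `nResample` | 11 | frames | recognition window width after resampling; frame-rate invariance |
| `minMicroSz` | $\lfloor\tau/4\rfloor$ | frames | minimum surviving interval size |
| `maxDist` | $2\tau$ | frames | maximum gap for interval merging |
| `nEstimators` | 35 | — | boosted weak learners |
| `treeDepth` | 1 | — | weak-learner depth (stumps) |
| `covFloor` | $10^{-6}$ | px² | covariance ridge; keeps degenerate training sets positive definite |
| `mmBaseline` | `"eq1"` | — | recognition MM reference: $t-\lfloor\tau/2\rfloor$, or the window's own first frame (`"windowStart"`) |

All are bundled and re-validated by `pipelineConfig()`, with YAML
round-trip via `readPipelineConfig()` / `writePipelineConfig()`.

# Numerical choices and degenerate inputs

* $\tau/2$ means $\lfloor\tau/2\rfloor$ for odd $\tau$. Reference indices
  $t-\lfloor\tau/2\rfloor$ and $t-\varepsilon$ clamp to frame 0; the
  spotting stage additionally zero-fills the per-cell signal for
  $t < \lceil\tau/2\rceil$ and forces those frames to non-ME, so clamping
  only affects recognition windows near the start of a sequence.
* Cells resolve to integer pixel blocks (side rounded half-up, pixel
  centers at integer coordinates); cells are clipped to the frame at use
  time, and a cell entirely outside the frame is an error. All half-up
  rounding uses `floor(x + 0.5)` rather than banker's rounding.
* Roll normalization rotates image and landmarks about the landmark
  centroid; the image warp is bilinear with zero fill, precomputed once
  per sequence. A zero estimated roll returns the inputs bitwise
  unchanged. Faces with $|\theta| \ge 90°$ or coincident eye corners are
  rejected.
* Weighted centroids are always defined because $MM > 0$ everywhere (the
  `+1` floor), and always lie inside the clipped cell.
* Sequences shorter than $\tau$ are skipped with a message during
  detection and evaluation.
* AdaBoost stops early on a perfect weak learner and discards a weak
  learner whose weighted error reaches 0.5 (keeping at least one);
  prediction is the sign of the weighted vote, with the tie (score
  exactly 0) mapped to non-ME.

# The synthetic generator

The simulator emulates the regime the pipeline targets: a near-frontal
face with stable landmarks, localized sub-pixel-to-few-pixel intensity
motion inside specified facial cells with class-specific directions and an
onset → apex → offset temporal envelope, additive Gaussian sensor noise
and optional global sinusoidal flicker, quantized to 8-bit frames. Every
output is a pure function of its parameters and seed.

Each cell carries one *anchor* intensity blob; an expression event
re-renders the affected cells with the anchor displaced by
$\mathrm{direction} \times \mathrm{magnitude} \times \mathrm{envelope}(t)$.
Rendering is restricted to the cell square, so with noise and flicker
disabled every pixel outside affected cells is constant over time — a
property the tests assert exactly. A single translating blob was chosen
deliberately: the $|{\rm diff}|$ field of a translated blob is exactly
symmetric about the path midpoint, so the weighted-centroid displacement
points along the true motion direction; translating the whole textured
cell instead would move the centroid toward the texture's gradient-mass
center, confounding direction with texture layout.

Class direction templates follow the facial action units: surprise raises
brows and procerus and lifts the eye region (upward vectors in five
cells); positive pulls the mouth corners outward and upward; negative
knits the brows downward/inward and drags the mouth corners down. The
negative class is a single motion template standing for the pooled
disgust/anger/fear/sadness/contempt category.

**Envelope.** The displacement rises $0 \to 1$ over [onset, apex] and
falls over [apex, offset] (piecewise cosine), but does not return all the
way: a residual fraction (default 0.5) remains at the annotated offset and
relaxes to zero slowly over a further 80 frames. This models how offsets
are annotated in practice — the offset marks the end of *visible* motion,
not the frame where the appearance has exactly reverted — and it matters
for the descriptor: with an instantaneous return to neutral, every frame
in $[\mathrm{offset}, \mathrm{offset}+\tau/2]$ contrasts a neutral frame
against an in-event frame, so the elevated-signal band extends $\tau/2$
frames past the offset and the interval midpoint (the detected apex) is
systematically late by about $\tau/4$ — right at the scoring threshold.
With the slow relaxation, no $\lfloor\tau/2\rfloor$-frame pair after the
offset spans a large appearance contrast, and the detected band centers on
the apex, which is also the regime in which the published real-data
accuracy of this method class is achievable at all.

**Datasets.** `generateDataset()` gives every subject a distinct face
seed and a small landmark jitter ($\sigma = 1\%$ of the frame); sequences
carry 0, 1 or 2 events (default probabilities 0.2 / 0.6 / 0.2), durations
uniform in [20, 40] frames, magnitudes uniform in [1, 4] px by default,
apexes at least 40 frames from the borders and (for two-event sequences)
160 frames apart so that separate events survive interval merging
($2\tau = 74$ would otherwise glue their detection bands together).

**What passing tests do and do not show.** The generator produces
rigid-translation intensity motion of isolated blobs under i.i.d. Gaussian
noise. Real faces add texture deformation (not just translation), eye
blinks, macro-expressions, head motion, illumination drift and
subject-specific appearance differences far richer than blob-amplitude
variation. Tests passing on this simulator validate the machinery —
descriptors, learning, post-processing, protocol — under the assumptions
the method itself makes; they do not certify accuracy figures on real
video.

# Analysis notes from the evaluation study

* *Detection saturates around 80–90% and is not noise-limited.* The
  labeling rule marks in-event frames outside $t_{apex} \pm \delta\tau$
  as non-ME although their windowed min/max features are nearly identical
  to apex-frame features. Boosting cannot fix these contradictory
  negatives and responds by inflating stump thresholds, which clips the
  weakest events. The effect persists when the noise is switched off and
  magnitudes are raised (the miss floor stays ≈ 15%), and the boosted
  ensemble was verified to agree exactly with an independent AdaBoost
  implementation on identical features — the ceiling is a property of the
  feature/labeling design, mirrored by the accuracy levels reported for
  this method class on real data.
* *Half-pixel block bias in displacement directions.* The integer pixel
  block of a cell is offset from the landmark-derived (real-valued) cell
  center by up to half a pixel, adding a constant off-axis term to
  centroid displacements that is comparable to a ~1 px motion signal.
  The offset is uniform over subjects, so the subject-averaged direction
  recovers the class template (tested within 30°), and the per-class
  Gaussians absorb it as a subject/cell-specific bias.
* *Permutation null is wider than binomial.* Under label permutation,
  LOSO recognition accuracy has mean near 1/3 but a much larger spread
  than the naive binomial band: predictions within a fold share the same
  fitted models, and the compositional overlap between permuted training
  sets and test features adds correlated optimism (observed spread
  roughly 0.30–0.56). The chance band used by the tests, $[0.1, 0.6]$,
  is $1/3 \pm 3\sigma$ with a fold-clustered $\sigma \approx 0.09$,
  paired with the requirement that permutation collapses accuracy by at
  least 0.3 from the unpermuted run.
* *Problem sizes.* The evaluation study uses 8 subjects × 5 sequences of
  360 frames at 96 × 96 px, pooled over five dataset seeds, which keeps a
  full run in the minutes range while still providing ≈ 200 events; the
  unit tests use smaller scenes chosen to exercise the same code paths in
  seconds.

# Known limitations

* Only roll is corrected; yaw/pitch and head motion are out of scope.
* The spotting features discard temporal position within the window
  (min/max only), which bounds apex-localization accuracy as analyzed
  above.
* Recognition assumes per-cell Gaussian displacement clusters; classes
  whose motion differs mainly in dynamics (not direction) would not be
  separable in this feature space.
* The three-class taxonomy pools all negative emotions; finer taxonomies
  need more data than spontaneous-ME corpora currently provide.
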