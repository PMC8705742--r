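---
title: "Gait representation learning from tracked skeletons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait representation learning from tracked skeletons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gait — the way a person walks — is a biometric that can be read from a
distance, without cooperation, and without appearance information. When a
pose estimator plus a tracker is run over ordinary video, each tracked
person yields a *tracklet*: a contiguous sequence of 2D skeletons in the
COCO-17 convention (17 joints, each with x, y and a detection
confidence). `skelgait` turns such tracklets into anonymized,
height-normalized gait samples, learns an embedding in which walks of the
same person lie close together, and evaluates recognition with the
standard gallery/probe protocols of the gait literature. Because raw
surveillance-style tracklets carry no identity labels, the training
signal is the tracking itself: two augmented crops of one tracklet form a
positive pair, and everything else in the batch is a negative.

## Curation: filters and normalization

Raw tracked skeletons include broken tracks, badly detected poses and
people who are not walking. The filter cascade keeps a tracklet only if:

* its **mean joint confidence** (all frames x 17 joints) is strictly
  above 0.60;
* it has at most 3 **consecutive frames with feet confidence below
  0.50**, where the per-frame feet confidence is the *minimum* of the two
  ankle confidences — both feet must be visible essentially throughout;
* its length is between 54 frames (about two gait cycles at 24 fps) and a
  configurable maximum (default 1000 — very long tracks are
  characteristically loiterers, and the exact cutoff is exposed because
  no principled universal value exists);
* the **mean leg velocity** — the per-frame Euclidean displacement of
  ankles and knees, averaged over joints and frames, in *normalized*
  units — is at least 0.01. Static people fail this even with realistic
  detector jitter.

Filters run in the fixed order length → confidence → feet → velocity,
and every rejection is attributed to the first failing stage, which makes
reports deterministic and rejection counts additive.

Two readings of "feet velocity" exist — ankles only, or ankles plus
knees. The default averages ankles and knees (`velocity_joints =
"legs"`); the ankles-only variant is one configuration flag away. The
velocity stage consumes *normalized* coordinates, so normalization must
run first; the pipeline applies normalize → filter.

Normalization maps each skeleton, per frame, to a canonical body frame:

$$x' = \frac{x - x_{pelvis}}{|x_{R.shoulder} - x_{L.shoulder}|},\qquad
  y' = \frac{y - y_{pelvis}}{|y_{neck} - y_{pelvis}|}$$

with the pelvis defined as the hip midpoint and the neck as the shoulder
midpoint (COCO-17 has neither point; the midpoint construction is the
only one consistent with the equations on COCO input). After the map the
pelvis is exactly at the origin and the shoulder width and torso length
are exactly 1, so the output carries no absolute position, scale or
stature information — this is also the anonymization step. The map is
idempotent and invariant to translation and uniform scaling of the
input; the y-down pixel convention is kept (no axis flip). Frames whose
shoulder width or torso length falls below `eps = 1e-6` source units are
degenerate; the default policy rejects the whole tracklet (dropping
frames would silently break temporal contiguity), with `"drop"`
available.

## The encoder

The encoder is a spatio-temporal graph-convolutional network. The
skeleton is a graph on 17 joints with the COCO bone structure `A`
(symmetric, zero diagonal), self-connections `I`, and the degree matrix
$\Lambda_{ii} = \sum_j (A_{ij} + I_{ij})$. One block applies

$$f_{out} = \Lambda^{-1/2}\left((A + I) \otimes M\right)\Lambda^{-1/2}
  \, f_{in} \, W$$

where $\otimes$ is the elementwise product and `M` is a learnable
edge-importance mask, initialized to ones and deliberately *not*
symmetrized. The degree normalization is computed from `A + I`, not from
the masked matrix, so it stays fixed while `M` is learned; with `M = 1`
the spatial operator is symmetric with spectral radius at most 1. The
channel mixing `W` is realized inside a standard `1 x Γ` temporal
convolution (default `Γ = 9`, odd, padding `Γ//2`), so each block does
spatial aggregation over the masked adjacency followed by temporal
filtering and a ReLU. Global average pooling over joints and time feeds a
two-layer projection head whose output is L2-normalized onto the unit
sphere. There is no classification head, so the parameter count is
independent of how many identities (or tracklets) the training data
contains.

The default stack follows the classic seven-block recipe
(64/64/64/128/128/256/256, stride 2 where the width grows). The
desk-scale experiments in this package use a two-block 16/32 encoder
with a 16-dimensional embedding — small enough to train on one CPU in
minutes, and the architecture is fully configuration-driven.

Because no automatic-differentiation framework is part of this package's
dependency set, the forward and backward passes are written directly as
vectorized matrix algebra (im2col temporal convolution, closed-form
gradients through the masked adjacency, pooling, head and the L2
normalization), optimized with Adam. The backward pass is verified
against finite differences in the test suite, including the gradient
that reaches the edge-importance mask.

## Augmentation and the contrastive objective

Each training batch draws `N` tracklets and builds two views of each:
pace change (time-resampling by a factor drawn uniformly from
{0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2}), then a random 54-frame crop
(a tracklet shorter than the window is tiled from its start), then
horizontal squeeze, optional mirror (x negation *plus* left/right joint
relabeling) and time reversal, and joint/frame dropout (zeroing, never
deletion, so tensor shapes are static). "Flipping" and "mirroring" name
two distinct transforms; the conventional split — temporal reversal
versus horizontal reflection — is used. The squeeze interval and the
dropout rates have no canonical published values and are configuration
parameters.

The loss over the `2N` unit-norm embeddings $z$ with batch labels
$\tilde y$ is the supervised contrastive loss

$$\mathcal{L} = \sum_{i}\frac{-1}{|P(i)|}\sum_{p \in P(i)}
  \log\frac{\exp(z_i \cdot z_p/\tau)}{\sum_{a \in A(i)}\exp(z_i \cdot z_a/\tau)}$$

with $A(i)$ all other indices, $P(i)$ the same-label ones, and
temperature $\tau = 0.01$ by default (smaller temperatures sharpen the
contrast). At $\tau = 0.01$ the naive exponentials overflow, so the
implementation is log-sum-exp stabilized; the degenerate all-identical
batch evaluates exactly to $\log(2N - 1)$ for any temperature, which the
tests pin down. In pretraining the labels are tracklet ids — the only
(indirect) supervision is tracking. Fine-tuning reuses the same loss
with identity labels on a per-identity sample of runs
(`round(fraction * runs)`, floor of one), with layer-wise learning
rates: the head trains at the base rate and each deeper level (toward
the input blocks and the edge mask) at a factor `0.5` lower, protecting
pretrained low-level features.

## Evaluation

Retrieval uses cosine similarity (the dot product on the unit sphere);
rank-1 accuracy is the fraction of probes whose nearest gallery item
shares their identity, with ties broken to the lowest gallery index so
results are deterministic. The cross-view protocol probes one viewpoint
angle at a time with a gallery containing all *other* angles, testing
viewpoint invariance; identity splits keep training identities out of
the evaluation set, and the harness refuses overlapping splits outright.

Test-time embedding is deterministic multi-crop: each tracklet is cut
into four evenly spaced 54-frame windows, each window is encoded, and
the embeddings are averaged and re-normalized. A single window picks an
arbitrary gait phase; averaging a few windows removes that nuisance
without any randomness.

The embedding scatter plot projects with classical multidimensional
scaling on cosine distances — a deterministic projection that needs no
extra dependency; it is a diagnostic, not part of the method.

## The synthetic gait simulator

All end-to-end tests run on a parametric 2D walker. Each identity draws
a kinematic signature: cadence ~ Normal(0.9, 0.1) strides/s truncated
above 0.5, ankle swing half-range ~ Normal(0.35, 0.05) torso units, knee
and arm amplitudes, left/right phase offsets in antiphase π plus
Normal(0, 0.1) jitter, bone lengths jittered ~5% around a canonical
frame (torso = 1), and a vertical bounce amplitude. A tracklet renders
sinusoids of that signature: ankles and knees swing along x, arms
counter-swing, the body bounces at twice the cadence, a viewpoint angle
θ foreshortens body-local x by cos θ and adds a walking drift along
sin θ, and the result is scaled to pixels (y-down). Lengths are drawn
around a mean of 108 frames at 24 fps, matching the scale of real
curated tracklet corpora.

Two modeling choices deserve justification:

* **Joint noise is AR(1)-correlated and calibrated in normalized
  units** (σ = 0.01 per coordinate after normalization, ρ = 0.95 at
  24 fps). The x component therefore scales with the (foreshortened)
  shoulder width and the y component with the torso length, so the
  jitter a downstream consumer sees is σ regardless of viewpoint.
  Pose-estimator jitter on tracked pose streams is smooth, not white,
  and the correlation constant comes from a velocity budget: a standing
  person's normalized leg velocity must stay below half the 0.01
  walking threshold, which caps the per-frame step noise
  σ√(2(1−ρ)) and gives ρ ≥ ~0.92; ρ = 0.95 (correlation time ~0.8 s)
  satisfies it with margin. White noise at the same σ would make
  standing contaminants indistinguishable from slow walkers, which no
  realistic jitter model should do.
* **Confidences follow a fixed joint-type reliability profile** (face
  and torso joints high, wrists/ankles lower) plus temporal noise.
  Drawing a random base confidence per joint *per tracklet* would give
  every tracklet a static 17-dimensional fingerprint that tracklet-level
  contrastive training exploits instead of the kinematics — an artifact
  no real detector produces, since detector reliability attaches to
  joint types and viewing conditions, not to track identities.

Contaminant modes exercise the filters: `standing` zeroes all
oscillation (fails the velocity filter), `low-confidence` inserts a ≥4
frame block of ankle confidences below 0.5 (fails the feet filter); the
benchmark generator records each tracklet's expected verdict, and the
tests require exact agreement between those labels and the filter
cascade.

What the simulator does *not* emulate: clothing/carrying variation,
occlusion by other people, non-sinusoidal gait detail, genuine 3D
projection (the viewpoint model is a 2D foreshortening), and detector
failure modes such as left/right swaps. Passing the end-to-end tests
therefore shows that the pipeline recovers identities whose walks differ
in cadence, amplitudes, phases and proportions under moderate smooth
noise — not that it reaches any particular accuracy on real surveillance
footage.

## Desk-scale experiment design

The bundled experiments (`identity_recovery_run()`,
`pretraining_benefit_run()`, `size_trend_run()`) are scaled so each runs
in minutes on one CPU: 20 identities x 4 runs x 2 angles (0° and 45°),
a 10/10 identity split, the two-block 16/32 encoder, 16-source batches
and 40 pretraining epochs. Angles 0° and 45° keep the viewpoint model
well-conditioned (at 90° the cos θ foreshortening collapses x entirely
and the 2D viewpoint model stops being meaningful).

At this scale the augmentation suite for training is restricted to the
temporal transforms — pace change over the full factor set and the
random 54-frame crop: with only 40 training tracklets, the strong
stochastic corruptions (dropout, mirror, squeeze jitter) overwhelm the
identity signal before the encoder can absorb it, a small-data effect
that disappears at the corpus sizes those augmentations are designed
for. The choice is an explicit experiment parameter, not a change to
the augmentation module's defaults.

Numerical conventions collected in one place: frame indices are 0-based
with frame `k` at `k/fps` seconds; interpolation (resampling, pace
change) is linear with constant extrapolation at the boundary, and
interpolated confidences are clamped to [0, 1]; nearest-neighbor ties
break to the lowest gallery index; every stochastic step derives its
seed from one experiment seed by a stable hash, so runs are exactly
reproducible; repeat-padding of short sequences tiles from index 0 (the
alternative prefix-duplication reading is noted in the crop
documentation and would only matter for sequences shorter than the
window).

## Known limitations

* The hand-written training loop is CPU-bound R; it is sized for the
  bundled experiments, not for corpus-scale pretraining.
* The viewpoint model is a planar foreshortening; angles near 90° are
  degenerate by construction.
* Tracklet-level contrastive labels conflict with multi-run-per-identity
  training pools (two runs of one person are treated as negatives); with
  one tracklet per person — the regime unconstrained corpora are in —
  the conflict vanishes. The few-shot fine-tuning path with identity
  labels is the supervised complement.
* `read_keypoint_tracklets()` expects contiguous per-track frame
  indices and treats gaps as corruption; stitching fragmented tracks is
  out of scope.
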