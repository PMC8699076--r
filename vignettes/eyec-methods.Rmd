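---
title: "Detecting dyadic eye contact from keypoints and 3-D gaze: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dyadic eye contact from keypoints and 3-D gaze: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyec)
```

## The problem

In unconstrained clinical video — for example a therapist and a preschool
child playing during an assessment session, filmed by a single uncalibrated
camera in the corner of the room — episodes of mutual eye contact are a
behaviourally meaningful, hand-codable quantity. Manual frame-by-frame
coding is prohibitively slow, so the practical pipeline is: a multi-person
pose estimator produces 2-D body keypoints per frame; a head crop around
each person feeds an appearance-based gaze estimator that returns a 3-D
gaze direction `g = (x, y, z)` in camera-centred coordinates; and a
geometric rule decides, frame by frame, whether the two people are looking
at each other. This package implements everything downstream of the two
neural estimators: head-box construction, tracking, the eye-contact
geometry, event segmentation, frame-level validation, session features,
and cohort stratification, plus a synthetic scene generator so the whole
chain is testable without clinical footage.

The two estimators themselves are out of scope by design; their outputs are
consumed as files (OpenPose-style body_25 JSON and a CSV gaze table). That
decoupling also means any gaze estimator — or the bundled simulator — can
drive the detector.

## Head boxes from keypoints

The six keypoints used are the nose, both eyes, both ears (the "facial"
points) and the neck. A keypoint with confidence 0 is missing. The head box
of one person in one frame is the axis-aligned bounding rectangle of the
present facial points; with fewer than two facial points the head is
underdetermined and the frame contributes no box. Eye/ear extents alone
systematically underestimate head height (they all sit near one horizontal
band, and in profile views nearly collapse), so when the neck is present
the height is floored at 0.8 times the nose-to-neck pixel distance,
growing the box symmetrically about its centre. The 0.8 factor reflects
ordinary head anthropometry: the chin-to-crown extent is somewhat smaller
than the nose-to-neck-base distance.

Two preprocessing operations mirror what makes gaze estimation workable on
small, jittery detections:

* **Enlargement** (`enlarge_box`, default +50%) scales a box about its
  centre, handing the gaze estimator a larger crop. It exists for crop
  extraction; in `run_session` the *detection* geometry deliberately uses
  un-enlarged boxes, because the contact threshold below is defined
  relative to the head's actual size, and inflating both by a constant
  would silently loosen the threshold by the same factor.
* **Size normalisation** (`normalize_box_sizes`, default 25 frames = 1 s
  at 25 fps) partitions each gap-free run of boxes into consecutive
  25-frame sequences and assigns every box in a sequence the maximum
  width and height recorded there, keeping centres. This holds the crop
  shape constant over short sequences, which stabilises sequence-based
  gaze estimators, and it makes the per-frame box size a robust quantity
  when single frames detect only a sliver of the head. Block maxima
  (rather than a sliding maximum) keep the operation idempotent and never
  let sizes leak across detection gaps.

Tracking is greedy frame-to-frame association by
intersection-over-union against each live track's last box, falling back
to nearest centres when nothing overlaps; tracks with fewer than 25 boxes
are discarded as flicker. Roles are assigned either from an explicit
configuration or by the adult-size heuristic: the track with the larger
median normalised box height is the therapist. Medians closer than 5%
are declared ambiguous rather than guessed. Size normalisation runs
*before* the heuristic: frames where a subject faces away from the camera
yield degenerate boxes, and the blockwise maxima restore a representative
height for the comparison.

## The eye-contact geometry

Let `g0_A`, `g0_B` be the two head-box centres (pixels) and `g_A`, `g_B`
the unit gaze vectors. For subject A looking toward B, the gaze ray from
`g0_A` with image-plane slope `g_y / g_x` is intersected with the vertical
line through `g0_B`; the distance

`d_A = | p_y − g0_B,y |`

between that intersection and B's centre measures how closely A's gaze
passes B's face. Ray — not line — semantics: if `g_x` is zero or points
away from B, there is no intersection and `d = +Inf`, so a subject looking
directly away can never register contact (a full line would).

A frame is a contact frame when three conditions hold:

1. `d_A ≤ T_d · size(box_B)` and `d_B ≤ T_d · size(box_A)`, with
   `size = max(width, height)` and `T_d = 0.8` by default. The threshold
   is box-relative, which makes every contact decision invariant to
   uniform rescaling of the image — the same interaction filmed at 384 px
   or 1920 px yields the same flags.
2. Depth compatibility: two people genuinely looking at each other from
   different camera depths must have `z` components of opposite sign.
   When either `|z| ≤ T_z` (default 0.3) the pair is at nearly the same
   depth, where estimation fluctuation around zero makes the sign test
   unreliable, so it is waived. The mixed case — one deep, one shallow —
   is treated as compatible, consistent with the waiver's motivation.
3. Minimum duration: maximal runs of contact frames shorter than
   `min_duration_frames` (default 25 frames ≈ 1 s at 25 fps) are
   discarded, suppressing single-frame coincidences and matching the
   perceptual time scale at which human coders call something an episode.

Frames missing either box or either gaze are *undefined*: never contact,
and by default they break runs. `gap_bridge_frames` (default 0) optionally
bridges non-contact gaps of at most that many frames between runs before
the duration filter. It exists for robustness analysis: per-frame
detection dropout at rate q fragments a genuine episode of length L into
sub-runs with probability ≈ 1 − (1 − q)^L, which the duration filter then
deletes — at q = 4% combined and L = 42 that is about 5 in 6 episodes
lost. A small bridge (2–3 frames, ≤ 120 ms) rides over isolated dropouts
while leaving genuine interruptions intact; the package's noisy-condition
evaluations use 3.

Per-frame contact is symmetric in the two subjects by construction, and
the flag count is monotone in both `T_d` and `T_z`, while the event count
is antitone in the minimum duration — properties the test suite asserts on
randomised sessions.

## Validation and parameter selection

Hand-coded annotations (BORIS-style interval exports) are rasterised to
per-frame booleans with `frame = floor(t · fps)` over half-open intervals
`[start, stop)`, overlaps unioned — stated exactly so fixtures are
bit-reproducible. Detected events are rasterised over the session span and
compared frame by frame: accuracy, precision, recall, and the Matthews
correlation coefficient (MCC), the balanced metric appropriate when
contact frames are rare. All zero-denominator cases are defined as 0.

`grid_search` evaluates a finite `T_d × T_z × min_duration` grid by the
unweighted mean MCC across annotated sessions and returns the argmax,
breaking exact ties toward the most conservative cell (smaller `T_d`,
smaller `T_z`, larger minimum duration). Because the per-frame geometry
does not depend on the thresholds, dyad-frame tables are computed once per
session and re-thresholded per cell.

## What the simulator emulates — and what it does not

`simulate_scene` builds a fully labelled dyadic session: two spherical
heads (child 9 cm radius, therapist 12 cm) in front of an ideal pinhole
camera (focal length 900 px, 1280×720 image), at 1.6 m lateral separation
and equal 3 m camera depth, with smooth deterministic sway. Keypoints sit
at fixed angular offsets on each head; points whose outward normal faces
more than ~100° away from the camera are occluded, so away-facing frames
genuinely lose eyes and nose, exercising the underdetermined-head path.
Heads yaw toward the gaze target but pitch far less than the eyes do
(vertical gaze component damped ×0.3 in the facing direction), as real
heads do. During scheduled episodes each agent's gaze is the exact unit
vector toward the other's head centre; at equal depth the projected ray
then passes exactly through the partner's projected centre, so at zero
noise the analytic gaze distance is identically 0 on episode frames and
the emitted `z` components are ≈ 0. Outside episodes, agents dwell
10–50 frames on random scene points kept both 15° away from the partner
in 3-D *and* at least four head radii away in projected ray distance —
without the projected margin, a deviation mostly in depth can still cross
the partner's head in the image and plant geometric mutual gaze on frames
labelled negative.

Three noise knobs emulate the estimators' error modes: angular gaze noise
(Gaussian, degrees), multiplicative head-size jitter (the dominant failure
of head detection on dynamic footage), and per-frame per-person dropout.
The simulator does **not** model lens distortion (the cameras it emulates
are uncalibrated but treated as ideal pinholes), correlated or
heavy-tailed gaze errors of a specific estimator, occlusion by furniture,
or more than two people. Passing tests on simulated scenes therefore
demonstrate the correctness and robustness of the downstream geometry and
segmentation, not the accuracy of any particular pose or gaze network on
real footage.

`simulate_tuning_session` generates annotated sessions directly at the
gaze-geometry level, with an error structure that makes the canonical
cell (0.8, 0.3, 25 frames) the best match to the annotations: genuine
episodes whose smooth gaze offsets regularly enter the 0.6–0.8 band (a
tighter threshold loses frames), near-miss passes at 0.82–0.98 of the box
size (a looser threshold admits them), same-sign depth fluctuation within
|z| ∈ [0.21, 0.29] on a quarter of episodes (a tighter depth tolerance
rejects them), deep same-sign 2-D-only crossings at |z| ∈ [0.32, 0.42]
(a looser tolerance admits them), and sub-second genuine glances of 8–20
frames that coders do not annotate as episodes (a shorter minimum
duration turns them into false events).

## Session features and stratification

Per session: `num` (event count), `freq = num / session_minutes`
(events/min), `dur` (mean event duration, s), and `d_mean` — the mean
child-side gaze distance over **all** frames where it is defined and
finite, not only contact frames; it measures how close the child's gaze
stays to the therapist's face across the whole interaction, which is why
its natural scale (hundreds of pixels) sits far above the contact
threshold. Zero-event sessions report `dur` as missing. `time_binned`
splits the frame span into equal contiguous segments (default 4,
remainder to the last) and assigns each event to the bin holding its
start frame, so events never straddle bins.

The cohort pipeline follows the published stratification recipe:
population-sd z-scores (stated so fixtures are exact to the last digit);
variance-inflation factors `1/(1 − R²)` for multicollinearity screening
(an event count and its rate over near-constant session lengths exceed
the conventional VIF > 5 flag, the package reproduces this
qualitatively); natural-log transforms for skewed features (`log1p` when
zeros are present, recorded in an attribute); a 2-component UMAP
embedding with 5 nearest neighbours and minimum distance 0 (uwot, single
thread, seeded — the layout is stochastic and a seed is required for
reproducibility); HDBSCAN density clustering with minimum cluster size 10
(twice the number of clustering features) and the `-1` noise label; and
the silhouette coefficient over non-noise points, computed in the
embedded space, since the embedding is the object that was clustered.

HDBSCAN is implemented in the package (mutual-reachability distances from
core distances at `min_samples = min_cluster_size`, a Prim minimum
spanning tree, single-linkage hierarchy, condensation by minimum cluster
size, and excess-of-mass stability selection with the root never
selectable) because no R implementation is available in the supported
stack; on fixture data its labels agree with scikit-learn's HDBSCAN
label-for-label, which the test suite pins. The O(n²) formulation is
deliberate: cohorts here are tens to hundreds of subjects.

### A note on cohort-recovery expectations

The bundled cohort generator draws independent per-feature Gaussians from
the published three-sub-group parameters (group sizes 23/21/16). Those
printed standard deviations are identical across groups for every feature
— the signature of pooled model standard errors rather than raw
within-group spreads — and at that spread the two low-coordination
sub-groups overlap enough that the density clusterer merges them on most
seeds: the modal cluster count over 10 seeds is 2, and the mean adjusted
Rand index against the generating labels is ≈ 0.64 (the acceptance script
recomputes both; an independent python UMAP + HDBSCAN stack reproduces
the same behaviour on identical cohorts). The high-coordination group is
always isolated, and on seeds where three clusters do emerge the
adjusted Rand index is ≈ 0.85. With within-group SDs at one half to two
thirds of the printed values the pipeline recovers three clusters
near-perfectly (ARI ≈ 0.97) — so the limitation lies in the printed
spread parameters, not in the pipeline. The generator nevertheless keeps
the printed values as its defaults: they are the stated study
conditions, and the package reports what they honestly yield.

## Numerical choices and degenerate inputs

* Gaze vectors are renormalised on read; zero-norm rows are dropped with
  a warning. Only direction is ever used.
* `d = +Inf` for rays that cannot reach the target line; undefined frames
  (missing box/gaze) are `NA` and never contact.
* Degenerate head boxes (collinear keypoints) receive a 1 px floor so
  areas stay positive.
* Event bounds are inclusive `[start, end]`; duration in frames is
  `end − start + 1`; frame indices are 0-based; image origin top-left
  with y downward.
* MCC/precision/recall are 0 whenever a denominator vanishes.
* Exact grid-search ties resolve deterministically (most conservative
  cell), making results independent of session order.
* All randomness flows from explicit integer seeds; simulator outputs are
  byte-identical across runs with the same configuration.

## Problem sizes

The test suite and the acceptance script work at sizes chosen to exercise
every code path at interactive speeds: simulated sessions of 1 500 frames
(60 s at 25 fps) with six planted episodes of 30–120 frames; 10 seeds per
noise condition; five 3 000-frame annotated sessions under a 3×3×3
parameter grid; and cohorts of 60 subjects over 10 seeds for the
stratification pipeline. These are an order of magnitude below the ~70 000
annotated frames of a real validation campaign but stress the same
geometry, segmentation and selection logic.

## Known limitations

* The gaze-to-head distance is measured only along the vertical line
  through the target's centre — the published operationalisation — so
  horizontal near-misses at the same height are indistinguishable from
  direct hits until the depth rule intervenes.
* The depth rule uses signs and a single tolerance, not actual depth
  estimates; at extreme depth asymmetry the 2-D slope approximation the
  projection relies on degrades.
* Role assignment by size fails when the two interactants have similar
  head sizes; an explicit role hint is the supported escape hatch.
* The simulator's noise model is independent per frame; real gaze
  estimators produce temporally correlated errors, which bridging handles
  less gracefully than isolated dropouts.
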