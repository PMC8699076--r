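# eyec — dyadic eye-contact detection and stratification from keypoints and 3-D gaze

`eyec` detects episodes of mutual eye contact between two people filmed by
a single uncalibrated camera — the typical setting of a therapist–child
play interaction recorded in a clinic — starting from the outputs of
standard vision models: per-frame 2-D body keypoints (OpenPose-style
body_25 JSON) and per-frame 3-D gaze direction vectors `g = (x, y, z)` in
the camera-centred convention of appearance-based gaze estimators
(`z < 0` looks toward the camera). It is aimed at behavioural researchers
who want frame-accurate, reproducible eye-contact measures from
unconstrained video, and at methodologists validating such detectors.

## The method

For each frame, head bounding boxes are built from the nose, eye, ear and
neck keypoints (with a neck-based height floor), enlarged for gaze-crop
extraction, size-normalised over short frame sequences, and associated
into two tracks (child / therapist). Subject A "looks at" subject B when
the image-plane ray from A's head-box centre `g0_A` along `(g_x, g_y)`
crosses the vertical line through B's centre `g0_B` at a distance

    d_A = | p_y − g0_B,y | ≤ T_d · size(box_B),   size = max(w, h)

with `T_d = 0.8` by default. A frame is a **contact frame** when both
distances pass their box-relative thresholds and the gaze depths are
compatible: `z` components of opposite sign, the requirement being waived
when either `|z| ≤ T_z` (default 0.3, the same-room-depth case). Maximal
runs of contact frames of at least `min_duration_frames` (default 25 ≈ 1 s
at 25 fps) become **eye-contact events**. Detection quality is scored
frame-by-frame against observational annotations with accuracy,
precision, recall and the Matthews correlation coefficient (MCC), and the
three parameters can be re-selected by grid search on mean MCC across
annotated sessions.

Per-session features — number of events `num`, frequency `freq`
(events/min), mean duration `dur` (s), and the session-wide mean gaze
distance `d` (px) — feed an unsupervised stratification pipeline:
population-sd z-scoring, VIF multicollinearity screening, 2-component
UMAP (5 neighbours, min distance 0), HDBSCAN density clustering
(minimum cluster size 10, noise label −1; implemented in the package and
pinned against scikit-learn's labels), and silhouette scoring.

A fully labelled scene simulator (pinhole camera, spherical keypoint
heads with occlusion, planted mutual-gaze episodes, angular gaze noise,
box-size jitter, detection dropout) and a per-group Gaussian cohort
generator make the whole chain testable without clinical data.

## Worked example

Simulate a noisy 60-second dyadic session (2° gaze noise, 10% head-box
jitter, 2% detection dropout), run the full pipeline, and score it against
the simulator's ground truth:

```r
library(eyec)

scn <- simulate_scene(scene_config(seed = 42, n_frames = 1500,
                                   gaze_noise_deg = 2, box_jitter_frac = 0.1,
                                   dropout_prob = 0.02))
res <- run_session(scn$keypoints, scn$gaze,
                   params = detector_params(gap_bridge_frames = 3))
res$events
#>   start_frame end_frame n_frames duration_s   mean_d
#> 1          73       150       78       3.12 15.63738
#> 2         305       398       94       3.76 12.22379
#> 3         486       539       54       2.16 15.23642
#> 4         728       830      103       4.12 11.29510
#> 5         934       979       46       1.84 13.57040
#> 6        1276      1353       78       3.12 11.32499

compute_features(res$frames, res$events, fps = 25)
#>   num freq  dur d_mean session_minutes age_months
#> 1   6    6 3.02  188.6               1         NA

evaluate_events(res$events, scn$truth$mutual)
#> $accuracy  0.999   $precision 1   $recall 0.998   $mcc 0.998
```

All six planted episodes are recovered (`mean_d` stays ~12–16 px, far
inside the ~48 px threshold a 60 px head box implies); the frame-level
MCC of 0.998 reflects a few boundary frames lost to noise. The same
session with `gaze_noise_deg = 0, box_jitter_frac = 0, dropout_prob = 0`
gives MCC = 1 with event bounds exactly equal to the planted schedule.

Cohort stratification on a simulated 60-subject cohort (three sub-groups
with published means/SDs):

```r
co <- simulate_cohort(seed = 42)
cols <- c("num", "freq", "dur", "d_mean", "age_months")
vif(co, cols)
#>   num  freq   dur d_mean age_months
#>  4.13  4.34  1.22   1.48       1.35
cl <- cluster_density(embed_2d(zscore(co, cols), cols, seed = 42), 10)
cl
#> <eyec_clusters n=60 clusters=2 noise=0 silhouette=0.799>
```

(On these synthetic cohorts the two low-coordination sub-groups often
merge; see the methods vignette for why the printed per-group SDs make
that expected.)

A thin command-line front end over the same functions ships in
`inst/cli/eyec.R` (`detect`, `simulate`, `simulate-cohort`, `features`,
`eval`, `cluster` subcommands).

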