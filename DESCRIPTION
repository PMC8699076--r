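Package: eyec
Title: Dyadic Eye-Contact Detection and Stratification from Keypoints and 3-D Gaze
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects episodes of mutual eye contact between two people
    (e.g., a child and a therapist) filmed by a single uncalibrated camera,
    starting from per-frame 2-D body keypoints (OpenPose-style JSON) and
    per-frame 3-D gaze direction vectors in the camera-centred convention
    used by appearance-based gaze estimators. Builds enlarged,
    size-normalised head bounding boxes from facial keypoints, tracks the
    two interactants across frames, applies a geometric mutual-gaze test
    with a box-relative distance threshold and a depth-compatibility rule,
    and segments contact frames into events with a minimum duration.
    Includes frame-level validation against observational annotations
    (accuracy, precision, recall, Matthews correlation coefficient) with
    grid search over detector parameters, session-level eye-contact
    features (number, frequency, mean duration, mean gaze distance, time
    bins), a fully labelled synthetic dyadic-scene and cohort simulator,
    and an unsupervised stratification pipeline (z-scoring, VIF screening,
    UMAP embedding, HDBSCAN density clustering with a noise label, and
    silhouette scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    uwot,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
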