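# Frame-level validation against hand-coded annotations, and empirical
# detector-parameter selection by grid search on the average Matthews
# correlation coefficient (MCC) across annotated sessions.

#' Read observational annotations into per-frame labels
#'
#' Reads a behavioural-coding export (BORIS-style) and rasterises it to a
#' per-frame boolean vector. Two dialects are accepted: interval rows with
#' columns `start_time_s`, `stop_time_s` (seconds), rasterised with
#' `frame = floor(t * fps)` over half-open intervals `[start, stop)`; or
#' per-frame rows with columns `frame`, `label` (0/1 or logical).
#' Overlapping intervals union.
#'
#' @param path CSV export path.
#' @param fps Frame rate used for rasterisation.
#' @param total_frames Length of the output vector (frames 0 ..
#'   `total_frames - 1`).
#' @return Logical vector of length `total_frames`.
#' @export
read_annotations <- function(path, fps = 25, total_frames) {
  if (!is_count(total_frames, 1L)) stop_eyec("`total_frames` must be >= 1")
  ann <- read.csv(path, stringsAsFactors = FALSE)
  out <- rep(FALSE, total_frames)
  if (all(c("start_time_s", "stop_time_s") %in% names(ann))) {
    if (any(ann$stop_time_s < ann$start_time_s)) {
      stop_eyec("annotation interval with stop before start")
    }
    for (i in seq_len(nrow(ann))) {
      a <- floor(ann$start_time_s[i] * fps)
      b <- floor(ann$stop_time_s[i] * fps) - 1  # half-open [start, stop)
      a <- max(a, 0); b <- min(b, total_frames - 1)
      if (a <= b) out[(a:b) + 1L] <- TRUE
    }
  } else if (all(c("frame", "label") %in% names(ann))) {
    sel <- ann$frame >= 0 & ann$frame < total_frames
    out[ann$frame[sel] + 1L] <- as.logical(ann$label[sel])
  } else {
    stop_eyec("annotation export needs columns start_time_s,stop_time_s ",
              "or frame,label")
  }
  out
}

#' Frame-level confusion counts
#'
#' @param pred Predicted per-frame labels (logical; NA counts as FALSE).
#' @param truth Ground-truth per-frame labels (logical).
#' @return List with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_eyec("`pred` and `truth` must have equal length")
  }
  pred <- !is.na(pred) & pred
  truth <- !is.na(truth) & truth
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, and the Matthews correlation coefficient.
#' Zero-denominator conventions: precision and recall are 0 when undefined;
#' the MCC is 0 when any factor of its denominator is 0.
#'
#' @param c Confusion counts from [confusion_counts()].
#' @return List with `accuracy`, `precision`, `recall`, `mcc`.
#' @export
classification_metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  n <- tp + fp + tn + fn
  acc <- if (n > 0) (tp + tn) / n else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2) else 0
  list(accuracy = acc, precision = pre, recall = rec, mcc = mcc)
}

#' Evaluate a detection against annotations at the frame level
#'
#' Convenience wrapper: rasterises detected events over the session span
#' and compares them with the truth vector.
#'
#' @param events Event table from [detect_eye_contact()].
#' @param truth Logical per-frame ground truth.
#' @param start_frame Frame index of `truth[1]` (default 0).
#' @return List of metrics (see [classification_metrics()]).
#' @export
evaluate_events <- function(events, truth, start_frame = 0) {
  pred <- flags_from_events(events, length(truth), start_frame)
  classification_metrics(confusion_counts(pred, truth))
}

#' Select detector parameters by grid search on mean MCC
#'
#' Runs the detector on every annotated session for every cell of a finite
#' parameter grid and returns the cell maximising the unweighted mean
#' frame-level MCC across sessions. Ties break toward the most conservative
#' cell: smaller `td_fraction`, then smaller `tz`, then larger
#' `min_duration_frames`.
#'
#' @param sessions List of sessions, each a list with elements `child`,
#'   `therapist` (`eyec_track` with gaze joined), `truth` (logical
#'   per-frame annotation vector) and optionally `fps` (default 25).
#' @param grid List with numeric vectors `td_fraction`, `tz`,
#'   `min_duration_frames` (any may be length 1); optionally
#'   `gap_bridge_frames` (scalar, default 0).
#' @return List with `best` ([detector_params()]) and `table` (one row per
#'   cell with its mean MCC, ordered as evaluated).
#' @export
grid_search <- function(sessions, grid) {
  if (length(sessions) < 1L) stop_eyec("need at least one annotated session")
  for (nm in c("td_fraction", "tz", "min_duration_frames")) {
    if (is.null(grid[[nm]]) || length(grid[[nm]]) == 0L) {
      stop_eyec("grid is missing values for ", nm)
    }
  }
  gap <- if (is.null(grid$gap_bridge_frames)) 0L else grid$gap_bridge_frames[1]
  cells <- expand.grid(td_fraction = sort(grid$td_fraction),
                       tz = sort(grid$tz),
                       min_duration_frames = sort(grid$min_duration_frames,
                                                  decreasing = TRUE))
  # Per-session frame geometry does not depend on the thresholds, so the
  # dyad-frame tables are built once and re-thresholded per cell.
  pre <- lapply(sessions, function(s) {
    fps <- if (is.null(s$fps)) 25 else s$fps
    list(frames = build_dyad_frames(s$child, s$therapist),
         truth = s$truth, fps = fps)
  })
  mean_mcc <- vapply(seq_len(nrow(cells)), function(i) {
    p <- detector_params(cells$td_fraction[i], cells$tz[i],
                         cells$min_duration_frames[i], gap)
    mccs <- vapply(pre, function(s) {
      fr <- frame_contact(s$frames, p)
      ev <- segment_events(fr$contact, p, s$fps, start_frame = fr$frame[1])
      pred <- flags_from_events(ev, length(s$truth), start_frame = fr$frame[1])
      classification_metrics(confusion_counts(pred, s$truth))$mcc
    }, 0)
    mean(mccs)
  }, 0)
  cells$mean_mcc <- mean_mcc
  tied <- cells[cells$mean_mcc == max(cells$mean_mcc), , drop = FALSE]
  tied <- tied[order(tied$td_fraction, tied$tz, -tied$min_duration_frames), ,
               drop = FALSE]
  best <- tied[1, ]
  list(best = detector_params(best$td_fraction, best$tz,
                              best$min_duration_frames, gap),
       table = cells)
}
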