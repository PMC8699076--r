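# Per-person tracks: a time-ordered sequence of head boxes (gaps allowed)
# plus, after joining, a time-ordered sequence of gaze samples.

#' Construct a track
#'
#' A track bundles one person's head boxes and gaze samples over a session.
#' At most one box per frame is allowed and frames are kept strictly
#' increasing.
#'
#' @param track_id Identifier (coerced to character).
#' @param boxes Data frame with columns `frame`, `cx`, `cy`, `w`, `h`
#'   (an optional `person` column records the raw per-frame detection index
#'   used to join gaze rows).
#' @param gaze Optional data frame with columns `frame`, `gx`, `gy`, `gz`.
#' @param role One of `"child"`, `"therapist"`, `"unknown"`.
#' @return An object of class `eyec_track`.
#' @export
new_track <- function(track_id, boxes, gaze = NULL, role = "unknown") {
  stopifnot(is.data.frame(boxes),
            all(c("frame", "cx", "cy", "w", "h") %in% names(boxes)))
  role <- match.arg(role, c("child", "therapist", "unknown"))
  boxes <- boxes[order(boxes$frame), , drop = FALSE]
  if (anyDuplicated(boxes$frame)) stop_eyec("track has duplicate frames")
  rownames(boxes) <- NULL
  structure(list(track_id = as.character(track_id), role = role,
                 boxes = boxes, gaze = gaze),
            class = "eyec_track")
}

#' @export
print.eyec_track <- function(x, ...) {
  cat(sprintf("<eyec_track %s role=%s boxes=%d gaze=%s>\n", x$track_id,
              x$role, nrow(x$boxes),
              if (is.null(x$gaze)) "none" else nrow(x$gaze)))
  invisible(x)
}

#' Enlarge head boxes about their centre
#'
#' Multiplies box width and height by `1 + factor`, keeping the centre
#' fixed. The default enlargement of 50 percent gives the gaze estimator a
#' larger head crop, which stabilises gaze prediction when heads are small.
#'
#' @param b A boxes data frame (columns `w`, `h`), a box list from
#'   [head_box_from_keypoints()], or an `eyec_track`.
#' @param factor Fractional enlargement, greater than -1; default 0.5.
#' @return The same kind of object with scaled `w` and `h`.
#' @export
enlarge_box <- function(b, factor = 0.5) {
  if (!is_number(factor) || factor <= -1) {
    stop_eyec("`factor` must be a finite number > -1")
  }
  scale_wh <- function(x) { x$w <- x$w * (1 + factor); x$h <- x$h * (1 + factor); x }
  if (inherits(b, "eyec_track")) {
    b$boxes <- scale_wh(b$boxes)
    return(b)
  }
  scale_wh(b)
}

#' Normalise head-box sizes over short frame sequences
#'
#' Within each maximal run of consecutive frames, boxes are grouped into
#' consecutive non-overlapping sequences of `window_frames` frames, and
#' every box in a sequence takes the maximum width and maximum height
#' recorded in that sequence, keeping its original centre. This forces a
#' matched head-crop dimension over short sequences, counteracting the
#' rapid box-size fluctuation that detection produces during dynamic
#' interaction. Maxima never propagate across detection gaps, and the
#' operation is idempotent for a fixed window.
#'
#' @param t An `eyec_track` or a boxes data frame with a `frame` column.
#' @param window_frames Sequence length in frames (default 25, i.e. 1 s at
#'   25 fps); a window of 1 leaves the input unchanged.
#' @return The input with normalised `w`, `h`.
#' @export
normalize_box_sizes <- function(t, window_frames = 25) {
  if (!is_count(window_frames, min = 1L)) {
    stop_eyec("`window_frames` must be an integer >= 1")
  }
  if (inherits(t, "eyec_track")) {
    t$boxes <- normalize_box_sizes(t$boxes, window_frames)
    return(t)
  }
  stopifnot(is.data.frame(t), all(c("frame", "w", "h") %in% names(t)))
  if (nrow(t) < 2L || window_frames == 1L) return(t)
  t <- t[order(t$frame), , drop = FALSE]
  run_id <- cumsum(c(1L, diff(t$frame) != 1L))
  for (r in split(seq_len(nrow(t)), run_id)) {
    blk <- (seq_along(r) - 1L) %/% window_frames
    t$w[r] <- ave(t$w[r], blk, FUN = max)
    t$h[r] <- ave(t$h[r], blk, FUN = max)
  }
  t
}

box_iou <- function(a, b) {
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

#' Associate per-frame detections into person tracks
#'
#' Greedy frame-to-frame association: each frame's detections are matched to
#' the live track whose most recent box has the largest
#' intersection-over-union; detections with zero overlap against every track
#' fall back to the nearest box centre. Unmatched detections start new
#' tracks. Tracks supported by fewer than `min_track_len` frames in total
#' are dropped as spurious flicker.
#'
#' @param boxes Data frame from [head_boxes()] (columns `frame`, `person`,
#'   `cx`, `cy`, `w`, `h`).
#' @param min_track_len Minimum number of boxes for a track to survive
#'   (default 25).
#' @return A list of `eyec_track` objects, longest first.
#' @export
track_persons <- function(boxes, min_track_len = 25) {
  stopifnot(is.data.frame(boxes),
            all(c("frame", "person", "cx", "cy", "w", "h") %in% names(boxes)))
  tracks <- list()   # each: list(last = one-row df, rows = list of row dfs)
  for (f in sort(unique(boxes$frame))) {
    det <- boxes[boxes$frame == f, , drop = FALSE]
    n_det <- nrow(det); n_trk <- length(tracks)
    assigned_det <- rep(FALSE, n_det)
    assigned_trk <- rep(FALSE, n_trk)
    if (n_trk > 0L && n_det > 0L) {
      iou <- matrix(0, n_det, n_trk)
      cdist <- matrix(0, n_det, n_trk)
      for (ti in seq_len(n_trk)) {
        last <- tracks[[ti]]$last
        iou[, ti] <- box_iou(det, last)
        cdist[, ti] <- sqrt((det$cx - last$cx)^2 + (det$cy - last$cy)^2)
      }
      # pass 1: greedy by descending overlap
      repeat {
        m <- which(iou == max(iou) & iou > 0, arr.ind = TRUE)
        if (max(iou) <= 0 || nrow(m) == 0L) break
        d <- m[1, 1]; ti <- m[1, 2]
        assigned_det[d] <- TRUE; assigned_trk[ti] <- TRUE
        tracks[[ti]]$last <- det[d, , drop = FALSE]
        tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <- det[d, , drop = FALSE]
        iou[d, ] <- -Inf; iou[, ti] <- -Inf
        cdist[d, ] <- Inf; cdist[, ti] <- Inf
      }
      # pass 2: greedy by ascending centre distance for zero-overlap pairs
      while (any(!assigned_det) && any(!assigned_trk)) {
        m <- which(cdist == min(cdist), arr.ind = TRUE)
        d <- m[1, 1]; ti <- m[1, 2]
        assigned_det[d] <- TRUE; assigned_trk[ti] <- TRUE
        tracks[[ti]]$last <- det[d, , drop = FALSE]
        tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <- det[d, , drop = FALSE]
        cdist[d, ] <- Inf; cdist[, ti] <- Inf
      }
    }
    for (d in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <-
        list(last = det[d, , drop = FALSE], rows = list(det[d, , drop = FALSE]))
    }
  }
  kept <- Filter(function(t) length(t$rows) >= min_track_len, tracks)
  kept <- kept[order(vapply(kept, function(t) length(t$rows), 0L),
                     decreasing = TRUE)]
  lapply(seq_along(kept), function(i) {
    new_track(track_id = as.character(i - 1L),
              boxes = do.call(rbind, kept[[i]]$rows))
  })
}

#' Assign child/therapist roles to a tracked dyad
#'
#' With an explicit `hint` (named list or vector mapping `track_id` to
#' `"child"`/`"therapist"`) roles are pinned. Otherwise a size heuristic is
#' used on exactly two tracks: the track with the larger median head-box
#' height is the adult (therapist), the other the child. When the medians
#' differ by less than 5 percent the assignment is ambiguous: both roles are
#' left `"unknown"` and a warning is raised.
#'
#' @param tracks List of `eyec_track`.
#' @param hint Optional named role mapping keyed by `track_id`.
#' @return The list of tracks with `role` fields set.
#' @export
assign_roles <- function(tracks, hint = NULL) {
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, TRUE, "eyec_track")))
  if (!is.null(hint)) {
    hint <- unlist(hint)
    for (i in seq_along(tracks)) {
      id <- tracks[[i]]$track_id
      if (id %in% names(hint)) {
        tracks[[i]]$role <- match.arg(hint[[id]],
                                      c("child", "therapist", "unknown"))
      }
    }
    return(tracks)
  }
  if (length(tracks) != 2L) {
    stop_eyec("role assignment needs exactly 2 tracks (got ", length(tracks),
              "); pass `hint` to pin roles explicitly")
  }
  med <- vapply(tracks, function(t) median(t$boxes$h), 0)
  if (abs(diff(med)) < 0.05 * max(med)) {
    warning("median head heights within 5%; roles left unknown", call. = FALSE)
    tracks[[1]]$role <- tracks[[2]]$role <- "unknown"
    return(tracks)
  }
  adult <- which.max(med)
  tracks[[adult]]$role <- "therapist"
  tracks[[-adult + 3L]]$role <- "child"
  tracks
}

#' Flatten tracks into a head-box table
#'
#' @param tracks List of `eyec_track`.
#' @return Data frame with columns `frame`, `track_id`, `role`, `cx`, `cy`,
#'   `w`, `h`, suitable for CSV export.
#' @export
headbox_table <- function(tracks) {
  out <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(frame = t$boxes$frame, track_id = t$track_id, role = t$role,
               cx = t$boxes$cx, cy = t$boxes$cy, w = t$boxes$w, h = t$boxes$h)
  }))
  out[order(out$frame, out$track_id), , drop = FALSE]
}
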