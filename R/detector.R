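# Mutual-gaze geometry and eye-contact event segmentation.
#
# A subject "looks at" the other when the projection of their gaze ray into
# the image passes close to the other's head-box centre: the gaze ray from
# the looker's head centre is intersected with the vertical line through
# the target's centre, and the distance d between that intersection and
# the centre (a vertical pixel offset, since both points share the
# target's x) must not exceed a box-relative threshold. Depth is handled
# through the z components: gazes aligned at clearly different depths must
# have opposite z signs, while near-zero z (same room depth) waives the
# sign requirement. Contact frames are segmented into events with a
# minimum duration.

#' Detector parameters
#'
#' @param td_fraction Maximum gaze-to-head distance as a fraction of the
#'   looked-at head-box size (`max(w, h)`); default 0.8.
#' @param tz Depth tolerance: when `|z|` of either gaze is at or below
#'   `tz` the opposite-sign depth rule is waived; default 0.3.
#' @param min_duration_frames Minimum event length in consecutive frames;
#'   default 25 (1 s at 25 fps).
#' @param gap_bridge_frames Non-contact gaps of at most this many frames
#'   between contact runs are bridged before the duration filter; default 0
#'   (no bridging). Bridging is a sensitivity/robustness knob, e.g. to ride
#'   over single-frame detection dropouts.
#' @return An object of class `eyec_params`.
#' @export
detector_params <- function(td_fraction = 0.8, tz = 0.3,
                            min_duration_frames = 25, gap_bridge_frames = 0) {
  if (!is_number(td_fraction) || td_fraction <= 0) {
    stop_eyec("`td_fraction` must be > 0")
  }
  if (!is_number(tz) || tz < 0 || tz > 1) stop_eyec("`tz` must be in [0, 1]")
  if (!is_count(min_duration_frames, 1L)) {
    stop_eyec("`min_duration_frames` must be an integer >= 1")
  }
  if (!is_count(gap_bridge_frames, 0L)) {
    stop_eyec("`gap_bridge_frames` must be an integer >= 0")
  }
  structure(list(td_fraction = td_fraction, tz = tz,
                 min_duration_frames = as.integer(min_duration_frames),
                 gap_bridge_frames = as.integer(gap_bridge_frames)),
            class = "eyec_params")
}

#' @export
print.eyec_params <- function(x, ...) {
  cat(sprintf("<eyec_params td=%.3g tz=%.3g min_dur=%d gap=%d>\n",
              x$td_fraction, x$tz, x$min_duration_frames,
              x$gap_bridge_frames))
  invisible(x)
}

#' Intersection of a gaze ray with a vertical target line
#'
#' Intersects the image-plane ray from `origin` along the (x, y) components
#' of gaze `g` with the vertical line x = `target_x`. Ray (not line)
#' semantics: when the gaze's x component is zero, or points away from the
#' target line, there is no intersection — a subject looking directly away
#' cannot hit a target behind their facing direction.
#'
#' @param origin Numeric `(x, y)` pixel position of the looker's head
#'   centre.
#' @param g Numeric gaze vector; only `g[1]` (x) and `g[2]` (y) are used.
#' @param target_x The x coordinate of the target's head-box centre.
#' @return Numeric `(x, y)` intersection point, or `NULL` when the ray
#'   cannot reach the line.
#' @examples
#' gaze_intersection(c(100, 100), c(0.707, 0.707, 0), 200)  # (200, 200)
#' @export
gaze_intersection <- function(origin, g, target_x) {
  gx <- g[[1]]; gy <- g[[2]]
  if (gx == 0 || (target_x - origin[[1]]) * gx <= 0) return(NULL)
  p_y <- origin[[2]] + gy / gx * (target_x - origin[[1]])
  c(target_x, p_y)
}

#' Gaze-to-head distance
#'
#' Pixel distance between a gaze-ray intersection point and the looked-at
#' head-box centre. Because the intersection lies on the vertical line
#' through the target centre, the distance reduces to the absolute vertical
#' offset. A missing intersection (gaze pointing away) has distance
#' `+Inf` by convention, so it can never fall under a finite threshold.
#'
#' @param p Intersection from [gaze_intersection()], or `NULL`.
#' @param g0_target Numeric `(x, y)` target head-box centre.
#' @return Distance in pixels (possibly `Inf`).
#' @export
gaze_distance <- function(p, g0_target) {
  if (is.null(p)) return(Inf)
  abs(p[[2]] - g0_target[[2]])
}

#' Depth compatibility of two gaze vectors
#'
#' Two subjects looking at each other from different room depths must have
#' z components of opposite sign; when either `|z|` is within the tolerance
#' `tz` the pair is at (nearly) the same depth and small estimation
#' fluctuations around zero would make the sign test unreliable, so the
#' opposite-sign requirement is waived. Vectorised over `zA`, `zB`.
#'
#' @param zA,zB z components of the two gaze vectors, in `[-1, 1]`.
#' @param tz Depth tolerance in `[0, 1]`.
#' @return Logical vector.
#' @export
depth_compatible <- function(zA, zB, tz = 0.3) {
  abs(zA) <= tz | abs(zB) <= tz | sign(zA) == -sign(zB)
}

# Vectorised child->therapist (and vice versa) distance over dyad frames.
ray_distance_vec <- function(ox, oy, gx, gy, tx, ty) {
  d <- rep(Inf, length(ox))
  ok <- !is.na(gx) & !is.na(ox) & !is.na(tx) & gx != 0
  ok[ok] <- (tx[ok] - ox[ok]) * gx[ok] > 0
  d[ok] <- abs(oy[ok] + gy[ok] / gx[ok] * (tx[ok] - ox[ok]) - ty[ok])
  d[is.na(ox) | is.na(gx) | is.na(tx)] <- NA_real_
  d
}

#' Build per-frame dyad state from two tracks
#'
#' Aligns the child and therapist tracks on the full consecutive frame
#' range they jointly span and assembles one row per frame holding both
#' boxes and both gaze vectors (NA where missing).
#'
#' @param child,therapist `eyec_track` objects with gaze joined.
#' @return Data frame with columns `frame`, box columns (`*_c`, `*_t`) and
#'   gaze columns, one row per frame in the covered range.
#' @export
build_dyad_frames <- function(child, therapist) {
  stopifnot(inherits(child, "eyec_track"), inherits(therapist, "eyec_track"))
  lo <- min(child$boxes$frame, therapist$boxes$frame)
  hi <- max(child$boxes$frame, therapist$boxes$frame)
  frames <- seq.int(lo, hi)
  df <- data.frame(frame = frames)
  pull <- function(track, suffix) {
    i <- match(frames, track$boxes$frame)
    df[[paste0("cx_", suffix)]] <<- track$boxes$cx[i]
    df[[paste0("cy_", suffix)]] <<- track$boxes$cy[i]
    df[[paste0("w_", suffix)]] <<- track$boxes$w[i]
    df[[paste0("h_", suffix)]] <<- track$boxes$h[i]
    if (!is.null(track$gaze) && nrow(track$gaze) > 0L) {
      j <- match(frames, track$gaze$frame)
      df[[paste0("gx_", suffix)]] <<- track$gaze$gx[j]
      df[[paste0("gy_", suffix)]] <<- track$gaze$gy[j]
      df[[paste0("gz_", suffix)]] <<- track$gaze$gz[j]
    } else {
      df[[paste0("gx_", suffix)]] <<- NA_real_
      df[[paste0("gy_", suffix)]] <<- NA_real_
      df[[paste0("gz_", suffix)]] <<- NA_real_
    }
  }
  pull(child, "c")
  pull(therapist, "t")
  df
}

#' Per-frame contact decision
#'
#' Computes, for every dyad frame, the two gaze-to-head distances, the
#' depth flag, and the contact flag. Contact requires (1) both distances at
#' or below `td_fraction` times the looked-at subject's head-box size
#' (`max(w, h)`), and (2) depth-compatible z components. The flag is `NA`
#' (undefined) whenever either box or either gaze is missing; undefined
#' frames never count as contact.
#'
#' @param frames Data frame from [build_dyad_frames()].
#' @param params [detector_params()].
#' @return `frames` with columns `d_child` (child gaze to therapist head),
#'   `d_therapist`, `depth_ok`, `contact` added.
#' @export
frame_contact <- function(frames, params = detector_params()) {
  stopifnot(inherits(params, "eyec_params"))
  d_child <- ray_distance_vec(frames$cx_c, frames$cy_c, frames$gx_c,
                              frames$gy_c, frames$cx_t, frames$cy_t)
  d_ther <- ray_distance_vec(frames$cx_t, frames$cy_t, frames$gx_t,
                             frames$gy_t, frames$cx_c, frames$cy_c)
  size_t <- pmax(frames$w_t, frames$h_t)
  size_c <- pmax(frames$w_c, frames$h_c)
  depth_ok <- depth_compatible(frames$gz_c, frames$gz_t, params$tz)
  defined <- !is.na(frames$cx_c) & !is.na(frames$cx_t) &
    !is.na(frames$gx_c) & !is.na(frames$gx_t)
  contact <- d_child <= params$td_fraction * size_t &
    d_ther <= params$td_fraction * size_c & depth_ok
  contact[!defined] <- NA
  depth_ok[!defined] <- NA
  frames$d_child <- d_child
  frames$d_therapist <- d_ther
  frames$depth_ok <- depth_ok
  frames$contact <- contact
  frames
}

#' Segment per-frame contact flags into events
#'
#' Finds maximal runs of contact frames (undefined flags count as
#' non-contact), optionally bridges non-contact gaps of at most
#' `gap_bridge_frames` between runs, and keeps runs of at least
#' `min_duration_frames` as events. Event bounds are inclusive; the
#' duration in frames is `end - start + 1`.
#'
#' @param flags Logical vector of per-frame contact (NA allowed).
#' @param params [detector_params()].
#' @param fps Frame rate, used to convert frame counts to seconds.
#' @param start_frame Frame index of `flags[1]` (default 0).
#' @return Data frame with columns `start_frame`, `end_frame`, `n_frames`,
#'   `duration_s`, events disjoint and time-ordered.
#' @export
segment_events <- function(flags, params = detector_params(), fps = 25,
                           start_frame = 0) {
  if (!is_number(fps) || fps <= 0) stop_eyec("`fps` must be > 0")
  stopifnot(inherits(params, "eyec_params"))
  runs <- true_runs(flags)
  if (nrow(runs) > 1L && params$gap_bridge_frames > 0L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= params$gap_bridge_frames) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= params$min_duration_frames, ,
               drop = FALSE]
  n <- runs$end - runs$start + 1L
  data.frame(start_frame = runs$start - 1L + start_frame,
             end_frame = runs$end - 1L + start_frame,
             n_frames = n, duration_s = n / fps)
}

#' Rasterise events back to per-frame flags
#'
#' @param events Event table from [segment_events()] or
#'   [detect_eye_contact()].
#' @param n_frames Length of the output vector.
#' @param start_frame Frame index of position 1 (default 0).
#' @return Logical vector of length `n_frames`.
#' @export
flags_from_events <- function(events, n_frames, start_frame = 0) {
  out <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(events))) {
    a <- events$start_frame[i] - start_frame + 1L
    b <- events$end_frame[i] - start_frame + 1L
    a <- max(a, 1L); b <- min(b, n_frames)
    if (a <= b) out[a:b] <- TRUE
  }
  out
}

#' Detect eye-contact events between two tracks
#'
#' Runs the full per-frame geometry and event segmentation for a dyad. The
#' per-frame contact flag is symmetric in the two subjects; the `mean_d`
#' reported per event is the mean child-side distance (child gaze to
#' therapist head centre) over the event's frames with a defined, finite
#' distance.
#'
#' @param child,therapist `eyec_track` objects with gaze joined (see
#'   [join_tracks()]).
#' @param params [detector_params()].
#' @param fps Frame rate (frames/s).
#' @return List with `frames` (per-frame dyad table including `d_child`,
#'   `d_therapist`, `depth_ok`, `contact`) and `events` (with `mean_d`).
#' @export
detect_eye_contact <- function(child, therapist, params = detector_params(),
                               fps = 25) {
  if (nrow(child$boxes) == 0L || nrow(therapist$boxes) == 0L) {
    stop_eyec("both tracks must be non-empty")
  }
  frames <- frame_contact(build_dyad_frames(child, therapist), params)
  if (!any(!is.na(frames$contact))) {
    warning("zero overlapping defined frames; returning empty outputs",
            call. = FALSE)
  }
  events <- segment_events(frames$contact, params, fps,
                           start_frame = frames$frame[1])
  events$mean_d <- vapply(seq_len(nrow(events)), function(i) {
    sel <- frames$frame >= events$start_frame[i] &
      frames$frame <= events$end_frame[i]
    d <- frames$d_child[sel]
    d <- d[!is.na(d) & is.finite(d)]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, 0)
  list(frames = frames, events = events)
}
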