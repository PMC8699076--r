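# 3-D gaze samples in the camera-centred Cartesian convention of
# appearance-based gaze estimators: g = (x, y, z) is a unit direction with
# x rightward, y downward in the image, and z < 0 pointing toward the
# camera, so g = (0, 0, -1) means looking straight into the lens. The
# detector uses only the direction; magnitudes are discarded on read.

#' Read a gaze table
#'
#' Reads per-frame per-person 3-D gaze vectors from a CSV with header
#' `frame,track_id,gx,gy,gz`. Vectors are renormalised to unit length;
#' zero-norm rows carry no direction and are dropped with a warning.
#'
#' @param path CSV file path.
#' @return Data frame with columns `frame`, `track_id`, `gx`, `gy`, `gz`,
#'   each vector of unit norm.
#' @export
read_gaze <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "track_id", "gx", "gy", "gz")
  if (!all(need %in% names(g))) {
    stop_eyec("gaze table must have columns ", paste(need, collapse = ","),
              "; missing: ", paste(setdiff(need, names(g)), collapse = ","))
  }
  normalize_gaze(g[need])
}

normalize_gaze <- function(g) {
  nrm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  bad <- !is.finite(nrm) | nrm == 0
  if (any(bad)) {
    warning(sum(bad), " zero-norm gaze row(s) dropped", call. = FALSE)
    g <- g[!bad, , drop = FALSE]
    nrm <- nrm[!bad]
  }
  g$gx <- g$gx / nrm; g$gy <- g$gy / nrm; g$gz <- g$gz / nrm
  rownames(g) <- NULL
  g
}

#' Write a gaze table
#'
#' @param gaze Data frame with columns `frame`, `track_id`, `gx`, `gy`, `gz`.
#' @param path Output CSV path.
#' @export
write_gaze <- function(gaze, path) {
  write.csv(gaze, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach gaze samples to tracks
#'
#' Joins a gaze table to a set of tracks. Rows are matched by `track_id`
#' when the identifiers resolve to track ids; otherwise, when the gaze rows
#' are keyed by the raw per-frame person index (the index of the head crop
#' that produced them), set `by = "person"` and rows are matched through
#' each track's `(frame, person)` provenance. Frames with a box but no gaze
#' row remain gaze-undefined. Duplicate `(frame, id)` rows resolve
#' last-wins with a warning.
#'
#' @param tracks List of `eyec_track`.
#' @param gaze Gaze table (see [read_gaze()]).
#' @param by `"track_id"` (default) or `"person"`.
#' @return The tracks with `gaze` data frames (`frame`, `gx`, `gy`, `gz`)
#'   populated.
#' @export
join_tracks <- function(tracks, gaze, by = c("track_id", "person")) {
  by <- match.arg(by)
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, TRUE, "eyec_track")))
  gaze <- normalize_gaze(gaze)
  if (by == "track_id") {
    known <- vapply(tracks, function(t) t$track_id, "")
    missing_ids <- setdiff(unique(as.character(gaze$track_id)), known)
    if (length(missing_ids) > 0L) {
      stop_eyec("gaze rows reference unknown track id(s): ",
                paste(missing_ids, collapse = ", "))
    }
  }
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    if (by == "track_id") {
      rows <- gaze[as.character(gaze$track_id) == t$track_id, , drop = FALSE]
    } else {
      if (!"person" %in% names(t$boxes)) {
        stop_eyec("tracks carry no `person` provenance; cannot join by person index")
      }
      key_box <- paste(t$boxes$frame, t$boxes$person)
      key_gaze <- paste(gaze$frame, gaze$track_id)
      rows <- gaze[key_gaze %in% key_box, , drop = FALSE]
    }
    if (anyDuplicated(rows$frame)) {
      warning("duplicate gaze rows for track ", t$track_id,
              "; keeping the last of each frame", call. = FALSE)
      rows <- rows[!duplicated(rows$frame, fromLast = TRUE), , drop = FALSE]
    }
    rows <- rows[order(rows$frame), c("frame", "gx", "gy", "gz"), drop = FALSE]
    rownames(rows) <- NULL
    tracks[[i]]$gaze <- rows
  }
  tracks
}
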