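# Keypoint ingestion.
#
# Image coordinate convention used throughout the package: origin at the
# top-left corner, x rightward, y downward, units of pixels, frame indices
# 0-based. Keypoint confidences lie in [0, 1]; a confidence of exactly 0
# marks a missing keypoint whose coordinates are ignored.

# body_25 indices (0-based) of the six keypoints the pipeline uses.
BODY25_HEAD_PARTS <- c(
  nose = 0L, neck = 1L,
  eye_R = 15L, eye_L = 16L,
  ear_R = 17L, ear_L = 18L
)

FACIAL_PARTS <- c("nose", "eye_L", "eye_R", "ear_L", "ear_R")

#' Read OpenPose-style body keypoints
#'
#' Reads multi-person 2-D body keypoints in the OpenPose body_25 JSON layout
#' and keeps the six head/neck keypoints (nose, neck, both eyes, both ears)
#' that head-box construction uses. The source is either a directory of
#' per-frame JSON files (frame index parsed from the last run of digits in
#' each file name, OpenPose's zero-padded convention) or a JSON-lines file
#' with one frame object per line carrying an explicit `frame_index`.
#'
#' Each person in a frame contributes a flat numeric array of 75 values
#' (25 keypoints times x, y, confidence). Keypoints with confidence 0 are
#' treated as missing and dropped.
#'
#' @param path Directory of per-frame `*.json` files, or a `.jsonl` file.
#' @param fps Frame rate of the source video (frames/s); stored as an
#'   attribute for downstream duration computations.
#' @return A data frame with columns `frame`, `person`, `part`, `x`, `y`,
#'   `conf`, one row per detected head/neck keypoint, with attribute `fps`.
#' @examples
#' dir <- tempfile(); scn <- simulate_scene(scene_config(seed = 1, n_frames = 30))
#' write_scene(scn, dir)
#' kp <- read_keypoints(file.path(dir, "keypoints"), fps = 25)
#' head(kp)
#' @export
read_keypoints <- function(path, fps = 25) {
  if (length(path) != 1L || !is.character(path)) {
    stop_eyec("`path` must be a single directory or file path")
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0L) stop_eyec("no .json files found under ", path)
    frames <- lapply(files, function(f) {
      idx <- frame_index_from_name(basename(f))
      obj <- tryCatch(jsonlite::read_json(f, simplifyVector = FALSE),
                      error = function(e) {
                        stop_eyec("malformed JSON in frame file ", basename(f),
                                  ": ", conditionMessage(e))
                      })
      parse_frame_people(obj$people, idx, where = basename(f))
    })
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    frames <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                      error = function(e) {
                        stop_eyec("malformed JSON at line ", i, ": ",
                                  conditionMessage(e))
                      })
      idx <- if (!is.null(obj$frame_index)) as.integer(obj$frame_index) else i - 1L
      parse_frame_people(obj$people, idx, where = paste0("line ", i))
    })
  } else {
    stop_eyec("keypoint source not found: ", path)
  }
  out <- do.call(rbind, frames)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), person = integer(),
                      part = character(), x = numeric(), y = numeric(),
                      conf = numeric())
  }
  rownames(out) <- NULL
  attr(out, "fps") <- fps
  out
}

frame_index_from_name <- function(name) {
  m <- regmatches(name, gregexpr("[0-9]+", name))[[1]]
  if (length(m) == 0L) stop_eyec("cannot parse a frame index from file name ", name)
  as.integer(m[[length(m)]])
}

parse_frame_people <- function(people, frame_index, where) {
  if (is.null(people) || length(people) == 0L) return(NULL)
  rows <- lapply(seq_along(people), function(p) {
    kp <- unlist(people[[p]]$pose_keypoints_2d, use.names = FALSE)
    if (length(kp) != 75L) {
      stop_eyec("unsupported keypoint layout in ", where, ": expected 75 ",
                "values per person (body_25), got ", length(kp))
    }
    i <- BODY25_HEAD_PARTS            # 0-based keypoint indices
    x <- kp[3L * i + 1L]
    y <- kp[3L * i + 2L]
    conf <- kp[3L * i + 3L]
    keep <- conf > 0
    if (!any(keep)) return(NULL)
    data.frame(frame = frame_index, person = p - 1L,
               part = names(i)[keep], x = x[keep], y = y[keep],
               conf = conf[keep])
  })
  do.call(rbind, rows)
}

#' Head bounding box from one person's keypoints
#'
#' Builds an axis-aligned head bounding box from the facial keypoints of a
#' single person in a single frame. The box is the bounding rectangle of all
#' present facial keypoints (nose, eyes, ears). When fewer than two facial
#' keypoints are present the head is underdetermined and `NULL` is returned.
#' When the neck is present the box height is floored at 0.8 times the
#' nose-to-neck distance (ear/eye extents alone underestimate head height in
#' profile views); the floor grows the box symmetrically about its centre.
#'
#' @param k Data frame with columns `part`, `x`, `y` (and optionally `conf`)
#'   for one person in one frame, as one group of [read_keypoints()] output.
#' @return A list with elements `cx`, `cy`, `w`, `h` (pixels), or `NULL`.
#' @examples
#' k <- data.frame(part = c("ear_L", "ear_R", "nose", "eye_L", "eye_R"),
#'                 x = c(90, 110, 100, 96, 104), y = c(100, 100, 108, 98, 98))
#' head_box_from_keypoints(k)
#' @export
head_box_from_keypoints <- function(k) {
  stopifnot(is.data.frame(k), all(c("part", "x", "y") %in% names(k)))
  if ("conf" %in% names(k)) k <- k[k$conf > 0, , drop = FALSE]
  face <- k[k$part %in% FACIAL_PARTS, , drop = FALSE]
  if (nrow(face) < 2L) return(NULL)
  xr <- range(face$x); yr <- range(face$y)
  w <- xr[2] - xr[1]
  h <- yr[2] - yr[1]
  cx <- mean(xr); cy <- mean(yr)
  nose <- k[k$part == "nose", , drop = FALSE]
  neck <- k[k$part == "neck", , drop = FALSE]
  if (nrow(nose) == 1L && nrow(neck) == 1L) {
    nn <- sqrt((nose$x - neck$x)^2 + (nose$y - neck$y)^2)
    h <- max(h, 0.8 * nn)
  }
  # degenerate extents (collinear keypoints) are given a 1 px floor so the
  # box always has positive area
  list(cx = cx, cy = cy, w = max(w, 1), h = max(h, 1))
}

#' Head boxes for every person in every frame
#'
#' Vectorised application of the [head_box_from_keypoints()] rule across a
#' keypoint table.
#'
#' @param kp Keypoint table from [read_keypoints()].
#' @return Data frame with columns `frame`, `person`, `cx`, `cy`, `w`, `h`;
#'   persons whose head is underdetermined in a frame are absent.
#' @export
head_boxes <- function(kp) {
  stopifnot(is.data.frame(kp))
  empty <- data.frame(frame = integer(), person = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric())
  if (nrow(kp) == 0L) return(empty)
  if ("conf" %in% names(kp)) kp <- kp[kp$conf > 0, , drop = FALSE]
  face <- kp[kp$part %in% FACIAL_PARTS, , drop = FALSE]
  if (nrow(face) == 0L) return(empty)
  key <- paste(face$frame, face$person)
  n_face <- tapply(face$x, key, length)
  keys <- names(n_face)[n_face >= 2L]     # < 2 facial points: no box
  if (length(keys) == 0L) return(empty)
  xmin <- tapply(face$x, key, min)[keys]
  xmax <- tapply(face$x, key, max)[keys]
  ymin <- tapply(face$y, key, min)[keys]
  ymax <- tapply(face$y, key, max)[keys]
  nose <- kp[kp$part == "nose", , drop = FALSE]
  neck <- kp[kp$part == "neck", , drop = FALSE]
  ni <- match(keys, paste(nose$frame, nose$person))
  ki <- match(keys, paste(neck$frame, neck$person))
  nn <- sqrt((nose$x[ni] - neck$x[ki])^2 + (nose$y[ni] - neck$y[ki])^2)
  h <- ymax - ymin
  has_nn <- !is.na(nn)
  h[has_nn] <- pmax(h[has_nn], 0.8 * nn[has_nn])
  first <- match(keys, key)
  out <- data.frame(frame = face$frame[first], person = face$person[first],
                    cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2,
                    w = pmax(xmax - xmin, 1), h = pmax(h, 1))
  out <- out[order(out$frame, out$person), , drop = FALSE]
  rownames(out) <- NULL
  out
}
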