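# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# A body_25 keypoint flat array (75 values) with the six head/neck parts
# set and every other keypoint zeroed.
body25_array <- function(nose = NULL, neck = NULL, eye_L = NULL,
                         eye_R = NULL, ear_L = NULL, ear_R = NULL) {
  arr <- numeric(75)
  put <- function(idx0, v) {
    if (!is.null(v)) arr[(3 * idx0 + 1):(3 * idx0 + 3)] <<- v
  }
  put(0, nose); put(1, neck); put(15, eye_R); put(16, eye_L)
  put(17, ear_R); put(18, ear_L)
  arr
}

write_keypoint_frame <- function(dir, frame, people_arrays) {
  jsonlite::write_json(
    list(version = 1.3,
         people = lapply(people_arrays, function(a) list(pose_keypoints_2d = a))),
    file.path(dir, sprintf("frame_%06d_keypoints.json", frame)),
    auto_unbox = TRUE, digits = NA)
}

# A five-point frontal face around (cx, cy) with a given half-width.
face_keypoints <- function(frame, person, cx, cy, half = 10, neck_drop = 32,
                           conf = 0.9) {
  data.frame(
    frame = frame, person = person,
    part = c("ear_L", "ear_R", "nose", "eye_L", "eye_R", "neck"),
    x = cx + c(-half, half, 0, -0.4 * half, 0.4 * half, 0),
    y = cy + c(0, 0, 0.8 * half, -0.2 * half, -0.2 * half, neck_drop),
    conf = conf)
}

# A random dyadic session at the geometry level: two fixed boxes, gaze
# vectors that aim at the partner with a random vertical offset fraction
# and random z, plus stretches of looking away. Used by invariance and
# monotonicity tests.
random_session <- function(seed, n = 150, size_c = 50, size_t = 70) {
  set.seed(seed)
  c_c <- c(runif(1, 100, 400), runif(1, 200, 500))
  c_t <- c(runif(1, 700, 1100), runif(1, 150, 450))
  frames <- 0:(n - 1)
  mk <- function(centre, size) {
    data.frame(frame = frames, cx = centre[1], cy = centre[2],
               w = size, h = size)
  }
  aim <- function(own, other, frac, z, away) {
    # away: gaze x points away from the partner
    dx <- (other[1] - own[1]) * ifelse(away, -1, 1)
    dy <- (other[2] + frac * 80 - own[2])
    n2 <- sqrt(dx^2 + dy^2)
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * dx / n2, s * dy / n2, z)
  }
  frac_c <- rnorm(n, 0, 0.8); frac_t <- rnorm(n, 0, 0.8)
  z_c <- runif(n, -0.8, 0.8); z_t <- runif(n, -0.8, 0.8)
  away_c <- runif(n) < 0.2; away_t <- runif(n) < 0.2
  gc <- aim(c_c, c_t, frac_c, z_c, away_c)
  gt <- aim(c_t, c_c, frac_t, z_t, away_t)
  child <- new_track("child", mk(c_c, size_c),
                     gaze = data.frame(frame = frames, gx = gc[, 1],
                                       gy = gc[, 2], gz = gc[, 3]),
                     role = "child")
  therapist <- new_track("therapist", mk(c_t, size_t),
                         gaze = data.frame(frame = frames, gx = gt[, 1],
                                           gy = gt[, 2], gz = gt[, 3]),
                         role = "therapist")
  list(child = child, therapist = therapist)
}

scale_track <- function(track, k) {
  track$boxes$cx <- track$boxes$cx * k
  track$boxes$cy <- track$boxes$cy * k
  track$boxes$w <- track$boxes$w * k
  track$boxes$h <- track$boxes$h * k
  track
}

# Naive reference segmentation: bridge gaps then scan runs with a loop.
naive_segment <- function(flags, min_dur, gap, fps = 25) {
  flags <- !is.na(flags) & flags
  n <- length(flags)
  # bridge: any FALSE gap of length <= gap strictly between TRUE frames
  if (gap > 0 && any(flags)) {
    out <- flags
    i <- 1L
    while (i <= n) {
      if (!flags[i]) {
        j <- i
        while (j <= n && !flags[j]) j <- j + 1L
        len <- j - i
        if (i > 1L && j <= n && len <= gap) out[i:(j - 1L)] <- TRUE
        i <- j
      } else i <- i + 1L
    }
    flags <- out
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j <= n && flags[j]) j <- j + 1L
      if (j - i >= min_dur) {
        starts <- c(starts, i - 1L); ends <- c(ends, j - 2L)
      }
      i <- j
    } else i <- i + 1L
  }
  data.frame(start_frame = starts, end_frame = ends,
             n_frames = ends - starts + 1L,
             duration_s = (ends - starts + 1L) / fps)
}

count_contacts <- function(session, params) {
  res <- detect_eye_contact(session$child, session$therapist, params)
  sum(res$frames$contact, na.rm = TRUE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
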