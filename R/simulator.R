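# Synthetic dyadic scenes with full ground truth.
#
# Two agents (child and therapist) are placed in a 3-D room in front of an
# ideal pinhole camera (origin at the camera, x rightward, y downward,
# z into the scene; a gaze direction with negative z points toward the
# camera). Heads are spheres carrying nose/eye/ear/neck keypoints at fixed
# angular offsets from the facing direction; keypoints facing away from
# the camera are occluded. During scheduled mutual-gaze episodes each
# agent's gaze is the exact unit vector toward the other's head centre;
# outside episodes agents dwell on random scene points kept angularly away
# from the partner's head. Angular gaze noise, head-box size jitter and
# per-frame detection dropout emulate the error modes of keypoint and gaze
# estimation on real video.

#' Scene configuration
#'
#' @param seed Integer seed; every random element of the scene flows from
#'   it.
#' @param n_frames Session length in frames (default 1500, i.e. 60 s at
#'   25 fps).
#' @param fps Frame rate (default 25).
#' @param image_size `(width, height)` in pixels (default 1280 x 720).
#' @param focal_px Pinhole focal length in pixels (default 900).
#' @param child_base,therapist_base 3-D head-centre base positions in
#'   metres (camera coordinates). Defaults place the two agents 1.6 m
#'   apart at the same 3 m camera depth.
#' @param head_radius_m Head radii in metres, `c(child, therapist)`;
#'   the adult head is larger so that the size-based role heuristic and
#'   box-relative thresholds are exercised.
#' @param sway_amp_m Amplitude of the deterministic sinusoidal head sway,
#'   per axis in metres. The default keeps depth (z) fixed so both agents
#'   stay at the same camera depth.
#' @param sway_period_frames Period of the sway (default 250).
#' @param episodes Integer matrix or data frame with columns `start`,
#'   `end` (0-based, inclusive) scheduling mutual-gaze episodes, or `NULL`
#'   to sample a schedule from the seed.
#' @param n_episodes,episode_frames When sampling a schedule: how many
#'   episodes and the inclusive range of their lengths in frames.
#' @param gaze_noise_deg Angular gaze noise, standard deviation in
#'   degrees (default 0).
#' @param box_jitter_frac Head-box size jitter: per-frame multiplicative
#'   keypoint-layout scale noise, standard deviation as a fraction of 1
#'   (default 0).
#' @param dropout_prob Per-frame per-person probability that detection
#'   fails entirely (no keypoints, no gaze) (default 0).
#' @return An object of class `eyec_scene_config`.
#' @export
scene_config <- function(seed = 1, n_frames = 1500, fps = 25,
                         image_size = c(1280, 720), focal_px = 900,
                         child_base = c(-0.8, 0.25, 3.0),
                         therapist_base = c(0.8, 0.05, 3.0),
                         head_radius_m = c(0.09, 0.12),
                         sway_amp_m = c(0.12, 0.04, 0),
                         sway_period_frames = 250,
                         episodes = NULL, n_episodes = 6,
                         episode_frames = c(30, 120),
                         gaze_noise_deg = 0, box_jitter_frac = 0,
                         dropout_prob = 0) {
  stopifnot(is_count(seed), is_count(n_frames, 1L), fps > 0,
            length(image_size) == 2L, focal_px > 0,
            length(child_base) == 3L, length(therapist_base) == 3L,
            length(head_radius_m) == 2L, all(head_radius_m > 0),
            gaze_noise_deg >= 0, box_jitter_frac >= 0,
            dropout_prob >= 0, dropout_prob < 1)
  if (sqrt(sum((child_base - therapist_base)^2)) < 4 * max(head_radius_m)) {
    stop_eyec("agents are (nearly) coincident; move the base positions apart")
  }
  if (!is.null(episodes)) {
    episodes <- as.data.frame(episodes)
    names(episodes)[1:2] <- c("start", "end")
    if (any(episodes$start > episodes$end) || any(episodes$start < 0) ||
        any(episodes$end >= n_frames)) {
      stop_eyec("episodes must satisfy 0 <= start <= end < n_frames")
    }
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 fps = fps, image_size = image_size, focal_px = focal_px,
                 child_base = child_base, therapist_base = therapist_base,
                 head_radius_m = head_radius_m, sway_amp_m = sway_amp_m,
                 sway_period_frames = sway_period_frames,
                 episodes = episodes, n_episodes = n_episodes,
                 episode_frames = episode_frames,
                 gaze_noise_deg = gaze_noise_deg,
                 box_jitter_frac = box_jitter_frac,
                 dropout_prob = dropout_prob),
            class = "eyec_scene_config")
}

unit3 <- function(v) v / sqrt(sum(v^2))

project_px <- function(p, focal_px, image_size) {
  c(image_size[1] / 2 + focal_px * p[1] / p[3],
    image_size[2] / 2 + focal_px * p[2] / p[3])
}

# Keypoint angular layout on the canonical head sphere: offsets from the
# facing direction F toward the lateral axis, in degrees.
HEAD_LAYOUT <- list(
  nose = c(yaw = 0, raise = 0),
  eye_L = c(yaw = 28, raise = 0.15), eye_R = c(yaw = -28, raise = 0.15),
  ear_L = c(yaw = 92, raise = 0), ear_R = c(yaw = -92, raise = 0)
)

sample_episode_schedule <- function(n_frames, n_episodes, episode_frames) {
  # non-contact padding around each episode; scaled down for short scenes
  pad <- min(50L, max(2L, n_frames %/% 12L))
  # shrink the episode count, then the lengths, until the schedule fits
  repeat {
    if (n_episodes < 1L) stop_eyec("session too short for any episode")
    max_len <- (n_frames - pad * (n_episodes + 1L)) %/% n_episodes
    if (max_len >= 2L) break
    n_episodes <- n_episodes - 1L
  }
  lo <- min(episode_frames[1], max_len)
  hi <- min(episode_frames[2], max_len)
  lens <- sample(lo:hi, n_episodes, replace = TRUE)
  slack <- n_frames - sum(lens) - pad * (n_episodes + 1L)
  cuts <- sort(sample.int(slack + 1L, n_episodes, replace = TRUE) - 1L)
  starts <- pad + cuts + c(0L, cumsum(head(lens, -1) + pad))
  data.frame(start = starts, end = starts + lens - 1L)
}

#' Simulate a dyadic scene
#'
#' Generates per-frame keypoints, a gaze table, and frame-level ground
#' truth for one synthetic session, deterministically from the config
#' seed. During mutual-gaze episodes the true gaze of each agent points
#' exactly at the other's head centre, so at zero noise the analytic gaze
#' distance of each agent is 0 on every episode frame (both agents sit at
#' equal camera depth by default), and the emitted z components are close
#' to 0.
#'
#' @param cfg A [scene_config()].
#' @return List of class `eyec_scene` with elements `config`, `episodes`
#'   (scheduled intervals), `keypoints` (long keypoint table as from
#'   [read_keypoints()]; person 0 is the child, 1 the therapist),
#'   `gaze` (per-frame per-person gaze table keyed by person index), and
#'   `truth` (per frame: `mutual` flag, true projected head centres and
#'   true gaze vectors for both agents).
#' @export
simulate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "eyec_scene_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_frames
    episodes <- cfg$episodes
    if (is.null(episodes)) {
      episodes <- sample_episode_schedule(n, cfg$n_episodes,
                                          cfg$episode_frames)
    }
    in_episode <- rep(FALSE, n)
    for (i in seq_len(nrow(episodes))) {
      in_episode[(episodes$start[i]:episodes$end[i]) + 1L] <- TRUE
    }

    phase <- runif(6, 0, 2 * pi)   # per-agent per-axis sway phases
    pos_at <- function(base, ph, f) {
      base + cfg$sway_amp_m * sin(2 * pi * f / cfg$sway_period_frames + ph)
    }
    centres <- list(
      child = t(vapply(0:(n - 1), function(f)
        pos_at(cfg$child_base, phase[1:3], f), numeric(3))),
      therapist = t(vapply(0:(n - 1), function(f)
        pos_at(cfg$therapist_base, phase[4:6], f), numeric(3)))
    )

    # Off-episode gaze targets: dwell on random scene points kept (a) more
    # than 15 degrees away from the partner's head direction in 3-D and
    # (b) with an image-projected gaze-to-head distance of several head
    # radii — a 3-D margin alone can hide deviation in depth whose
    # projected ray still crosses the partner's head, which would plant
    # geometric mutual gaze on frames the ground truth labels negative.
    sample_away_target <- function(own, partner, partner_radius_m) {
      to_partner <- unit3(partner - own)
      r_px <- cfg$focal_px * partner_radius_m / partner[3]
      own_px <- project_px(own, cfg$focal_px, cfg$image_size)
      par_px <- project_px(partner, cfg$focal_px, cfg$image_size)
      repeat {
        tgt <- c(runif(1, -2, 2), runif(1, -0.6, 1.6), runif(1, 0.8, 5.5))
        dir <- tgt - own
        if (sqrt(sum(dir^2)) < 0.3) next
        dir <- unit3(dir)
        if (sum(dir * to_partner) >= cos(15 * pi / 180)) next
        # projected ray distance at the partner's centre line
        if (dir[1] != 0 && (par_px[1] - own_px[1]) * dir[1] > 0) {
          p_y <- own_px[2] + dir[2] / dir[1] * (par_px[1] - own_px[1])
          if (abs(p_y - par_px[2]) <= 4 * r_px) next
        }
        return(tgt)
      }
    }

    noise_sd <- tan(cfg$gaze_noise_deg * pi / 180)
    gaze_true <- list(child = matrix(0, n, 3), therapist = matrix(0, n, 3))
    gaze_obs <- list(child = matrix(0, n, 3), therapist = matrix(0, n, 3))
    for (agent in c("child", "therapist")) {
      other <- if (agent == "child") "therapist" else "child"
      other_radius <- cfg$head_radius_m[if (agent == "child") 2L else 1L]
      dwell_left <- 0L
      tgt <- NULL
      for (f in seq_len(n)) {
        own <- centres[[agent]][f, ]
        partner <- centres[[other]][f, ]
        if (in_episode[f]) {
          g <- unit3(partner - own)
          dwell_left <- 0L
        } else {
          if (dwell_left <= 0L) {
            tgt <- sample_away_target(own, partner, other_radius)
            dwell_left <- sample(10:50, 1)
          }
          g <- unit3(tgt - own)
          dwell_left <- dwell_left - 1L
        }
        gaze_true[[agent]][f, ] <- g
      }
      obs <- gaze_true[[agent]]
      if (noise_sd > 0) {
        obs <- obs + matrix(rnorm(3L * n, 0, noise_sd), n, 3)
        obs <- obs / sqrt(rowSums(obs^2))
      }
      gaze_obs[[agent]] <- obs
    }

    dropout <- list(
      child = runif(n) < cfg$dropout_prob,
      therapist = runif(n) < cfg$dropout_prob
    )
    scale_jitter <- list(
      child = pmax(0.3, 1 + rnorm(n, 0, cfg$box_jitter_frac)),
      therapist = pmax(0.3, 1 + rnorm(n, 0, cfg$box_jitter_frac))
    )

    W2 <- cfg$image_size[1] / 2; H2 <- cfg$image_size[2] / 2
    fl <- cfg$focal_px
    kp_rows <- list()
    gz_rows <- list()
    truth_centres <- list()
    for (pi_ in 1:2) {
      agent <- c("child", "therapist")[pi_]
      C <- centres[[agent]]            # n x 3 true head centres
      truth_centres[[agent]] <- cbind(W2 + fl * C[, 1] / C[, 3],
                                      H2 + fl * C[, 2] / C[, 3])
      keep <- !dropout[[agent]]
      r <- cfg$head_radius_m[pi_] * scale_jitter[[agent]]
      # heads yaw toward the gaze target but pitch much less than the
      # eyes do, so the keypoint layout follows a pitch-damped facing
      G <- gaze_true[[agent]]
      Fd <- cbind(G[, 1], 0.3 * G[, 2], G[, 3])
      Fd <- Fd / sqrt(rowSums(Fd^2))
      lat <- cbind(Fd[, 3], 0, -Fd[, 1])         # cross((0,1,0), F)
      lnorm <- sqrt(rowSums(lat^2))
      lnorm[lnorm < 1e-8] <- 1
      lat <- lat / lnorm
      for (part in names(HEAD_LAYOUT)) {
        a <- HEAD_LAYOUT[[part]]
        yaw <- a[["yaw"]] * pi / 180
        P <- C + r * (cos(yaw) * Fd + sin(yaw) * lat)
        P[, 2] <- P[, 2] - r * a[["raise"]]
        normal <- (P - C) / sqrt(rowSums((P - C)^2))
        toward_cam <- -P / sqrt(rowSums(P^2))
        visible <- rowSums(normal * toward_cam) > -0.2
        sel <- keep & visible
        if (!any(sel)) next
        kp_rows[[length(kp_rows) + 1L]] <- data.frame(
          frame = which(sel) - 1L, person = pi_ - 1L, part = part,
          x = W2 + fl * P[sel, 1] / P[sel, 3],
          y = H2 + fl * P[sel, 2] / P[sel, 3], conf = 0.9)
      }
      neck_y <- C[, 2] + 1.5 * r                 # neck hangs below, always seen
      kp_rows[[length(kp_rows) + 1L]] <- data.frame(
        frame = which(keep) - 1L, person = pi_ - 1L, part = "neck",
        x = W2 + fl * C[keep, 1] / C[keep, 3],
        y = H2 + fl * neck_y[keep] / C[keep, 3], conf = 0.9)
      Gobs <- gaze_obs[[agent]]
      gz_rows[[pi_]] <- data.frame(frame = which(keep) - 1L,
                                   track_id = pi_ - 1L,
                                   gx = Gobs[keep, 1], gy = Gobs[keep, 2],
                                   gz = Gobs[keep, 3])
    }

    keypoints <- do.call(rbind, kp_rows)
    keypoints <- keypoints[order(keypoints$frame, keypoints$person), ,
                           drop = FALSE]
    rownames(keypoints) <- NULL
    attr(keypoints, "fps") <- cfg$fps
    gaze <- do.call(rbind, gz_rows)
    rownames(gaze) <- NULL
    truth <- data.frame(
      frame = 0:(n - 1), mutual = in_episode,
      cx_child = truth_centres$child[, 1], cy_child = truth_centres$child[, 2],
      cx_therapist = truth_centres$therapist[, 1],
      cy_therapist = truth_centres$therapist[, 2],
      gx_child = gaze_true$child[, 1], gy_child = gaze_true$child[, 2],
      gz_child = gaze_true$child[, 3],
      gx_therapist = gaze_true$therapist[, 1],
      gy_therapist = gaze_true$therapist[, 2],
      gz_therapist = gaze_true$therapist[, 3]
    )
    structure(list(config = cfg, episodes = episodes, keypoints = keypoints,
                   gaze = gaze, truth = truth),
              class = "eyec_scene")
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write a simulated scene to disk
#'
#' Emits the scene in the on-disk formats the ingest functions read: a
#' directory of per-frame OpenPose-style JSON keypoint files
#' (`keypoints/frame_NNNNNN_keypoints.json`), a `gaze.csv` table and a
#' `truth.csv` table.
#'
#' @param scene An `eyec_scene` from [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "eyec_scene"))
  kp_dir <- file.path(dir, "keypoints")
  dir.create(kp_dir, recursive = TRUE, showWarnings = FALSE)
  n <- scene$config$n_frames
  by_frame <- split(scene$keypoints, scene$keypoints$frame)
  for (f in 0:(n - 1)) {
    g <- by_frame[[as.character(f)]]
    people <- list()
    if (!is.null(g)) {
      for (p in sort(unique(g$person))) {
        arr <- numeric(75)
        rows <- g[g$person == p, , drop = FALSE]
        idx <- BODY25_HEAD_PARTS[rows$part]
        arr[3 * idx + 1] <- rows$x
        arr[3 * idx + 2] <- rows$y
        arr[3 * idx + 3] <- rows$conf
        people[[length(people) + 1L]] <- list(pose_keypoints_2d = arr)
      }
    }
    jsonlite::write_json(list(version = 1.3, people = people),
                         file.path(kp_dir, sprintf("frame_%06d_keypoints.json", f)),
                         auto_unbox = TRUE, digits = NA)
  }
  write_gaze(scene$gaze, file.path(dir, "gaze.csv"))
  write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Run the full detection pipeline on keypoints and gaze
#'
#' Convenience wrapper chaining ingest, tracking, role assignment, box-size
#' normalisation, gaze joining and detection. Head boxes used for the
#' detection geometry are size-normalised but not enlarged (enlargement
#' exists to hand bigger crops to a gaze estimator, not to move the
#' contact threshold).
#'
#' @param keypoints Keypoint table from [read_keypoints()] (or a path
#'   readable by it).
#' @param gaze Gaze table (or CSV path); keyed by per-frame person index
#'   (`by = "person"`) or by track id.
#' @param fps Frame rate.
#' @param params [detector_params()].
#' @param normalize_window Window for [normalize_box_sizes()]; default 25.
#' @param min_track_len Minimum track length for [track_persons()].
#' @param role_hint Optional role hint for [assign_roles()].
#' @param join_by How gaze rows are keyed; default `"person"`.
#' @return List with `tracks`, `frames`, `events` (see
#'   [detect_eye_contact()]).
#' @export
run_session <- function(keypoints, gaze, fps = 25,
                        params = detector_params(), normalize_window = 25,
                        min_track_len = 25, role_hint = NULL,
                        join_by = "person") {
  if (is.character(keypoints)) keypoints <- read_keypoints(keypoints, fps)
  if (is.character(gaze)) gaze <- read_gaze(gaze)
  boxes <- head_boxes(keypoints)
  tracks <- track_persons(boxes, min_track_len = min_track_len)
  # size-normalise before the role heuristic: frames where a subject faces
  # away yield degenerate boxes, and the blockwise maxima restore a
  # representative head size for the adult/child comparison
  tracks <- lapply(tracks, normalize_box_sizes, window_frames = normalize_window)
  tracks <- assign_roles(tracks, hint = role_hint)
  tracks <- join_tracks(tracks, gaze, by = join_by)
  roles <- vapply(tracks, function(t) t$role, "")
  if (!all(c("child", "therapist") %in% roles)) {
    stop_eyec("could not identify a child and a therapist track; ",
              "pass `role_hint`")
  }
  res <- detect_eye_contact(tracks[[which(roles == "child")[1]]],
                            tracks[[which(roles == "therapist")[1]]],
                            params, fps)
  c(list(tracks = tracks), res)
}
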