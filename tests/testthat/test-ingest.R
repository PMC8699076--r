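test_that("read_keypoints maps body_25 indices and the confidence-0 convention", {
  dir <- withr::local_tempdir()
  p1 <- body25_array(nose = c(100, 108, 0.9), neck = c(100, 140, 0.8),
                     eye_L = c(96, 98, 0.9), eye_R = c(104, 98, 0.9),
                     ear_L = c(90, 100, 0.7), ear_R = c(110, 100, 0.7))
  p2 <- body25_array(nose = c(500, 200, 0.9), eye_L = c(0, 0, 0),
                     eye_R = c(505, 195, 0.5))
  write_keypoint_frame(dir, 0, list(p1, p2))
  write_keypoint_frame(dir, 1, list(p1))
  kp <- read_keypoints(dir, fps = 25)

  expect_equal(sort(unique(kp$frame)), c(0L, 1L))
  expect_equal(length(unique(kp$person[kp$frame == 0])), 2L)
  # person 2's zero-confidence eye_L is missing
  f0p1 <- kp[kp$frame == 0 & kp$person == 1, ]
  expect_false("eye_L" %in% f0p1$part)
  expect_setequal(f0p1$part, c("nose", "eye_R"))
  # index mapping: nose=0, neck=1, eye_R=15, eye_L=16, ear_R=17, ear_L=18
  f0p0 <- kp[kp$frame == 0 & kp$person == 0, ]
  expect_equal(f0p0$x[f0p0$part == "nose"], 100)
  expect_equal(f0p0$y[f0p0$part == "neck"], 140)
  expect_equal(f0p0$x[f0p0$part == "eye_R"], 104)
  expect_equal(f0p0$x[f0p0$part == "eye_L"], 96)
  expect_equal(f0p0$x[f0p0$part == "ear_R"], 110)
  expect_equal(f0p0$x[f0p0$part == "ear_L"], 90)
  expect_equal(attr(kp, "fps"), 25)
})

test_that("read_keypoints rejects malformed JSON and unknown layouts", {
  dir <- withr::local_tempdir()
  writeLines("{not json", file.path(dir, "frame_000000_keypoints.json"))
  expect_error(read_keypoints(dir), "frame_000000")
  dir2 <- withr::local_tempdir()
  jsonlite::write_json(list(people = list(list(pose_keypoints_2d = 1:54))),
                       file.path(dir2, "frame_000000_keypoints.json"),
                       auto_unbox = TRUE)
  expect_error(read_keypoints(dir2), "layout")
})

test_that("head box construction follows the facial bounding-box rule", {
  # underdetermined: a single keypoint
  expect_null(head_box_from_keypoints(
    data.frame(part = "nose", x = 100, y = 108)))
  # bounding box of listed facial points, no neck
  k <- data.frame(part = c("ear_L", "ear_R", "nose", "eye_L", "eye_R"),
                  x = c(90, 110, 100, 96, 104), y = c(100, 100, 108, 98, 98))
  b <- head_box_from_keypoints(k)
  expect_equal(b$cx, 100); expect_equal(b$cy, 103)
  expect_equal(b$w, 20); expect_equal(b$h, 10)
  # neck floor: nose-to-neck 32 px -> height max(10, 25.6), centre kept
  k2 <- rbind(k, data.frame(part = "neck", x = 100, y = 140))
  b2 <- head_box_from_keypoints(k2)
  expect_equal(b2$h, 25.6)
  expect_equal(b2$cy, 103)
  expect_equal(b2$w, 20)
})

test_that("box construction is translation-equivariant", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- face_keypoints(0, 0, runif(1, 50, 900), runif(1, 50, 600),
                        half = runif(1, 5, 40))
    k <- k[sample(nrow(k), sample(3:6, 1)), ]
    if (is.null(head_box_from_keypoints(k))) next
    dxy <- runif(2, -200, 200)
    k2 <- k; k2$x <- k2$x + dxy[1]; k2$y <- k2$y + dxy[2]
    b <- head_box_from_keypoints(k)
    b2 <- head_box_from_keypoints(k2)
    expect_equal(b2$cx, b$cx + dxy[1])
    expect_equal(b2$cy, b$cy + dxy[2])
    expect_equal(b2$w, b$w); expect_equal(b2$h, b$h)
  }
})

test_that("vectorised head_boxes agrees with the scalar rule", {
  set.seed(7)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    k <- face_keypoints(i %/% 3, i %% 3, runif(1, 50, 1200),
                        runif(1, 50, 650), half = runif(1, 4, 35))
    k[sample(nrow(k), sample(1:6, 1)), ]
  }))
  vec <- head_boxes(rows)
  key <- paste(rows$frame, rows$person)
  for (kk in unique(key)) {
    g <- rows[key == kk, ]
    b <- head_box_from_keypoints(g)
    sel <- vec[vec$frame == g$frame[1] & vec$person == g$person[1], ]
    if (is.null(b)) {
      expect_equal(nrow(sel), 0L)
    } else {
      expect_equal(nrow(sel), 1L)
      expect_equal(unlist(sel[c("cx", "cy", "w", "h")], use.names = FALSE),
                   unlist(b, use.names = FALSE))
    }
  }
})

test_that("enlarge_box scales about the centre and validates its factor", {
  b <- list(cx = 10, cy = 20, w = 20, h = 10)
  e <- enlarge_box(b, 0.5)
  expect_equal(e[c("cx", "cy", "w", "h")], list(cx = 10, cy = 20, w = 30, h = 15))
  expect_equal(enlarge_box(b, 0), b)
  expect_equal(enlarge_box(list(cx = 0, cy = 0, w = 2, h = 2), 1)$w, 4)
  expect_error(enlarge_box(b, -1), "factor")
})

test_that("normalize_box_sizes takes windowed maxima within runs only", {
  t3 <- data.frame(frame = 0:2, cx = 1:3, cy = 1:3, w = c(10, 30, 10),
                   h = c(10, 30, 10))
  n3 <- normalize_box_sizes(t3, 25)
  expect_equal(n3$w, rep(30, 3)); expect_equal(n3$h, rep(30, 3))
  expect_equal(n3$cx, t3$cx)
  # identity window
  expect_equal(normalize_box_sizes(t3, 1), t3)
  # maxima never cross a detection gap
  t2 <- data.frame(frame = c(0:2, 10:12), cx = 0, cy = 0,
                   w = c(10, 10, 10, 50, 50, 50), h = 5)
  n2 <- normalize_box_sizes(t2, 25)
  expect_equal(n2$w, c(10, 10, 10, 50, 50, 50))
  # idempotence
  set.seed(1)
  tr <- data.frame(frame = 0:99, cx = 0, cy = 0, w = runif(100, 10, 60),
                   h = runif(100, 10, 60))
  once <- normalize_box_sizes(tr, 9)
  expect_equal(normalize_box_sizes(once, 9), once)
})

test_that("enlargement and normalisation commute with uniform scaling", {
  set.seed(3)
  tr <- data.frame(frame = c(0:39, 60:99), cx = runif(80, 0, 500),
                   cy = runif(80, 0, 500), w = runif(80, 10, 60),
                   h = runif(80, 10, 60))
  for (k in c(0.5, 2, 10)) {
    a <- normalize_box_sizes(enlarge_box(tr, 0.5), 11)
    a_scaled <- a
    for (col in c("cx", "cy", "w", "h")) a_scaled[[col]] <- a[[col]] * k
    tr_k <- tr
    for (col in c("cx", "cy", "w", "h")) tr_k[[col]] <- tr[[col]] * k
    b <- normalize_box_sizes(enlarge_box(tr_k, 0.5), 11)
    expect_equal(b, a_scaled)
  }
})

test_that("greedy tracking keeps identities and drops flicker", {
  # two stationary boxes over 100 frames
  boxes <- rbind(
    data.frame(frame = 0:99, person = 0L, cx = 100, cy = 100, w = 40, h = 40),
    data.frame(frame = 0:99, person = 1L, cx = 600, cy = 120, w = 55, h = 55))
  tr <- track_persons(boxes)
  expect_length(tr, 2L)
  expect_equal(sort(vapply(tr, function(t) nrow(t$boxes), 0L)), c(100L, 100L))
  # each track is person-pure
  expect_true(all(vapply(tr, function(t) length(unique(t$boxes$person)) == 1L,
                         TRUE)))
  # a 10-frame flicker detection does not survive
  boxes2 <- rbind(boxes,
                  data.frame(frame = 20:29, person = 2L, cx = 300, cy = 400,
                             w = 30, h = 30))
  expect_length(track_persons(boxes2), 2L)
})

test_that("zero-overlap detections fall back to the nearest centre", {
  # one track at x=100, one at x=600; at frame 2 the first jumps to x=460
  # with no overlap with either last box: nearer to the x=600 track's
  # candidate replacement at 470
  boxes <- rbind(
    data.frame(frame = 0:1, person = 0L, cx = 100, cy = 100, w = 20, h = 20),
    data.frame(frame = 0:1, person = 1L, cx = 600, cy = 100, w = 20, h = 20),
    data.frame(frame = 2, person = 0L, cx = 460, cy = 100, w = 20, h = 20),
    data.frame(frame = 2, person = 1L, cx = 130, cy = 100, w = 20, h = 20))
  tr <- track_persons(boxes, min_track_len = 2)
  # the track whose last centre was 600 receives the 460 detection
  t600 <- tr[[which(vapply(tr, function(t) t$boxes$cx[1] == 600, TRUE))]]
  expect_equal(t600$boxes$cx, c(600, 600, 460))
})

test_that("role assignment uses hints, the size heuristic, and ambiguity", {
  mk <- function(id, h) new_track(id, data.frame(frame = 0:49, cx = 0, cy = 0,
                                                 w = h, h = h))
  tr <- list(mk("0", 40), mk("1", 60))
  hinted <- assign_roles(tr, hint = c("0" = "therapist", "1" = "child"))
  expect_equal(vapply(hinted, function(t) t$role, ""), c("therapist", "child"))
  auto <- assign_roles(tr)
  expect_equal(vapply(auto, function(t) t$role, ""), c("child", "therapist"))
  expect_warning(amb <- assign_roles(list(mk("0", 50), mk("1", 50))), "5%")
  expect_equal(vapply(amb, function(t) t$role, ""), c("unknown", "unknown"))
  expect_error(assign_roles(list(mk("0", 40))), "exactly 2")
})

test_that("tracking a noiseless simulated scene recovers simulator identities", {
  scn <- simulate_scene(scene_config(seed = 11, n_frames = 300))
  tr <- track_persons(head_boxes(scn$keypoints))
  expect_length(tr, 2L)
  purity <- vapply(tr, function(t) length(unique(t$boxes$person)) == 1L, TRUE)
  expect_true(all(purity))
  # after size normalisation the role heuristic identifies the larger
  # (therapist) head even though away-facing frames give degenerate boxes
  tr <- assign_roles(lapply(tr, normalize_box_sizes))
  person_of <- vapply(tr, function(t) t$boxes$person[1], 0L)
  role_of <- vapply(tr, function(t) t$role, "")
  expect_equal(role_of[person_of == 1L], "therapist")
  expect_equal(role_of[person_of == 0L], "child")
})
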