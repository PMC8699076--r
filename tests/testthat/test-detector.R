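test_that("gaze_intersection uses ray semantics on the vertical target line", {
  expect_equal(gaze_intersection(c(100, 100), c(1, 0, 0), 200), c(200, 100))
  expect_equal(gaze_intersection(c(100, 100), c(0.707, 0.707, 0), 200),
               c(200, 200))
  # looking away from the target line: no intersection
  expect_null(gaze_intersection(c(100, 100), c(-1, 0, 0), 200))
  # vertical gaze never reaches a distinct vertical line
  expect_null(gaze_intersection(c(100, 100), c(0, 1, 0), 200))
})

test_that("gaze_distance is the vertical offset, +Inf for a missing point", {
  expect_equal(gaze_distance(c(200, 100), c(200, 100)), 0)
  expect_equal(gaze_distance(c(200, 200), c(200, 150)), 50)
  expect_identical(gaze_distance(NULL, c(200, 150)), Inf)
})

test_that("depth compatibility waives the sign rule near zero depth", {
  expect_true(depth_compatible(0.05, 0.1, 0.3))    # both shallow
  expect_true(depth_compatible(0.5, -0.4, 0.3))    # opposite-sign deep
  expect_false(depth_compatible(0.5, 0.5, 0.3))    # same-sign deep
  # mixed case: one deep, one shallow -> compatible
  expect_true(depth_compatible(0.6, 0.1, 0.3))
  # vectorised
  expect_equal(depth_compatible(c(0.05, 0.5, 0.5), c(0.1, -0.4, 0.5), 0.3),
               c(TRUE, TRUE, FALSE))
})

dyad_frame_df <- function(d_frac_c = 0, d_frac_t = 0, z_c = 0, z_t = 0,
                          size_c = 50, size_t = 60, drop_gaze_t = FALSE) {
  c_c <- c(200, 300); c_t <- c(800, 260)
  aim <- function(own, other, frac, size, z) {
    dy <- other[2] + frac * size - own[2]
    dx <- other[1] - own[1]
    n2 <- sqrt(dx^2 + dy^2); s <- sqrt(1 - z^2)
    c(s * dx / n2, s * dy / n2, z)
  }
  gc <- aim(c_c, c_t, d_frac_c, size_t, z_c)
  gt <- aim(c_t, c_c, d_frac_t, size_c, z_t)
  if (drop_gaze_t) gt <- c(NA_real_, NA_real_, NA_real_)
  data.frame(frame = 0, cx_c = c_c[1], cy_c = c_c[2], w_c = size_c,
             h_c = size_c, gx_c = gc[1], gy_c = gc[2], gz_c = gc[3],
             cx_t = c_t[1], cy_t = c_t[2], w_t = size_t, h_t = size_t,
             gx_t = gt[1], gy_t = gt[2], gz_t = gt[3])
}

test_that("frame contact combines distance thresholds and depth", {
  p <- detector_params()
  perfect <- frame_contact(dyad_frame_df(), p)
  expect_true(perfect$contact)
  expect_equal(perfect$d_child, 0, tolerance = 1e-9)
  # child gaze at 0.9 x target box size: over the 0.8 threshold
  over <- frame_contact(dyad_frame_df(d_frac_c = 0.9), p)
  expect_false(over$contact)
  expect_equal(over$d_child, 0.9 * 60, tolerance = 1e-9)
  # at 0.79: inside
  expect_true(frame_contact(dyad_frame_df(d_frac_c = 0.79), p)$contact)
  # same-sign deep gaze is rejected, opposite-sign accepted
  expect_false(frame_contact(dyad_frame_df(z_c = 0.5, z_t = 0.5), p)$contact)
  expect_true(frame_contact(dyad_frame_df(z_c = 0.5, z_t = -0.5), p)$contact)
  # missing gaze -> undefined
  expect_true(is.na(frame_contact(dyad_frame_df(drop_gaze_t = TRUE), p)$contact))
})

test_that("segment_events applies duration and bridging rules", {
  p <- detector_params()
  ev <- segment_events(rep(TRUE, 25), p, fps = 25)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 1.0)
  expect_equal(ev$start_frame, 0L); expect_equal(ev$end_frame, 24L)
  expect_equal(nrow(segment_events(rep(TRUE, 24), p, 25)), 0L)
  flags <- c(rep(TRUE, 30), FALSE, rep(TRUE, 30))
  expect_equal(nrow(segment_events(flags, p, 25)), 2L)
  ev1 <- segment_events(flags, detector_params(gap_bridge_frames = 1), 25)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$n_frames, 61L)
})

test_that("segment_events matches the naive run scanner on random sequences", {
  set.seed(42)
  for (i in 1:250) {
    n <- sample(10:80, 1)
    flags <- runif(n) < runif(1, 0.2, 0.8)
    min_dur <- sample(1:10, 1)
    gap <- sample(0:3, 1)
    p <- detector_params(min_duration_frames = min_dur,
                         gap_bridge_frames = gap)
    expect_equal(segment_events(flags, p, 25), naive_segment(flags, min_dur, gap),
                 info = sprintf("case %d (n=%d dur=%d gap=%d)", i, n, min_dur, gap))
  }
})

test_that("detection is symmetric under swapping the two subjects", {
  s <- random_session(1)
  a <- detect_eye_contact(s$child, s$therapist)
  b <- detect_eye_contact(s$therapist, s$child)
  expect_equal(a$frames$contact, b$frames$contact)
  expect_equal(a$events$start_frame, b$events$start_frame)
  expect_equal(a$frames$d_child, b$frames$d_therapist)
})

test_that("contact flags are invariant under uniform coordinate scaling", {
  s <- random_session(2)
  base <- detect_eye_contact(s$child, s$therapist)$frames$contact
  for (k in c(0.5, 2, 10)) {
    scaled <- detect_eye_contact(scale_track(s$child, k),
                                 scale_track(s$therapist, k))$frames$contact
    expect_equal(scaled, base, info = paste("k =", k))
  }
})

test_that("contact count is monotone in the thresholds", {
  for (seed in 1:5) {
    s <- random_session(seed)
    td_counts <- vapply(c(0.4, 0.8, 1.2), function(td)
      count_contacts(s, detector_params(td_fraction = td)), 0)
    expect_true(all(diff(td_counts) >= 0))
    tz_counts <- vapply(c(0.1, 0.3, 0.6), function(tz)
      count_contacts(s, detector_params(tz = tz)), 0)
    expect_true(all(diff(tz_counts) >= 0))
    ev_counts <- vapply(c(5, 15, 40), function(md) {
      p <- detector_params(min_duration_frames = md)
      nrow(detect_eye_contact(s$child, s$therapist, p)$events)
    }, 0)
    expect_true(all(diff(ev_counts) <= 0))
  }
})

test_that("a dyad with no gaze overlap warns and returns empty outputs", {
  child <- new_track("c", data.frame(frame = 0:9, cx = 0, cy = 0, w = 1, h = 1),
                     gaze = data.frame(frame = integer(), gx = numeric(),
                                       gy = numeric(), gz = numeric()))
  ther <- new_track("t", data.frame(frame = 0:9, cx = 9, cy = 0, w = 1, h = 1),
                    gaze = data.frame(frame = integer(), gx = numeric(),
                                      gy = numeric(), gz = numeric()))
  expect_warning(res <- detect_eye_contact(child, ther), "zero overlapping")
  expect_equal(nrow(res$events), 0L)
  expect_true(all(is.na(res$frames$contact)))
})
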