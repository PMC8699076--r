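# Annotated sessions for detector-parameter selection, generated directly
# at the gaze-geometry level, plus synthetic cohorts of per-subject
# feature vectors.

# Build a gaze vector realising a prescribed signed vertical offset at the
# partner's centre line and a prescribed z component.
gaze_toward <- function(own, partner_x, aim_y, z) {
  d2 <- c(partner_x - own[1], aim_y - own[2])
  d2 <- d2 / sqrt(sum(d2^2))
  s <- sqrt(max(0, 1 - z^2))
  c(s * d2[1], s * d2[2], z)
}

#' Simulate an annotated tuning session
#'
#' Generates one session of dyad tracks plus frame-level annotations whose
#' error structure makes the canonical detector cell (`td_fraction` 0.8,
#' `tz` 0.3, 25-frame minimum duration) the best match to the annotations:
#'
#' * genuine episodes (annotated positive, 30-100 frames) have smoothly
#'   varying gaze offsets mostly well inside 0.8 of the head-box size but
#'   regularly entering the 0.6-0.8 band, so a 0.6 threshold loses frames;
#' * "near-miss" intervals (annotated negative) where both gazes pass at
#'   0.82-0.98 of the box size, so a 1.0 threshold admits false events;
#' * a quarter of the genuine episodes drift to same-sign gaze depths with
#'   `|z|` in 0.2-0.3 (same room depth, shallow-depth fluctuation), which a
#'   0.2 depth tolerance rejects;
#' * "deep same-sign" intervals (annotated negative: gazes crossing in 2-D
#'   only) with both `|z|` in 0.32-0.42, which a 0.4 tolerance admits;
#' * brief genuine mutual glances (8-20 frames, under the 1 s perceptual
#'   threshold observational coders use for an episode, annotated
#'   negative), which a 13-frame minimum duration turns into false events.
#'
#' @param seed Integer seed.
#' @param n_frames Session length (default 3000 frames = 2 min at 25 fps).
#' @param fps Frame rate (default 25).
#' @return List with `child`, `therapist` (`eyec_track` with gaze),
#'   `truth` (logical per-frame annotation vector) and `fps`, as one
#'   element of the `sessions` list [grid_search()] takes.
#' @export
simulate_tuning_session <- function(seed, n_frames = 3000, fps = 25) {
  stopifnot(is_count(seed), is_count(n_frames, 500L))
  with_seed(seed, {
    size <- 60                       # head-box size (px) of both subjects
    c_child <- c(300, 360)
    c_ther <- c(940, 300)
    n <- n_frames

    kind <- rep("bg", n)             # bg / episode / near / deep / glance
    z_mode <- rep("normal", n)
    # lay out alternating labelled intervals with background gaps
    cursor <- 30L
    ep_i <- 0L
    while (cursor < n - 120L) {
      what <- sample(c("episode", "near", "deep", "glance", "bg"), 1,
                     prob = c(0.30, 0.15, 0.12, 0.15, 0.28))
      len <- switch(what,
                    episode = sample(30:100, 1),
                    near = sample(30:80, 1),
                    deep = sample(30:80, 1),
                    glance = sample(8:20, 1),
                    bg = sample(40:120, 1))
      if (cursor + len >= n) break
      if (what != "bg") {
        kind[(cursor + 1L):(cursor + len)] <- what
        if (what == "episode") {
          ep_i <- ep_i + 1L
          if (ep_i %% 4L == 0L) {
            z_mode[(cursor + 1L):(cursor + len)] <- "shallow_same"
          }
        }
      }
      cursor <- cursor + len + sample(8:25, 1)  # short neutral spacing
    }

    # smooth per-frame offset fraction of the box size, per subject
    ar_noise <- function(n, sd, rho = 0.9) {
      x <- numeric(n)
      if (n > 1) {
        for (i in 2:n) {
          x[i] <- rho * x[i - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
        }
      }
      x
    }

    frac_c <- numeric(n); frac_t <- numeric(n)
    z_c <- numeric(n); z_t <- numeric(n)
    r <- rle(paste(kind, z_mode))
    pos <- cumsum(c(0L, r$lengths))
    for (i in seq_along(r$lengths)) {
      idx <- (pos[i] + 1L):pos[i + 1L]
      k <- kind[idx[1]]; zm <- z_mode[idx[1]]
      m <- length(idx)
      if (k %in% c("episode", "glance")) {
        base <- runif(2, 0.15, 0.55)
        frac_c[idx] <- pmax(0, pmin(base[1] + ar_noise(m, 0.18), 0.79))
        frac_t[idx] <- pmax(0, pmin(base[2] + ar_noise(m, 0.18), 0.79))
        if (zm == "shallow_same") {
          sgn <- sample(c(-1, 1), 1)
          z_c[idx] <- sgn * runif(m, 0.21, 0.29)
          z_t[idx] <- sgn * runif(m, 0.21, 0.29)
        } else {
          z_c[idx] <- rnorm(m, 0, 0.05)
          z_t[idx] <- rnorm(m, 0, 0.05)
        }
      } else if (k == "near") {
        frac_c[idx] <- runif(m, 0.82, 0.98)
        frac_t[idx] <- runif(m, 0.82, 0.98)
        z_c[idx] <- rnorm(m, 0, 0.05)
        z_t[idx] <- rnorm(m, 0, 0.05)
      } else if (k == "deep") {
        frac_c[idx] <- pmax(0, runif(m, 0.1, 0.5))
        frac_t[idx] <- pmax(0, runif(m, 0.1, 0.5))
        sgn <- sample(c(-1, 1), 1)
        z_c[idx] <- sgn * runif(m, 0.32, 0.42)
        z_t[idx] <- sgn * runif(m, 0.32, 0.42)
      } else {  # background: look far away
        frac_c[idx] <- runif(m, 3, 8)
        frac_t[idx] <- runif(m, 3, 8)
        z_c[idx] <- rnorm(m, 0, 0.2)
        z_t[idx] <- rnorm(m, 0, 0.2)
      }
    }

    sign_c <- sample(c(-1, 1), n, replace = TRUE)
    sign_t <- sample(c(-1, 1), n, replace = TRUE)
    gc <- t(vapply(seq_len(n), function(f) {
      gaze_toward(c_child, c_ther[1],
                  c_ther[2] + sign_c[f] * frac_c[f] * size,
                  pmax(-0.99, pmin(0.99, z_c[f])))
    }, numeric(3)))
    gt <- t(vapply(seq_len(n), function(f) {
      gaze_toward(c_ther, c_child[1],
                  c_child[2] + sign_t[f] * frac_t[f] * size,
                  pmax(-0.99, pmin(0.99, z_t[f])))
    }, numeric(3)))

    frames <- 0:(n - 1)
    mk_track <- function(id, centre, g) {
      new_track(id, data.frame(frame = frames, cx = centre[1],
                               cy = centre[2], w = size, h = size),
                gaze = data.frame(frame = frames, gx = g[, 1], gy = g[, 2],
                                  gz = g[, 3]))
    }
    child <- mk_track("child", c_child, gc)
    child$role <- "child"
    therapist <- mk_track("therapist", c_ther, gt)
    therapist$role <- "therapist"
    list(child = child, therapist = therapist,
         truth = kind == "episode", fps = fps)
  })
}

#' Default per-group cohort parameters
#'
#' Per-sub-group Gaussian means and standard deviations for the five
#' clustering features of a three-sub-group synthetic cohort: a
#' low-coordination toddler group, a high-coordination toddler group
#' (many, longer eye-contact episodes), and a smaller, older
#' low-coordination group whose gaze stays further from the adult's face.
#'
#' @return Named list, one element per group, each with numeric vectors
#'   `mean` and `sd` over `(num, freq, dur, d_mean, age_months)`, plus an
#'   `n` group size.
#' @export
default_cohort_params <- function() {
  feat <- c("num", "freq", "dur", "d_mean", "age_months")
  g <- function(mean, sd, n) list(mean = setNames(mean, feat),
                                  sd = setNames(sd, feat), n = n)
  list(
    low_coordination = g(c(9, 0.2, 1.6, 308.9, 37.9),
                         c(6.2, 0.1, 0.3, 152.1, 10.2), 23L),
    high_coordination = g(c(40.7, 0.7, 1.9, 301.0, 43.9),
                          c(6.2, 0.1, 0.3, 152.1, 10.1), 21L),
    old_low_coordination = g(c(11.6, 0.2, 1.7, 649.4, 60.9),
                             c(6.1, 0.1, 0.3, 152.1, 10.1), 16L)
  )
}

#' Simulate a cohort feature table
#'
#' Draws per-subject eye-contact features and age from independent
#' Gaussians with per-group means and standard deviations, truncated at
#' physical bounds (all features non-negative; `num` rounded to an
#' integer count).
#'
#' @param group_params Per-group parameters as from
#'   [default_cohort_params()]; group sizes may be overridden with
#'   `group_sizes`.
#' @param group_sizes Optional integer vector of subjects per group.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `group` (0-based label in
#'   parameter order), and the five features.
#' @export
simulate_cohort <- function(group_params = default_cohort_params(),
                            group_sizes = NULL, seed = 1) {
  stopifnot(is_count(seed))
  if (is.null(group_sizes)) {
    group_sizes <- vapply(group_params, function(g) as.integer(g$n), 0L)
  }
  stopifnot(length(group_sizes) == length(group_params), all(group_sizes >= 1))
  with_seed(seed, {
    rows <- lapply(seq_along(group_params), function(gi) {
      p <- group_params[[gi]]
      n <- group_sizes[gi]
      stopifnot(all(p$sd >= 0))
      draw <- vapply(seq_along(p$mean), function(j) {
        pmax(0, rnorm(n, p$mean[j], p$sd[j]))
      }, numeric(n))
      if (n == 1L) draw <- matrix(draw, nrow = 1L)
      colnames(draw) <- names(p$mean)
      out <- as.data.frame(draw)
      out$num <- round(out$num)
      out$group <- gi - 1L
      out
    })
    tab <- do.call(rbind, rows)
    tab$subject_id <- sprintf("S%03d", seq_len(nrow(tab)))
    rownames(tab) <- NULL
    tab[, c("subject_id", "group", "num", "freq", "dur", "d_mean",
            "age_months")]
  })
}
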