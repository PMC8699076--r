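# Session-level eye-contact features: the number of events (num), their
# frequency per minute (freq), their mean duration in seconds (dur), and
# the session-wide mean child-gaze distance in pixels (d_mean).

#' Session-level eye-contact features
#'
#' Summarises a detected session into the features used for correlation and
#' stratification: `num`, the event count; `freq = num / session_minutes`
#' in events per minute; `dur`, the mean event duration in seconds; and
#' `d_mean`, the mean child-side gaze distance over *all* frames where it
#' is defined and finite (not only contact frames — it measures how close
#' the child's gaze stays to the therapist's face over the whole
#' interaction). Sessions with zero events report `dur = NA`.
#'
#' @param frames Per-frame dyad table from [detect_eye_contact()].
#' @param events Event table from [detect_eye_contact()].
#' @param fps Frame rate (frames/s), must be positive.
#' @param age_months Optional subject age in months, carried into the
#'   output for stratification.
#' @return One-row data frame with columns `num`, `freq`, `dur`, `d_mean`,
#'   `session_minutes`, `age_months`.
#' @export
compute_features <- function(frames, events, fps = 25, age_months = NA) {
  if (!is_number(fps) || fps <= 0) stop_eyec("`fps` must be > 0")
  if (nrow(frames) == 0L) stop_eyec("session has no frames")
  minutes <- nrow(frames) / fps / 60
  num <- nrow(events)
  d <- frames$d_child
  d <- d[!is.na(d) & is.finite(d)]
  data.frame(
    num = num,
    freq = num / minutes,
    dur = if (num > 0L) mean(events$duration_s) else NA_real_,
    d_mean = if (length(d) > 0L) mean(d) else NA_real_,
    session_minutes = minutes,
    age_months = age_months
  )
}

#' Time-binned event features
#'
#' Splits the session's frame span into `n_bins` equal contiguous segments
#' (remainder frames go to the last bin) and assigns each event to the bin
#' containing its start frame, so an event never straddles bins. Used to
#' study how eye-contact behaviour evolves over the course of an
#' interaction.
#'
#' @param frames Per-frame dyad table (defines the session span).
#' @param events Event table.
#' @param n_bins Number of time bins (default 4).
#' @return List with `binned_num` (integer event count per bin) and
#'   `binned_dur` (mean event duration in seconds per bin, `NA` for empty
#'   bins).
#' @export
time_binned <- function(frames, events, n_bins = 4) {
  if (!is_count(n_bins, 1L)) stop_eyec("`n_bins` must be an integer >= 1")
  n <- nrow(frames)
  if (n == 0L) stop_eyec("session has no frames")
  width <- n %/% n_bins
  if (width == 0L) stop_eyec("more bins than frames")
  first <- frames$frame[1]
  # bin of a frame offset: offsets [0, width) -> 1, ...; remainder -> last
  bin_of <- pmin((events$start_frame - first) %/% width + 1L, n_bins)
  num <- tabulate(bin_of, nbins = n_bins)
  dur <- vapply(seq_len(n_bins), function(b) {
    d <- events$duration_s[bin_of == b]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, 0)
  list(binned_num = num, binned_dur = dur)
}
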