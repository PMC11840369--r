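# Inertial preprocessing: active-phase trimming, walk splitting at the
# turnaround, rotation to a gravity-aligned / heading-aligned global frame,
# and duration filtering.

#' Trim a stream to its active phase
#'
#' Activity is the moving RMS (1-s window) of the deviation of the
#' acceleration-magnitude from its median (which absorbs gravity). Leading
#' and trailing segments whose activity falls below `threshold` are removed;
#' the interior -- including the turnaround -- is retained intact. The
#' operation is idempotent.
#'
#' @param stream a [sensor_stream()]
#' @param threshold activity RMS threshold in m/s^2
#' @param window moving-RMS window in seconds
#' @return the trimmed `sensor_stream`
#' @export
trim_active_phase <- function(stream, threshold = 0.05, window = 1) {
  fs <- 1 / stats::median(diff(stream$timestamps))
  mag <- sqrt(rowSums(stream$acceleration^2))
  dev2 <- (mag - stats::median(mag))^2
  # coarse moving RMS locates the active region; a short (window/10) RMS
  # sharpens the boundary so the cut does not smear half a window into the
  # still segments
  rms <- sqrt(moving_mean(dev2, round(window * fs)))
  rms_fine <- sqrt(moving_mean(dev2, max(2L, round(window * fs / 10))))
  active <- which(rms > threshold & rms_fine > threshold)
  if (length(active) == 0L)
    cipn_error("stream has no active phase above threshold",
               "cipnsense_empty_sample_error")
  idx <- active[1]:active[length(active)]
  subset_stream(stream, idx)
}

subset_stream <- function(stream, idx) {
  sensor_stream(stream$timestamps[idx],
                stream$acceleration[idx, , drop = FALSE],
                stream$rotation_rate[idx, , drop = FALSE],
                stream$attitude[idx, , drop = FALSE],
                phase = if (!is.null(stream$phase)) stream$phase[idx],
                kind = stream$kind, meta = stream$meta)
}

#' Split a walking stream at the turnaround
#'
#' Locates the 180-degree turn as the midpoint of the maximal-yaw-rate
#' window (yaw rate taken about the global vertical axis after attitude
#' rotation, smoothed over 0.5 s) and returns the forth and back legs with
#' the turn segment excluded from both. If the cumulative yaw change around
#' the candidate turn is below 120 degrees, no turn is detected: a warning
#' is raised and the stream kept whole.
#'
#' @param stream a walking [sensor_stream()]
#' @return list with `forth`, `back` (`NULL` if no turn), `turn_time`
#'   (estimated turnaround time, NA if none) and `no_turn` flag
#' @export
split_walk <- function(stream) {
  fs <- 1 / stats::median(diff(stream$timestamps))
  rot_g <- quat_rotate(stream$attitude, stream$rotation_rate)
  yaw <- rot_g[, 3]
  yaw_s <- moving_mean(yaw, round(0.5 * fs))
  dt <- c(diff(stream$timestamps), 1 / fs)
  cum_yaw <- cumsum(yaw * dt)

  c_idx <- which.max(abs(yaw_s))
  half <- round(1.5 * fs)  # inspect a 3-s window around the peak
  lo <- max(1L, c_idx - half)
  hi <- min(length(yaw), c_idx + half)
  turn_change <- abs(cum_yaw[hi] - cum_yaw[lo])

  if (turn_change < (120 / 180) * pi) {
    cipn_warning("no turn detected (cumulative yaw change < 120 degrees); stream kept whole",
                 "cipnsense_no_turn_warning")
    return(list(forth = stream, back = NULL, turn_time = NA_real_,
                no_turn = TRUE))
  }

  # turn extent: contiguous region around the peak with |yaw| above 20% of
  # the peak rate
  thr <- 0.2 * abs(yaw_s[c_idx])
  in_turn <- abs(yaw_s) > thr
  start <- c_idx
  while (start > 1L && in_turn[start - 1L]) start <- start - 1L
  end <- c_idx
  n <- length(yaw)
  while (end < n && in_turn[end + 1L]) end <- end + 1L

  turn_time <- stream$timestamps[c_idx]
  forth <- if (start > 1L) subset_stream(stream, 1:(start - 1L)) else NULL
  back <- if (end < n) subset_stream(stream, (end + 1L):n) else NULL
  list(forth = forth, back = back, turn_time = turn_time, no_turn = FALSE)
}

#' Duration filter for walking samples
#'
#' Walking legs shorter than 7.5 s (natural) or 10.5 s (tandem) indicate an
#' aborted task and are discarded. The comparison is strictly "less than":
#' a leg of exactly 7.5 / 10.5 s is kept.
#'
#' @param sample a `sensor_stream` or `clean_sample` with a duration
#' @param kind `"natural"` or `"tandem"`
#' @return `TRUE` to keep, `FALSE` to discard
#' @export
filter_duration <- function(sample, kind = c("natural", "tandem")) {
  kind <- match.arg(kind)
  dur <- if (inherits(sample, "sensor_stream")) stream_duration(sample)
         else sample$duration
  dur >= if (kind == "natural") 7.5 else 10.5
}

#' Rotate a stream to the global reference frame
#'
#' Applies the per-sample attitude, fine-aligns the mean measured gravity
#' direction with the vertical axis, and yaw-aligns the heading: for walks
#' the forward (y) axis is the principal horizontal direction of the
#' gravity-removed acceleration; for stances it is the initial device
#' heading. Global axes are (side-to-side, forward-backward, up); rotation
#' rates are reported about these axes as (pitch, roll, yaw) = rotation
#' about (x, y, z). When the attitude is missing or degenerate, a
#' gravity-vector fallback aligns only the vertical axis and the result is
#' flagged `yaw_indeterminate`.
#'
#' @param stream a [sensor_stream()]
#' @param heading `"walk"` or `"stance"` heading rule
#' @return object of class `clean_sample`: timestamps, global acceleration
#'   (gravity retained on z), global rotation, phase labels, duration, flags
#' @export
rotate_to_global <- function(stream, heading = c("walk", "stance")) {
  heading <- match.arg(heading)
  n <- length(stream$timestamps)
  yaw_ok <- TRUE

  att_ok <- !is.null(stream$attitude) &&
    all(is.finite(stream$attitude)) &&
    all(abs(sqrt(rowSums(stream$attitude^2)) - 1) < 1e-6)

  if (att_ok) {
    acc_g <- quat_rotate(stream$attitude, stream$acceleration)
    rot_g <- quat_rotate(stream$attitude, stream$rotation_rate)
  } else {
    acc_g <- stream$acceleration
    rot_g <- stream$rotation_rate
    yaw_ok <- FALSE
  }

  # fine gravity alignment: mean acceleration direction -> (0, 0, -1)
  gbar <- colMeans(acc_g)
  q_fix <- quat_between(gbar / sqrt(sum(gbar^2)), c(0, 0, -1))
  acc_g <- quat_rotate(q_fix, acc_g)
  rot_g <- quat_rotate(q_fix, rot_g)

  if (yaw_ok) {
    dyn <- sweep(acc_g, 2, colMeans(acc_g))
    psi <- if (heading == "walk") {
      cc <- stats::cov(dyn[, 1:2])
      e <- eigen(cc, symmetric = TRUE)$vectors[, 1]
      if (e[2] < 0) e <- -e
      atan2(e[1], e[2])
    } else {
      h <- quat_rotate(q_fix, quat_rotate(stream$attitude[1, ], c(0, 1, 0)))
      atan2(h[1], h[2])
    }
    q_yaw <- quat_from_axis_angle(c(0, 0, 1), -psi)
    acc_g <- quat_rotate(q_yaw, acc_g)
    rot_g <- quat_rotate(q_yaw, rot_g)
  }

  structure(list(source_id = stream$meta$session_id,
                 timestamps = stream$timestamps,
                 acceleration = acc_g,
                 rotation = rot_g,
                 phase = stream$phase,
                 kind = stream$kind,
                 duration = stream_duration(stream),
                 yaw_indeterminate = !yaw_ok),
            class = "clean_sample")
}

#' Angle between the mean measured gravity and the vertical axis
#' @param sample a `clean_sample`
#' @return angle in degrees
#' @export
gravity_angle <- function(sample) {
  gbar <- colMeans(sample$acceleration)
  gbar <- gbar / sqrt(sum(gbar^2))
  acos(pmin(1, pmax(-1, sum(gbar * c(0, 0, -1))))) * 180 / pi
}

#' Preprocess one assessment session
#'
#' Runs the full cleaning chain appropriate for the task: walks are trimmed
#' to the active phase, split at the turnaround, rotated to the global frame
#' and duration-filtered per leg; the Romberg stance is rotated and split
#' into its eyes-open / eyes-closed phases; the tandem stance is rotated
#' whole. Tapping and peg sessions pass through untouched.
#'
#' @param session an assessment session (as produced by [simulate_cohort()])
#' @param trim_threshold activity threshold passed to [trim_active_phase()]
#' @return list with `samples` (named list of `clean_sample` or raw
#'   tap/peg data) and `qc` (data frame of kept/discarded parts with
#'   reasons)
#' @export
preprocess_session <- function(session, trim_threshold = 0.05) {
  kind <- session$kind
  qc <- data.frame(session_id = character(), part = character(),
                   kept = logical(), reason = character())
  note <- function(part, kept, reason = "") {
    qc <<- rbind(qc, data.frame(session_id = session$session_id, part = part,
                                kept = kept, reason = reason))
  }
  samples <- list()

  if (kind %in% c("natural_walk", "tandem_walk")) {
    walk_kind <- sub("_walk", "", kind)
    stream <- session$data
    stream$meta$session_id <- session$session_id
    trimmed <- tryCatch(trim_active_phase(stream, trim_threshold),
                        cipnsense_empty_sample_error = function(e) NULL)
    if (is.null(trimmed)) {
      note("all", FALSE, "empty_sample")
      return(list(samples = samples, qc = qc))
    }
    parts <- withCallingHandlers(
      split_walk(trimmed),
      cipnsense_no_turn_warning = function(w) invokeRestart("muffleWarning"))
    if (parts$no_turn) note("all", FALSE, "no_turn")
    for (leg in c("forth", "back")) {
      st <- parts[[leg]]
      if (is.null(st) || parts$no_turn) next
      cs <- rotate_to_global(st, heading = "walk")
      cs$leg <- leg
      if (filter_duration(cs, walk_kind)) {
        samples[[leg]] <- cs
        note(leg, TRUE)
      } else {
        note(leg, FALSE, "too_short")
      }
    }
  } else if (kind == "tandem_stance") {
    cs <- rotate_to_global(session$data, heading = "stance")
    cs$leg <- "stance"
    samples[["stance"]] <- cs
    note("stance", TRUE)
  } else if (kind == "romberg_stance") {
    for (ph in c("eyes_open", "eyes_closed")) {
      idx <- which(session$data$phase == ph)
      st <- subset_stream(session$data, idx)
      cs <- rotate_to_global(st, heading = "stance")
      cs$leg <- ph
      samples[[ph]] <- cs
      note(ph, TRUE)
    }
  } else {
    samples[[kind]] <- session$data
    note(kind, TRUE)
  }
  list(samples = samples, qc = qc)
}

#' Write a cleaned sample as JSON
#'
#' Metadata header plus columnar arrays for the global-frame signals.
#'
#' @param sample a `clean_sample`
#' @param path output file
#' @export
write_clean_sample_json <- function(sample, path) {
  jsonlite::write_json(
    list(meta = list(source_id = sample$source_id, kind = sample$kind,
                     leg = sample$leg, duration = sample$duration,
                     yaw_indeterminate = sample$yaw_indeterminate),
         timestamps = sample$timestamps,
         acceleration = sample$acceleration,
         rotation = sample$rotation,
         phase = sample$phase),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
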