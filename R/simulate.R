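# Synthetic longitudinal CIPN cohort generator.
#
# The simulator emulates a remote-monitoring study design: ~45 patients,
# a baseline assessment before treatment plus one assessment set per
# chemotherapy cycle (every 2-4 weeks, ~11.5 weeks of treatment), six
# smartphone tasks per timepoint (natural walk, tandem walk, tandem stance,
# Romberg stance, finger tapping on both hands, hole-peg), a CIPN20
# questionnaire per timepoint, and end-of-treatment CIPN-f / CIPN-h
# diagnoses. Foot neuropathy is expressed as amplified lateral sway and
# roll rotation (strongest in the eyes-closed Romberg phase); hand
# neuropathy as a shifted inter-tap-interval AR(1) process and slower peg
# handling.

# ---- configuration ---------------------------------------------------------

#' Simulation configuration
#'
#' Bundles all tunable parameters of the synthetic cohort generator.
#' Defaults reproduce the emulated study design: 45 patients, CIPN-f
#' prevalence 24/45, CIPN-h prevalence 29/45, 21-day cycles over 4 cycles
#' (~12 weeks), and unit effect sizes. Setting both effect sizes to 0 yields
#' a null cohort in which cases and controls are statistically
#' indistinguishable.
#'
#' @param n_patients number of patients (>= 4)
#' @param prevalence_f,prevalence_h probabilities of end-of-treatment CIPN
#'   in the feet / hands
#' @param label_correlation latent (tetrachoric-style) correlation between
#'   the CIPN-f and CIPN-h statuses
#' @param cycle_interval_days days between chemotherapy cycles (14-28)
#' @param n_cycles number of treatment cycles (>= 1)
#' @param effect_size_f multiplier strength on lateral-sway / roll-rotation
#'   amplitude for foot neuropathy; 0 disables the effect
#' @param effect_size_h shift strength on tapping-interval lag-1
#'   autocorrelation and SD (and peg slowing) for hand neuropathy; 0 disables
#' @param sampling_rate inertial sampling rate in Hz
#' @param noise_sd accelerometer / gyroscope measurement noise SD
#'   (m/s^2, rad/s)
#' @param cipn20_noise_sd reporting-noise SD on the latent CIPN20 item scale
#' @param seed integer RNG seed; cohorts are byte-identical given the seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients = 45L,
                       prevalence_f = 24 / 45,
                       prevalence_h = 29 / 45,
                       label_correlation = 0.5,
                       cycle_interval_days = 21L,
                       n_cycles = 4L,
                       effect_size_f = 1,
                       effect_size_h = 1,
                       sampling_rate = 100,
                       noise_sd = 0.02,
                       cipn20_noise_sd = 0.15,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              prevalence_f = prevalence_f,
              prevalence_h = prevalence_h,
              label_correlation = label_correlation,
              cycle_interval_days = as.integer(cycle_interval_days),
              n_cycles = as.integer(n_cycles),
              effect_size_f = effect_size_f,
              effect_size_h = effect_size_h,
              sampling_rate = sampling_rate,
              noise_sd = noise_sd,
              cipn20_noise_sd = cipn20_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) cipn_error(msg, "cipnsense_config_error")
  if (!is.finite(cfg$n_patients) || cfg$n_patients < 4L)
    bad("n_patients must be >= 4")
  for (p in c("prevalence_f", "prevalence_h")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(sprintf("%s must be in [0, 1]", p))
  }
  if (abs(cfg$label_correlation) > 1) bad("label_correlation must be in [-1, 1]")
  if (cfg$cycle_interval_days < 14L || cfg$cycle_interval_days > 28L)
    bad("cycle_interval_days must be in 14..28")
  if (cfg$n_cycles < 1L) bad("n_cycles must be >= 1")
  if (cfg$effect_size_f < 0 || cfg$effect_size_h < 0)
    bad("effect sizes must be nonnegative")
  if (cfg$sampling_rate <= 0) bad("sampling_rate must be > 0")
  if (cfg$noise_sd < 0) bad("noise_sd must be >= 0")
  invisible(cfg)
}

# ---- sensor stream ---------------------------------------------------------

#' Construct a sensor stream
#'
#' A timestamped tri-axial inertial record of a walking or standing task in
#' the device frame, together with the device attitude (device-to-reference
#' unit quaternion) per sample.
#'
#' @param timestamps strictly increasing sample times (s)
#' @param acceleration n x 3 acceleration in the device frame, m/s^2,
#'   gravity included
#' @param rotation_rate n x 3 rotation rate in the device frame, rad/s
#' @param attitude n x 4 unit quaternions (w, x, y, z) mapping device to
#'   reference frame
#' @param phase optional per-sample phase labels (e.g. eyes_open/eyes_closed)
#' @param kind task kind string
#' @param meta list of generator metadata (ground truth for tests)
#' @return object of class `sensor_stream`
#' @export
sensor_stream <- function(timestamps, acceleration, rotation_rate, attitude,
                          phase = NULL, kind = "unknown", meta = list()) {
  n <- length(timestamps)
  stopifnot(nrow(acceleration) == n, nrow(rotation_rate) == n,
            nrow(attitude) == n)
  if (n > 1 && any(diff(timestamps) <= 0))
    cipn_error("timestamps must be strictly increasing", "cipnsense_stream_error")
  norms <- sqrt(rowSums(attitude^2))
  if (any(abs(norms - 1) > 1e-6))
    cipn_error("attitude quaternions must be unit norm", "cipnsense_stream_error")
  structure(list(timestamps = as.numeric(timestamps),
                 acceleration = unname(acceleration),
                 rotation_rate = unname(rotation_rate),
                 attitude = unname(attitude),
                 phase = phase,
                 kind = kind,
                 meta = meta),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream: %s, %d samples, %.1f s%s>\n", x$kind,
              length(x$timestamps), stream_duration(x),
              if (!is.null(x$phase)) ", phased" else ""))
  invisible(x)
}

#' Duration of a stream in seconds
#' @param stream a `sensor_stream`
#' @export
stream_duration <- function(stream) {
  ts <- stream$timestamps
  ts[length(ts)] - ts[1]
}

# Hamilton product of one quaternion with each row of a quaternion matrix.
quat_multiply_rows <- function(a, B) {
  cbind(a[1] * B[, 1] - a[2] * B[, 2] - a[3] * B[, 3] - a[4] * B[, 4],
        a[1] * B[, 2] + a[2] * B[, 1] + a[3] * B[, 4] - a[4] * B[, 3],
        a[1] * B[, 3] - a[2] * B[, 4] + a[3] * B[, 1] + a[4] * B[, 2],
        a[1] * B[, 4] + a[2] * B[, 3] - a[3] * B[, 2] + a[4] * B[, 1])
}

# Per-sample attitude: constant session orientation composed with a small
# sinusoidal wobble about a fixed random axis. Makes frame restoration
# nontrivial without altering the restored global-frame signals.
session_attitude <- function(orientation, t) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  phase <- stats::runif(1, 0, 2 * pi)
  ang <- 0.02 * sin(2 * pi * 0.25 * t + phase)
  half <- ang / 2
  s <- sin(half)
  W <- cbind(cos(half), s * axis[1], s * axis[2], s * axis[3])
  quat_normalize(quat_multiply_rows(orientation, W))
}

# Express global-frame signals in the device frame under the attitude.
to_device_frame <- function(acc_g, rot_g, attitude) {
  inv <- quat_conjugate(attitude)
  list(acceleration = quat_rotate(inv, acc_g),
       rotation_rate = quat_rotate(inv, rot_g))
}

# ---- walking task ----------------------------------------------------------

#' Synthesize a walking task stream
#'
#' Gait is modelled as a step-frequency sinusoid (~1.8 Hz) with harmonics on
#' the vertical and fore-aft axes, lateral sway and roll rotation at the
#' stride frequency (0.9 Hz), a 180-degree yaw turn at the midpoint, white
#' measurement noise, and 2-s still segments before and after the walk.
#' Lateral sway and roll-rotation amplitudes scale with
#' `1 + effect_size * severity`. Global axes: x = side-to-side,
#' y = forward-backward, z = up; gravity is `(0, 0, -g)`.
#'
#' @param severity latent neuropathy severity in \[0, 1\]
#' @param kind `"natural"` (two 9-s legs) or `"tandem"` (two 11.5-s legs)
#' @param orientation unit quaternion giving the constant phone orientation
#'   (device-to-global); defaults to a random orientation
#' @param effect_size foot-neuropathy effect size (amplitude multiplier
#'   strength)
#' @param sampling_rate Hz
#' @param noise_sd measurement noise SD
#' @param amp_factor between-patient amplitude heterogeneity multiplier
#' @return a [sensor_stream()] in the device frame; `meta$turn_time` holds
#'   the true turnaround time
#' @export
synthesize_walk <- function(severity, kind = c("natural", "tandem"),
                            orientation = quat_random(), effect_size = 1,
                            sampling_rate = 100, noise_sd = 0.02,
                            amp_factor = 1) {
  kind <- match.arg(kind)
  stopifnot(severity >= 0, severity <= 1)
  leg <- if (kind == "natural") 9 else 11.5
  turn_dur <- 2
  pad <- 2
  active_dur <- 2 * leg + turn_dur
  total <- active_dur + 2 * pad
  fs <- sampling_rate
  t <- seq(0, total, by = 1 / fs)
  n <- length(t)
  active <- as.numeric(t >= pad & t <= pad + active_dur)
  turn_center <- pad + leg + turn_dur / 2

  mult <- 1 + effect_size * severity
  a_lat <- (if (kind == "natural") 0.35 else 0.5) * amp_factor
  r_roll <- (if (kind == "natural") 0.25 else 0.35) * amp_factor
  f_step <- 1.8

  ph <- stats::runif(6, 0, 2 * pi)
  acc_x <- active * a_lat * mult * sin(2 * pi * 0.9 * t + ph[1])
  acc_y <- active * (1.6 * amp_factor * sin(2 * pi * f_step * t + ph[2]) +
                       0.25 * sin(2 * pi * 2 * f_step * t + ph[3]))
  acc_z <- active * (1.2 * amp_factor * sin(2 * pi * f_step * t + ph[4]) +
                       0.4 * sin(2 * pi * 2 * f_step * t + ph[5])) - GRAVITY

  # 180-degree turn: yaw-rate Hann pulse integrating to pi, random direction
  turn_sign <- sample(c(-1, 1), 1)
  tau <- (t - (turn_center - turn_dur / 2)) / turn_dur
  pulse <- ifelse(tau >= 0 & tau <= 1, 0.5 * (1 - cos(2 * pi * tau)), 0)
  rot_yaw <- turn_sign * (2 * pi / turn_dur) * pulse  # integrates to pi

  rot_pitch <- active * 0.15 * amp_factor * sin(2 * pi * f_step * t + ph[6])
  rot_roll <- active * r_roll * mult * sin(2 * pi * 0.9 * t + ph[1] + 0.4)

  acc_g <- cbind(acc_x, acc_y, acc_z) +
    matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  rot_g <- cbind(rot_pitch, rot_roll, rot_yaw) +
    matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)

  att <- session_attitude(orientation, t)
  dev <- to_device_frame(acc_g, rot_g, att)
  sensor_stream(t, dev$acceleration, dev$rotation_rate, att,
                kind = paste0(kind, "_walk"),
                meta = list(turn_time = turn_center, active_start = pad,
                            active_end = pad + active_dur,
                            orientation = orientation))
}

# ---- stance tasks ----------------------------------------------------------

# Band-limited (0.1-2 Hz) unit-SD sway noise.
sway_noise <- function(n, fs) {
  ny <- fs / 2
  bf <- signal::butter(2, c(0.1, min(2, 0.9 * ny)) / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]
  s <- stats::sd(x)
  if (s < .Machine$double.eps) x else x / s
}

#' Synthesize a stance task stream
#'
#' Postural sway is band-limited (0.1-2 Hz) noise on each axis. For the
#' Romberg stance the stream holds two labelled 10-s phases (`eyes_open`,
#' `eyes_closed`); the foot-neuropathy multiplier applies far more strongly
#' to the eyes-closed phase, reflecting the proprioceptive deficit the task
#' isolates. With `severity = 0` the two phases are identically distributed.
#'
#' @inheritParams synthesize_walk
#' @param kind `"tandem"` (single 10-s stance) or `"romberg"` (two phases)
#' @return a [sensor_stream()]; Romberg streams carry per-sample `phase`
#'   labels
#' @export
synthesize_stance <- function(severity, kind = c("tandem", "romberg"),
                              orientation = quat_random(), effect_size = 1,
                              sampling_rate = 100, noise_sd = 0.02,
                              amp_factor = 1) {
  kind <- match.arg(kind)
  stopifnot(severity >= 0, severity <= 1)
  fs <- sampling_rate
  phase_dur <- 10
  phases <- if (kind == "romberg") c("eyes_open", "eyes_closed") else "stance"
  es <- effect_size * severity
  phase_mult <- switch(kind,
                       tandem = c(stance = 1 + 0.6 * es),
                       romberg = c(eyes_open = 1 + 0.3 * es,
                                   eyes_closed = 1 + 1.5 * es))

  t_all <- acc_all <- rot_all <- lab_all <- NULL
  t0 <- 0
  for (ph in phases) {
    t <- seq(0, phase_dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    m <- phase_mult[[ph]]
    acc <- cbind(0.05 * amp_factor * m * sway_noise(n, fs),
                 0.04 * amp_factor * sway_noise(n, fs),
                 0.03 * amp_factor * sway_noise(n, fs) - GRAVITY)
    rot <- cbind(0.04 * amp_factor * sway_noise(n, fs),
                 0.06 * amp_factor * m * sway_noise(n, fs),
                 0.02 * amp_factor * sway_noise(n, fs))
    acc <- acc + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    rot <- rot + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    t_all <- c(t_all, t0 + t)
    acc_all <- rbind(acc_all, acc)
    rot_all <- rbind(rot_all, rot)
    lab_all <- c(lab_all, rep(ph, n))
    t0 <- t0 + phase_dur
  }

  att <- session_attitude(orientation, t_all)
  dev <- to_device_frame(acc_all, rot_all, att)
  sensor_stream(t_all, dev$acceleration, dev$rotation_rate, att,
                phase = if (kind == "romberg") lab_all else NULL,
                kind = paste0(kind, "_stance"),
                meta = list(orientation = orientation))
}

# ---- manual dexterity tasks ------------------------------------------------

#' Synthesize a finger-tapping session
#'
#' Inter-tap intervals follow an AR(1) process whose lag-1 coefficient and
#' marginal SD shift with `effect_size * severity`; the nondominant hand is
#' shifted more strongly than the dominant hand. Tapping stops at
#' min(100 taps, 100 s). Taps are intended to alternate between two screen
#' buttons; alternation errors and touch drift from the intended button
#' center grow with severity.
#'
#' @inheritParams synthesize_walk
#' @param hand `"dominant"` or `"nondominant"`
#' @param effect_size hand-neuropathy effect size
#' @return object of class `tap_session`: tap timestamps, intended/actual
#'   buttons, touch coordinates, hand, and button centers
#' @export
synthesize_taps <- function(severity, hand = c("dominant", "nondominant"),
                            effect_size = 1) {
  hand <- match.arg(hand)
  stopifnot(severity >= 0, severity <= 1)
  hshift <- if (hand == "nondominant") 1 else 0.5
  es <- effect_size * severity * hshift
  mu <- 0.35
  phi <- min(0.9, 0.15 + 0.45 * es)
  sd_marg <- 0.04 * (1 + es)

  n_max <- 100L
  eps_sd <- sd_marg * sqrt(1 - phi^2)
  intervals <- numeric(n_max - 1L)
  prev <- mu
  for (i in seq_len(n_max - 1L)) {
    prev <- mu + phi * (prev - mu) + stats::rnorm(1, sd = eps_sd)
    intervals[i] <- max(0.05, prev)
  }
  times <- c(0, cumsum(intervals))
  keep <- times <= 100
  times <- times[keep]
  n <- length(times)

  centers <- rbind(left = c(100, 400), right = c(220, 400))
  intended <- rep(c("left", "right"), length.out = n)
  p_err <- min(0.5, 0.01 + 0.05 * es)
  err <- stats::runif(n) < p_err
  err[1] <- FALSE
  actual <- intended
  for (i in which(err)) actual[i] <- actual[i - 1L]

  jitter_sd <- 8 * (1 + 0.5 * es)
  drift_rate <- 0.1 * effect_size * severity * hshift
  theta <- stats::runif(1, 0, 2 * pi)
  bias <- drift_rate * times
  xy <- centers[actual, , drop = FALSE] +
    cbind(bias * cos(theta), bias * sin(theta)) +
    matrix(stats::rnorm(2 * n, sd = jitter_sd), n, 2)

  structure(list(timestamps = times,
                 button = actual,
                 intended = intended,
                 x = xy[, 1], y = xy[, 2],
                 hand = hand,
                 button_centers = centers,
                 meta = list(phi = phi, sd_marg = sd_marg)),
            class = "tap_session")
}

#' Synthesize a hole-peg session
#'
#' Four place/remove repetitions; both durations scale with
#' `1 + 0.3 * effect_size * severity` (a weaker hand-neuropathy expression
#' than tapping, mirroring the lower sensitivity of on-screen peg handling).
#'
#' @inheritParams synthesize_taps
#' @return object of class `peg_session` with a 4-row `repetitions` data
#'   frame (place_start, place_end, remove_start, remove_end)
#' @export
synthesize_pegs <- function(severity, effect_size = 1) {
  stopifnot(severity >= 0, severity <= 1)
  slow <- 1 + 0.3 * effect_size * severity
  reps <- matrix(NA_real_, 4, 4,
                 dimnames = list(NULL, c("place_start", "place_end",
                                         "remove_start", "remove_end")))
  t0 <- 0
  for (r in 1:4) {
    place <- slow * max(0.3, stats::rnorm(1, 1.3, 0.15))
    remove <- slow * max(0.2, stats::rnorm(1, 0.9, 0.12))
    gap <- 0.3
    reps[r, ] <- c(t0, t0 + place, t0 + place + gap, t0 + place + gap + remove)
    t0 <- reps[r, 4] + gap
  }
  structure(list(repetitions = as.data.frame(reps)), class = "peg_session")
}

# ---- CIPN20 questionnaire --------------------------------------------------

# Item loading structure: 9 sensory, 8 motor, 3 autonomic items; odd-indexed
# sensory/motor items are hand-referenced, even-indexed foot-referenced
# (items 1-4 are the screening tingling/numbness items: fingers, toes,
# fingers, toes).
cipn20_loads <- function() {
  load <- c(rep(1, 9), rep(0.6, 8), rep(0.25, 3))
  side <- c(rep(c("h", "f"), length.out = 9),
            rep(c("h", "f"), length.out = 8),
            rep("b", 3))
  list(load = load, side = side)
}

#' Generate a CIPN20 questionnaire response
#'
#' Each item score (1-4) is drawn by thresholding a latent value
#' `loading * severity + reporting noise` at 0.25 / 0.5 / 0.75. Sensory items
#' load fully on severity, motor items at 0.6, autonomic items at 0.25;
#' hand-referenced items use the hand severity and foot-referenced items the
#' foot severity. With zero noise, severity 0 gives all items 1 and severity
#' 1 saturates the sensory items at 4.
#'
#' @param severity foot-neuropathy latent severity in \[0, 1\]
#' @param severity_hands hand-neuropathy latent severity (defaults to
#'   `severity`)
#' @param noise_sd reporting noise SD on the latent scale
#' @param treatment_day integer day label attached to the response
#' @return object of class `cipn20_response` with 20 integer items in 1..4
#' @export
generate_cipn20 <- function(severity, severity_hands = severity,
                            noise_sd = 0.15, treatment_day = 0L) {
  stopifnot(severity >= 0, severity <= 1,
            severity_hands >= 0, severity_hands <= 1)
  ld <- cipn20_loads()
  sev <- ifelse(ld$side == "h", severity_hands,
                ifelse(ld$side == "f", severity,
                       (severity + severity_hands) / 2))
  latent <- ld$load * sev + stats::rnorm(20, sd = noise_sd)
  items <- findInterval(latent, c(0.25, 0.5, 0.75)) + 1L
  structure(list(treatment_day = as.integer(treatment_day),
                 items = as.integer(items)),
            class = "cipn20_response")
}

#' Baseline eligibility rule
#'
#' A patient is eligible (no pre-existing neuropathy) iff none of the first
#' 4 CIPN20 items -- tingling and numbness in the fingers and toes -- scores
#' above 1.
#'
#' @param baseline a `cipn20_response`
#' @return `TRUE` iff items 1-4 all equal 1
#' @export
check_eligibility <- function(baseline) {
  stopifnot(inherits(baseline, "cipn20_response"),
            length(baseline$items) == 20L,
            all(baseline$items %in% 1:4))
  all(baseline$items[1:4] == 1L)
}

# Rejection-sample a baseline response until it passes the eligibility rule.
baseline_cipn20 <- function(noise_sd, treatment_day) {
  for (i in 1:200) {
    r <- generate_cipn20(0, 0, noise_sd = noise_sd,
                         treatment_day = treatment_day)
    if (check_eligibility(r)) return(r)
  }
  cipn_error("failed to draw an eligible baseline response",
             "cipnsense_simulation_error")
}

# ---- cohort ----------------------------------------------------------------

#' Simulate a longitudinal patient cohort
#'
#' Draws correlated CIPN-f / CIPN-h statuses at the configured prevalences
#' (Gaussian copula), assigns each patient a baseline timepoint (day -7),
#' one timepoint per cycle, and an end-of-treatment timepoint, and generates
#' all six task sessions plus a CIPN20 response at every timepoint. Latent
#' severity is linear in treatment day for cases (0 at baseline, 1 at end of
#' treatment) and identically 0 for controls, so case and control data are
#' indistinguishable whenever the corresponding effect size is 0. All
#' baseline questionnaires pass [check_eligibility()] by construction.
#'
#' @param config a [sim_config()]
#' @param timepoints optional integer vector of timepoint indices to
#'   generate sessions for (0 = baseline, 1..n_cycles = cycles,
#'   n_cycles + 1 = end of treatment); defaults to all. Labels, severities
#'   and questionnaires are always generated for all timepoints, so
#'   restricting this only skips raw sensor synthesis.
#' @return object of class `cipn_cohort`: a list with `patients` (list of
#'   patient records) and `config`
#' @export
simulate_cohort <- function(config, timepoints = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  rho <- config$label_correlation

  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cipn_f <- z1 < stats::qnorm(config$prevalence_f)
  cipn_h <- z2 < stats::qnorm(config$prevalence_h)

  tp_days <- c(-7L, as.integer((seq_len(config$n_cycles) - 1L) *
                                 config$cycle_interval_days),
               as.integer(config$n_cycles * config$cycle_interval_days))
  tp_idx <- seq_along(tp_days) - 1L
  if (is.null(timepoints)) timepoints <- tp_idx
  eot_day <- tp_days[length(tp_days)]
  span <- config$n_cycles * config$cycle_interval_days

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    # gait amplitudes vary much more between people (pace, build) than
    # quiet-stance sway does; this heterogeneity is label-independent
    walk_amp <- exp(stats::rnorm(1, 0, 0.35))
    stance_amp <- exp(stats::rnorm(1, 0, 0.10))
    ramp <- pmin(1, pmax(0, tp_days / span))
    sev_f <- if (cipn_f[i]) ramp else rep(0, length(tp_days))
    sev_h <- if (cipn_h[i]) ramp else rep(0, length(tp_days))

    sessions <- list()
    questionnaires <- vector("list", length(tp_days))
    for (k in seq_along(tp_days)) {
      day <- tp_days[k]
      tp <- tp_idx[k]
      sf <- sev_f[k]
      sh <- sev_h[k]
      questionnaires[[k]] <- if (tp == 0L) {
        baseline_cipn20(config$cipn20_noise_sd, day)
      } else {
        generate_cipn20(sf, sh, noise_sd = config$cipn20_noise_sd,
                        treatment_day = day)
      }
      if (!(tp %in% timepoints)) next
      sess_amp <- c(walk_amp, walk_amp, stance_amp, stance_amp) *
        exp(stats::rnorm(4, 0, 0.05))
      mk <- function(kind, data, extra = list()) {
        c(list(session_id = sprintf("%s_t%02d_%s", pid, tp, kind),
               patient_id = pid, kind = kind, treatment_day = day,
               timepoint = tp, data = data), extra)
      }
      sessions <- c(sessions, list(
        mk("natural_walk",
           synthesize_walk(sf, "natural", quat_random(),
                           effect_size = config$effect_size_f,
                           sampling_rate = config$sampling_rate,
                           noise_sd = config$noise_sd,
                           amp_factor = sess_amp[1])),
        mk("tandem_walk",
           synthesize_walk(sf, "tandem", quat_random(),
                           effect_size = config$effect_size_f,
                           sampling_rate = config$sampling_rate,
                           noise_sd = config$noise_sd,
                           amp_factor = sess_amp[2])),
        mk("tandem_stance",
           synthesize_stance(sf, "tandem", quat_random(),
                             effect_size = config$effect_size_f,
                             sampling_rate = config$sampling_rate,
                             noise_sd = config$noise_sd,
                             amp_factor = sess_amp[3])),
        mk("romberg_stance",
           synthesize_stance(sf, "romberg", quat_random(),
                             effect_size = config$effect_size_f,
                             sampling_rate = config$sampling_rate,
                             noise_sd = config$noise_sd,
                             amp_factor = sess_amp[4])),
        mk("finger_tapping",
           list(dominant = synthesize_taps(sh, "dominant",
                                           config$effect_size_h),
                nondominant = synthesize_taps(sh, "nondominant",
                                              config$effect_size_h))),
        mk("hole_peg", synthesize_pegs(sh, config$effect_size_h))))
    }

    patients[[i]] <- structure(
      list(patient_id = pid, cipn_f = cipn_f[i], cipn_h = cipn_h[i],
           severity_trajectory = data.frame(day = tp_days, severity_f = sev_f,
                                            severity_h = sev_h),
           sessions = sessions, questionnaires = questionnaires),
      class = "patient_record")
  }

  structure(list(patients = patients, config = config,
                 timepoint_days = tp_days, eot_day = eot_day),
            class = "cipn_cohort")
}

#' @export
print.cipn_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cipn_cohort: %d patients, %d timepoints, CIPN-f %d, CIPN-h %d>\n",
              length(x$patients), length(x$timepoint_days),
              sum(lab$cipn_f), sum(lab$cipn_h)))
  invisible(x)
}

#' End-of-treatment diagnosis labels of a cohort
#' @param cohort a `cipn_cohort`
#' @return data frame with patient_id, cipn_f, cipn_h
#' @export
cohort_labels <- function(cohort) {
  data.frame(patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
             cipn_f = vapply(cohort$patients, `[[`, NA, "cipn_f"),
             cipn_h = vapply(cohort$patients, `[[`, NA, "cipn_h"))
}

#' CIPN20 item matrix for one timepoint
#' @param cohort a `cipn_cohort`
#' @param timepoint timepoint index (0 = baseline)
#' @return data frame: patient_id, treatment_day, item01..item20
#' @export
cohort_cipn20 <- function(cohort, timepoint) {
  rows <- lapply(cohort$patients, function(p) {
    q <- p$questionnaires[[timepoint + 1L]]
    stats::setNames(data.frame(p$patient_id, q$treatment_day,
                               t(q$items)),
                    c("patient_id", "treatment_day",
                      sprintf("item%02d", 1:20)))
  })
  do.call(rbind, rows)
}
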