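# Preprocessing: trimming, walk splitting, duration filtering, and rotation
# to the gravity-aligned global frame.

test_that("trimming recovers the active phase and is idempotent", {
  st <- make_padded_walk(pad = 2, active = 10, fs = 50)
  tr <- trim_active_phase(st)
  expect_gte(stream_duration(tr), 9.5)
  expect_lte(stream_duration(tr), 10.5)
  # idempotence
  tr2 <- trim_active_phase(tr)
  expect_identical(tr2$timestamps, tr$timestamps)
  # an already-active stream is unchanged
  active <- make_padded_walk(pad = 0, active = 10, fs = 50)
  expect_identical(trim_active_phase(active)$timestamps, active$timestamps)
})

test_that("an all-still stream raises an empty-sample error", {
  t <- seq(0, 5, by = 0.02)
  still <- make_stream(t, cbind(0 * t, 0 * t, -9.80665 + 0 * t))
  expect_error(trim_active_phase(still),
               class = "cipnsense_empty_sample_error")
})

test_that("walks split at the turnaround within half a second", {
  set.seed(21)
  w <- synthesize_walk(0.3, "natural", sampling_rate = 50)
  tr <- trim_active_phase(w)
  sp <- split_walk(tr)
  expect_false(sp$no_turn)
  expect_lt(abs(sp$turn_time - w$meta$turn_time), 0.5)
  # turn excluded from both legs; durations conserve
  expect_lte(stream_duration(sp$forth) + stream_duration(sp$back),
             stream_duration(tr))
  expect_lt(max(sp$forth$timestamps), sp$turn_time)
  expect_gt(min(sp$back$timestamps), sp$turn_time)
})

test_that("streams without a turn raise a warning and stay whole", {
  st <- make_padded_walk(pad = 0, active = 12, fs = 50)  # zero yaw rate
  expect_warning(sp <- split_walk(st), class = "cipnsense_no_turn_warning")
  expect_true(sp$no_turn)
  expect_null(sp$back)
  expect_identical(sp$forth$timestamps, st$timestamps)
})

test_that("duration filter uses a strict less-than boundary", {
  mk <- function(dur, fs = 100) {
    t <- seq(0, dur, by = 1 / fs)
    make_stream(t, cbind(sin(t), sin(2 * t), -9.80665 + 0 * t))
  }
  expect_false(filter_duration(mk(6.0), "natural"))
  expect_true(filter_duration(mk(7.5), "natural"))    # boundary kept
  expect_false(filter_duration(mk(7.49), "natural"))
  expect_true(filter_duration(mk(10.5), "tandem"))
  expect_false(filter_duration(mk(10.4), "tandem"))
})

test_that("identity attitude with gravity on the vertical axis passes through", {
  t <- seq(0, 10, by = 0.02)
  acc <- cbind(0.1 * sin(2 * pi * t), 0.2 * sin(2 * pi * 1.8 * t),
               -9.80665 + 0.1 * cos(2 * pi * t))
  rot <- cbind(0.05 * sin(t), 0.04 * cos(t), 0 * t)
  st <- make_stream(t, acc, rot)
  cs <- rotate_to_global(st, heading = "stance")
  expect_lt(max(abs(cs$acceleration - acc)), 1e-6)
  expect_lt(max(abs(cs$rotation - rot)), 1e-6)
})

test_that("a known 90-degree roll is undone exactly", {
  q <- quat <- cipnsense:::quat_from_axis_angle(c(0, 1, 0), pi / 2)
  t <- seq(0, 10, by = 0.02)
  n <- length(t)
  acc_g <- cbind(0.1 * sin(2 * pi * t), 0.2 * sin(2 * pi * 1.8 * t),
                 -9.80665 + 0.1 * cos(2 * pi * t))
  rot_g <- cbind(0.05 * sin(t), 0.04 * cos(t), 0 * t)
  inv <- cipnsense:::quat_conjugate(q)
  rotated <- sensor_stream(t, cipnsense:::quat_rotate(inv, acc_g),
                           cipnsense:::quat_rotate(inv, rot_g),
                           matrix(rep(q, each = n), n, 4))
  cs <- rotate_to_global(rotated, heading = "stance")
  expect_lt(max(abs(cs$acceleration - acc_g)), 1e-6)
  expect_lt(max(abs(cs$rotation - rot_g)), 1e-6)
})

test_that("rotation restores gravity to vertical and preserves norms", {
  set.seed(31)
  for (kind in c("natural", "tandem")) {
    w <- synthesize_walk(0.5, kind, sampling_rate = 50)
    cs <- rotate_to_global(w, heading = "walk")
    expect_lt(gravity_angle(cs), 1)
    expect_lt(max(abs(sqrt(rowSums(cs$acceleration^2)) -
                        sqrt(rowSums(w$acceleration^2)))), 1e-9)
    expect_lt(max(abs(sqrt(rowSums(cs$rotation^2)) -
                        sqrt(rowSums(w$rotation_rate^2)))), 1e-9)
  }
})

test_that("a degenerate attitude falls back to gravity alignment with a flag", {
  t <- seq(0, 10, by = 0.02)
  acc <- cbind(0.1 * sin(2 * pi * t), 0.2 * sin(2 * pi * 1.8 * t),
               -9.80665 + 0 * t)
  st <- make_stream(t, acc)
  st$attitude <- st$attitude * NA_real_
  cs <- rotate_to_global(st, heading = "stance")
  expect_true(cs$yaw_indeterminate)
  expect_lt(gravity_angle(cs), 1)
})

test_that("downstream features are orientation invariant", {
  qn <- cipnsense:::quat_normalize
  feats <- function(orient) {
    set.seed(55)
    w <- synthesize_walk(0.5, "natural", orient, sampling_rate = 50)
    tr <- trim_active_phase(w)
    sp <- split_walk(tr)
    cs <- rotate_to_global(sp$forth, heading = "walk")
    cs$leg <- "forth"
    cipnsense:::sample_inertial_features(cs, "natural_walk", 50)
  }
  a <- feats(c(1, 0, 0, 0))
  b <- feats(qn(c(0.4, -0.3, 0.7, 0.2)))
  rel <- abs(a - b) / pmax(abs(a), 1e-12)
  expect_lt(max(rel[is.finite(rel)]), 1e-6)
})

test_that("full preprocessing of a romberg session yields two labelled phases", {
  set.seed(8)
  coh <- tiny_cohort()
  sess <- Filter(function(s) s$kind == "romberg_stance",
                 coh$patients[[1]]$sessions)[[1]]
  pre <- preprocess_session(sess)
  expect_setequal(names(pre$samples), c("eyes_open", "eyes_closed"))
  for (ph in names(pre$samples))
    expect_lt(gravity_angle(pre$samples[[ph]]), 1)
})
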