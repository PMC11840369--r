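# Cohort simulator: determinism, eligibility, study-design structure,
# questionnaire model, tapping/peg generators, effect-size behaviour.

test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_patients = 3), class = "cipnsense_config_error")
  expect_error(sim_config(prevalence_f = 1.2), class = "cipnsense_config_error")
  expect_error(sim_config(cycle_interval_days = 10),
               class = "cipnsense_config_error")
  expect_error(sim_config(effect_size_f = -1), class = "cipnsense_config_error")
  expect_error(sim_config(sampling_rate = 0), class = "cipnsense_config_error")
})

test_that("same seed gives byte-identical cohorts", {
  cfg <- sim_config(n_patients = 4, n_cycles = 1, sampling_rate = 50,
                    seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("cohort structure matches the study design", {
  coh <- tiny_cohort()
  expect_length(coh$patients, 5)
  # baseline (day < 0) + one per cycle + end of treatment
  expect_identical(coh$timepoint_days, c(-7L, 0L, 21L))
  for (p in coh$patients) {
    kinds <- vapply(p$sessions, `[[`, "", "kind")
    days <- vapply(p$sessions, `[[`, 0L, "treatment_day")
    for (d in unique(days))
      expect_setequal(kinds[days == d],
                      c("natural_walk", "tandem_walk", "tandem_stance",
                        "romberg_stance", "finger_tapping", "hole_peg"))
    expect_true(any(days < 0))
    # severity nondecreasing in day; zero everywhere for non-cases
    traj <- p$severity_trajectory
    expect_true(all(diff(traj$severity_f) >= 0))
    if (!p$cipn_f) expect_true(all(traj$severity_f == 0))
    if (!p$cipn_h) expect_true(all(traj$severity_h == 0))
    # all questionnaires valid, baseline eligible
    for (q in p$questionnaires) {
      expect_length(q$items, 20)
      expect_true(all(q$items %in% 1:4))
    }
    expect_true(check_eligibility(p$questionnaires[[1]]))
  }
})

test_that("case counts match the configured prevalences in expectation", {
  cfg0 <- sim_config(n_patients = 45, prevalence_f = 24 / 45,
                     prevalence_h = 29 / 45, seed = 1)
  counts <- t(vapply(1:200, function(s) {
    cfg <- cfg0
    cfg$seed <- s
    lab <- cohort_labels(simulate_cohort(cfg, timepoints = -1L))
    c(f = sum(lab$cipn_f), h = sum(lab$cipn_h))
  }, c(f = 0, h = 0)))
  # binomial means 24 and 29 out of 45; SE of the mean of 200 draws ~ 0.23
  expect_lt(abs(mean(counts[, "f"]) - 24), 1)
  expect_lt(abs(mean(counts[, "h"]) - 29), 1)
})

test_that("eligibility rule covers exactly the first four items", {
  base <- generate_cipn20(0, noise_sd = 0)
  expect_true(check_eligibility(base))
  r <- base
  r$items[2] <- 2L
  expect_false(check_eligibility(r))
  r <- base
  r$items[5] <- 4L
  expect_true(check_eligibility(r))
})

test_that("CIPN20 thresholds saturate and respond monotonically", {
  set.seed(1)
  expect_true(all(generate_cipn20(0, noise_sd = 0)$items == 1L))
  full <- generate_cipn20(1, noise_sd = 0)
  expect_true(all(full$items[1:9] == 4L))  # sensory items at maximum
  # Monte Carlo monotonicity of the expected item score over a severity grid
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_score <- vapply(grid, function(s) {
    mean(replicate(80, mean(generate_cipn20(s, noise_sd = 0.15)$items)))
  }, 0)
  expect_true(all(diff(mean_score) > 0))
})

test_that("tapping stops at 100 taps and AR parameters shift with severity", {
  set.seed(2)
  tp <- synthesize_taps(0, "dominant")
  # mean interval 0.35 s -> well under 100 s, so exactly 100 taps
  expect_length(tp$timestamps, 100)
  expect_lte(max(tp$timestamps), 100)
  expect_equal(tp$meta$phi, 0.15)        # control lag-1 coefficient
  expect_equal(tp$meta$sd_marg, 0.04)    # control marginal SD
  sev <- synthesize_taps(1, "nondominant", effect_size = 1)
  expect_gt(sev$meta$phi, tp$meta$phi)
  expect_gt(sev$meta$sd_marg, tp$meta$sd_marg)
  # nondominant shifted more than dominant at equal severity
  dom <- synthesize_taps(1, "dominant", effect_size = 1)
  expect_gt(sev$meta$phi, dom$meta$phi)
})

test_that("peg sessions always hold 4 ordered repetitions (8 durations)", {
  set.seed(3)
  pg <- synthesize_pegs(0.7)
  reps <- pg$repetitions
  expect_identical(nrow(reps), 4L)
  expect_true(all(reps$place_end > reps$place_start))
  expect_true(all(reps$remove_end > reps$remove_start))
  expect_true(all(reps$remove_start > reps$place_end))
})

test_that("romberg phases are identically scaled at zero severity and the
           eyes-closed effect grows with effect size", {
  sd_closed_roll <- function(effect, severity, seed) {
    set.seed(seed)
    st <- synthesize_stance(severity, "romberg", effect_size = effect,
                            sampling_rate = 50)
    rg <- cipnsense:::quat_rotate(st$attitude, st$rotation_rate)
    vapply(c("eyes_open", "eyes_closed"),
           function(ph) stats::sd(rg[st$phase == ph, 2]), 0)
  }
  expect_identical(sort(unique(synthesize_stance(0, "romberg")$phase)),
                   c("eyes_closed", "eyes_open"))
  # monotone in effect size (Monte Carlo over sessions)
  m <- vapply(c(0, 1, 2), function(e) {
    mean(vapply(1:60, function(s) sd_closed_roll(e, 1, s)["eyes_closed"], 0))
  }, 0)
  expect_true(all(diff(m) > 0))
  # zero severity: open and closed phases share their distribution
  zero <- t(vapply(1:60, function(s) sd_closed_roll(2, 0, s), c(a = 0, b = 0)))
  expect_gt(stats::wilcox.test(zero[, 1], zero[, 2])$p.value, 0.01)
})

test_that("null generator leaves cases and controls indistinguishable", {
  # with both effect sizes 0 the case/control feature distributions agree
  # (two-sample KS on the most sensitive feature, eyes-closed roll SD)
  sd_case <- vapply(1:80, function(s) {
    set.seed(s)
    st <- synthesize_stance(1, "romberg", effect_size = 0, sampling_rate = 50)
    rg <- cipnsense:::quat_rotate(st$attitude, st$rotation_rate)
    stats::sd(rg[st$phase == "eyes_closed", 2])
  }, 0)
  sd_ctrl <- vapply(81:160, function(s) {
    set.seed(s)
    st <- synthesize_stance(0, "romberg", effect_size = 0, sampling_rate = 50)
    rg <- cipnsense:::quat_rotate(st$attitude, st$rotation_rate)
    stats::sd(rg[st$phase == "eyes_closed", 2])
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(sd_case, sd_ctrl)$p.value), 0.01)
})

test_that("walk roll amplitude scales with 1 + effect * severity", {
  roll_sd <- function(severity, effect, seed) {
    set.seed(seed)
    w <- synthesize_walk(severity, "natural", c(1, 0, 0, 0),
                         effect_size = effect, sampling_rate = 50,
                         noise_sd = 0)
    sd(w$rotation_rate[, 2])
  }
  base <- mean(vapply(1:30, function(s) roll_sd(0, 2, s), 0))
  amplified <- mean(vapply(1:30, function(s) roll_sd(1, 2, s + 100), 0))
  # severity 1, effect 2 -> amplitude multiplier 3
  expect_lt(abs(amplified / base - 3), 0.25)
})
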