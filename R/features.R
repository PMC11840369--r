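# Feature extraction: time- and frequency-domain statistics on decomposition
# components of walking/stance signals, tapping interval/drift features per
# hand, and peg duration statistics, assembled into a patient-by-feature
# table with full provenance tags.

TIME_STATS <- c("mean", "sd", "skewness", "kurtosis", "rms", "range", "iqr",
                "mad", "zcr", "sampen")
FREQ_STATS <- c("domfreq", "centroid", "spec_entropy", "ber_low", "ber_mid",
                "ber_high")
AXIS_NAMES <- c("acc_x", "acc_y", "acc_z", "rot_pitch", "rot_roll", "rot_yaw")
TAP_STATS <- c("int_mean", "int_sd", "int_cv", "int_min", "int_max",
               "int_ac1", "int_ac2", "int_ac3", "drift_mean", "drift_sd",
               "drift_slope", "alt_errors")

#' Sample entropy
#'
#' Richman-Moorman sample entropy with embedding dimension `m` and tolerance
#' `r` (Chebyshev distance). Long signals are decimated to at most `max_n`
#' points before the quadratic template search. Returns `Inf` when no
#' template matches extend to length `m + 1` (imputed downstream like any
#' other infinite feature value).
#'
#' @param x numeric vector
#' @param m embedding dimension (default 2)
#' @param r tolerance; default `0.2 * sd(x)`
#' @param max_n decimation cap
#' @return nonnegative value (possibly `Inf`)
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), max_n = 250L) {
  n <- length(x)
  if (n > max_n) {
    x <- x[round(seq(1, n, length.out = max_n))]
    n <- max_n
  }
  if (n < m + 2L) return(NA_real_)
  ab <- sampen_counts(x, as.integer(m), r)
  if (ab[2] <= 0 || ab[1] <= 0) return(Inf)
  -log(ab[1] / ab[2])
}

#' Time- and frequency-domain statistics of one component
#'
#' The registry's per-component statistic set: amplitude/distribution
#' statistics (mean, SD, skewness, kurtosis, RMS, range, IQR, median
#' absolute deviation, zero-crossing rate, sample entropy) and spectral
#' statistics (dominant frequency, spectral centroid, normalized spectral
#' entropy, and low/mid/high band-energy ratios with edges at 1 and 4 Hz).
#'
#' @param component numeric vector from a decomposition
#' @param sampling_rate Hz
#' @return named numeric vector of length 16
#' @export
compute_axis_features <- function(component, sampling_rate) {
  x <- component
  n <- length(x)
  s <- stats::sd(x)
  xc <- x - mean(x)
  sgn <- sign(xc)
  zcr <- if (n > 1) sum(sgn[-1] != sgn[-n] & sgn[-1] != 0 & sgn[-n] != 0) / (n - 1) else 0

  p <- Mod(stats::fft(x))^2
  n_half <- floor(n / 2) + 1L
  p <- p[2:n_half]  # drop DC
  freqs <- (seq_len(n_half - 1L)) * sampling_rate / n
  ptot <- sum(p)
  if (ptot <= 0) {
    domfreq <- centroid <- spec_entropy <- 0
    ber <- c(0, 0, 0)
  } else {
    pn <- p / ptot
    domfreq <- freqs[which.max(p)]
    centroid <- sum(freqs * pn)
    nz <- pn[pn > 0]
    spec_entropy <- -sum(nz * log(nz)) / log(length(pn))
    ber <- c(sum(pn[freqs <= 1]),
             sum(pn[freqs > 1 & freqs <= 4]),
             sum(pn[freqs > 4]))
  }

  c(mean = mean(x), sd = s,
    skewness = if (s > 0) e1071::skewness(x) else 0,
    kurtosis = if (s > 0) e1071::kurtosis(x) else 0,
    rms = sqrt(mean(x^2)), range = max(x) - min(x),
    iqr = stats::IQR(x), mad = stats::mad(x), zcr = zcr,
    sampen = if (s > 0) sample_entropy(x) else 0,
    domfreq = domfreq, centroid = centroid, spec_entropy = spec_entropy,
    ber_low = ber[1], ber_mid = ber[2], ber_high = ber[3])
}

# Lag-k autocorrelation as the Pearson correlation of successive pairs;
# defined as 0 (with no error) for zero-variance series.
lag_cor <- function(x, k) {
  n <- length(x)
  if (n <= k + 1L) return(NA_real_)
  a <- x[1:(n - k)]
  b <- x[(k + 1):n]
  tol <- 1e-9 * max(abs(x), 1)  # zero-variance convention, fp-robust
  if (stats::sd(a) <= tol || stats::sd(b) <= tol) return(0)
  stats::cor(a, b)
}

#' Tapping features for one hand
#'
#' Inter-tap-interval statistics (mean, SD, CV, min, max, lag-1..3
#' autocorrelation), touch drift from the intended button centre (mean, SD,
#' least-squares trend slope) and the alternation error count (consecutive
#' taps on the same button). Features are namespaced by hand. Sessions with
#' fewer than 3 taps return all-missing values.
#'
#' @param session a `tap_session`
#' @return named numeric vector (names prefixed `tap_dom_` / `tap_nond_`)
#' @export
compute_tap_features <- function(session) {
  prefix <- if (session$hand == "dominant") "tap_dom_" else "tap_nond_"
  out <- stats::setNames(rep(NA_real_, length(TAP_STATS)),
                         paste0(prefix, TAP_STATS))
  ts <- session$timestamps
  if (length(ts) < 3L) return(out)
  iv <- diff(ts)
  centers <- session$button_centers[session$intended, , drop = FALSE]
  drift <- sqrt((session$x - centers[, 1])^2 + (session$y - centers[, 2])^2)
  tslope <- if (stats::sd(ts) > 0) {
    stats::cov(ts, drift) / stats::var(ts)
  } else NA_real_
  vals <- c(mean(iv), stats::sd(iv),
            if (mean(iv) != 0) stats::sd(iv) / mean(iv) else NA_real_,
            min(iv), max(iv),
            lag_cor(iv, 1L), lag_cor(iv, 2L), lag_cor(iv, 3L),
            mean(drift), stats::sd(drift), tslope,
            sum(session$button[-1] == session$button[-length(session$button)]))
  stats::setNames(vals, paste0(prefix, TAP_STATS))
}

#' Hole-peg features
#'
#' Mean and SD of the 4 placing durations and of the 4 removing durations
#' (4 features). Incomplete repetitions yield all-missing values.
#'
#' @param session a `peg_session`
#' @return named numeric vector of length 4
#' @export
compute_peg_features <- function(session) {
  nm <- c("peg_place_mean", "peg_place_sd", "peg_remove_mean", "peg_remove_sd")
  reps <- session$repetitions
  ok <- nrow(reps) == 4L && !anyNA(reps) &&
    all(reps$place_end > reps$place_start) &&
    all(reps$remove_end > reps$remove_start)
  if (!ok) return(stats::setNames(rep(NA_real_, 4), nm))
  place <- reps$place_end - reps$place_start
  remove <- reps$remove_end - reps$remove_start
  stats::setNames(c(mean(place), stats::sd(place),
                    mean(remove), stats::sd(remove)), nm)
}

#' The feature registry
#'
#' Enumerates every extracted feature with its provenance: assessment,
#' phase, axis, decomposition component, statistic and domain. Walk features
#' are per axis x 2 IMFs; the tandem stance per axis x 4 wavelet bands; the
#' Romberg stance the same separately per eyes-open/eyes-closed phase;
#' tapping per hand; peg durations 4 statistics.
#'
#' @param n_bands stance wavelet band count
#' @return data frame with columns feature_id, assessment, phase, axis,
#'   component, statistic, domain
#' @export
feature_registry <- function(n_bands = 4L) {
  rows <- list()
  add <- function(assessment, phase, axis, component, statistic) {
    domain <- ifelse(statistic %in% FREQ_STATS, "frequency", "time")
    id <- paste(c(assessment, phase, axis, component, statistic)[
      !is.na(c(assessment, phase, axis, component, statistic))], collapse = ".")
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = id, assessment = assessment,
      phase = ifelse(is.na(phase), NA_character_, phase),
      axis = ifelse(is.na(axis), NA_character_, axis),
      component = ifelse(is.na(component), NA_character_, component),
      statistic = statistic, domain = domain)
  }
  stats_all <- c(TIME_STATS, FREQ_STATS)
  for (walk in c("natural_walk", "tandem_walk"))
    for (ax in AXIS_NAMES)
      for (comp in c("imf1", "imf2"))
        for (st in stats_all) add(walk, NA, ax, comp, st)
  bands <- paste0("band", seq_len(n_bands))
  for (ax in AXIS_NAMES)
    for (comp in bands)
      for (st in stats_all) add("tandem_stance", "stance", ax, comp, st)
  for (ph in c("eyes_open", "eyes_closed"))
    for (ax in AXIS_NAMES)
      for (comp in bands)
        for (st in stats_all) add("romberg_stance", ph, ax, comp, st)
  for (hand in c("dominant", "nondominant")) {
    prefix <- if (hand == "dominant") "tap_dom_" else "tap_nond_"
    for (st in TAP_STATS)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(prefix, st), assessment = "finger_tapping",
        phase = hand, axis = NA_character_, component = NA_character_,
        statistic = st, domain = "time")
  }
  for (st in c("peg_place_mean", "peg_place_sd", "peg_remove_mean",
               "peg_remove_sd"))
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = st, assessment = "hole_peg", phase = NA_character_,
      axis = NA_character_, component = NA_character_, statistic = st,
      domain = "time")
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(reg$feature_id))
  reg
}

# Features for one cleaned inertial sample (walk leg or stance phase).
sample_inertial_features <- function(clean, assessment, sampling_rate,
                                     n_bands = 4L) {
  is_walk <- grepl("walk", assessment)
  signals <- cbind(sweep(clean$acceleration, 2, c(0, 0, -GRAVITY)),
                   clean$rotation)
  colnames(signals) <- AXIS_NAMES
  phase <- if (assessment %in% c("tandem_stance", "romberg_stance"))
    clean$leg else NULL
  out <- numeric(0)
  for (ax in AXIS_NAMES) {
    comps <- if (is_walk) {
      d <- decompose_walk_axis(signals[, ax])
      list(imf1 = d$imf1, imf2 = d$imf2)
    } else {
      b <- decompose_stance_axis(signals[, ax], sampling_rate, n_bands)
      stats::setNames(b, paste0("band", seq_along(b)))
    }
    for (comp in names(comps)) {
      f <- compute_axis_features(comps[[comp]], sampling_rate)
      prefix <- paste(c(assessment, phase, ax, comp), collapse = ".")
      out <- c(out, stats::setNames(f, paste(prefix, names(f), sep = ".")))
    }
  }
  out
}

#' Extract the full feature table of a cohort
#'
#' Preprocesses every session and computes all registry features. Each walk
#' leg produces its own row; the Romberg phases produce phase-tagged
#' feature blocks on a single row; tapping (both hands) and peg features
#' share the row of their assessment. Rows are keyed by (patient_id,
#' sample_id, treatment_day, timepoint, assessment, leg); missing values
#' (discarded legs, too-few taps) are explicit `NA`s and infinite values
#' are kept as `Inf` for downstream imputation.
#'
#' @param cohort a `cipn_cohort`
#' @param timepoints integer vector of timepoint indices to extract
#'   (default: all generated)
#' @param registry feature registry (default [feature_registry()])
#' @param trim_threshold activity threshold for walk trimming
#' @return object of class `feature_table`: a data frame of key columns
#'   followed by one column per registry feature, with the registry stored
#'   in `attr(, "registry")` and a QC log in `attr(, "qc")`
#' @export
extract_all <- function(cohort, timepoints = NULL,
                        registry = feature_registry(),
                        trim_threshold = 0.05) {
  fs <- cohort$config$sampling_rate
  keys <- list()
  vals <- list()
  qc <- list()

  for (p in cohort$patients) {
    by_tp <- split(p$sessions,
                   vapply(p$sessions, `[[`, 0L, "timepoint"))
    for (tp_name in names(by_tp)) {
      tp <- as.integer(tp_name)
      if (!is.null(timepoints) && !(tp %in% timepoints)) next
      sess_list <- by_tp[[tp_name]]
      for (sess in sess_list) {
        pre <- preprocess_session(sess, trim_threshold)
        qc[[length(qc) + 1L]] <- pre$qc
        push <- function(leg, fv) {
          keys[[length(keys) + 1L]] <<- c(sess$patient_id, sess$session_id,
                                          sess$treatment_day, tp, sess$kind,
                                          leg)
          vals[[length(vals) + 1L]] <<- fv
        }
        if (sess$kind %in% c("natural_walk", "tandem_walk")) {
          for (leg in names(pre$samples))
            push(leg, sample_inertial_features(pre$samples[[leg]],
                                               sess$kind, fs))
        } else if (sess$kind %in% c("tandem_stance", "romberg_stance")) {
          fv <- numeric(0)
          for (ph in names(pre$samples))
            fv <- c(fv, sample_inertial_features(pre$samples[[ph]],
                                                 sess$kind, fs))
          push("stance", fv)
        } else if (sess$kind == "finger_tapping") {
          push("taps", c(compute_tap_features(sess$data$dominant),
                         compute_tap_features(sess$data$nondominant)))
        } else if (sess$kind == "hole_peg") {
          push("pegs", compute_peg_features(sess$data))
        }
      }
    }
  }

  mat <- matrix(NA_real_, nrow = length(vals), ncol = nrow(registry),
                dimnames = list(NULL, registry$feature_id))
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    v <- v[names(v) %in% colnames(mat)]
    mat[i, names(v)] <- v
  }
  key_df <- if (length(keys)) {
    km <- do.call(rbind, keys)
    data.frame(patient_id = km[, 1], sample_id = km[, 2],
               treatment_day = as.integer(km[, 3]),
               timepoint = as.integer(km[, 4]), assessment = km[, 5],
               leg = km[, 6])
  } else {
    data.frame(patient_id = character(), sample_id = character(),
               treatment_day = integer(), timepoint = integer(),
               assessment = character(), leg = character())
  }
  out <- cbind(key_df, as.data.frame(mat, optional = TRUE))
  attr(out, "registry") <- registry
  attr(out, "qc") <- if (length(qc)) do.call(rbind, qc) else NULL
  class(out) <- c("feature_table", class(out))
  out
}

#' Key column names of a feature table
#' @keywords internal
feature_key_cols <- function() {
  c("patient_id", "sample_id", "treatment_day", "timepoint", "assessment",
    "leg")
}

#' Build a per-leg modelling table for one timepoint
#'
#' Joins a timepoint's samples into classifier rows: one row per
#' (patient, walking leg), carrying that leg's natural- and tandem-walk
#' features together with the patient's stance, tapping and peg features
#' (which are leg-independent and repeated on both rows). Patients with no
#' usable walk leg at the timepoint contribute a single row with walk
#' features missing.
#'
#' @param features a `feature_table` from [extract_all()]
#' @param timepoint timepoint index
#' @return data frame: patient_id, treatment_day, leg, then all registry
#'   feature columns
#' @export
build_model_table <- function(features, timepoint) {
  registry <- attr(features, "registry")
  ft <- features[features$timepoint == timepoint, , drop = FALSE]
  feat_cols <- registry$feature_id
  walk_cols <- feat_cols[grepl("_walk\\.", feat_cols)]
  other_cols <- setdiff(feat_cols, walk_cols)
  fm <- as.matrix(ft[, feat_cols, drop = FALSE])

  key_rows <- list()
  val_rows <- list()
  for (pid in unique(ft$patient_id)) {
    sel <- which(ft$patient_id == pid)
    day <- ft$treatment_day[sel[1]]
    is_walk_row <- ft$assessment[sel] %in% c("natural_walk", "tandem_walk")
    shared <- stats::setNames(rep(NA_real_, length(other_cols)), other_cols)
    for (i in sel[!is_walk_row]) {
      v <- fm[i, other_cols]
      shared[!is.na(v)] <- v[!is.na(v)]
    }
    legs <- intersect(c("forth", "back"), unique(ft$leg[sel[is_walk_row]]))
    if (length(legs) == 0L) legs <- NA_character_
    for (leg in legs) {
      wf <- stats::setNames(rep(NA_real_, length(walk_cols)), walk_cols)
      if (!is.na(leg)) {
        for (i in sel[is_walk_row][ft$leg[sel[is_walk_row]] == leg]) {
          v <- fm[i, walk_cols]
          wf[!is.na(v)] <- v[!is.na(v)]
        }
      }
      key_rows[[length(key_rows) + 1L]] <-
        data.frame(patient_id = pid, treatment_day = day, leg = leg)
      val_rows[[length(val_rows) + 1L]] <- c(wf, shared)[feat_cols]
    }
  }
  out <- cbind(do.call(rbind, key_rows),
               as.data.frame(do.call(rbind, val_rows), optional = TRUE))
  rownames(out) <- NULL
  out
}
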