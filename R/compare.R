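# Model comparison: paired patient-level bootstrap AUC tests, per-assessment
# contribution (single-assessment and leave-one-out models), and monthly
# treatment-window AUC trajectories.

#' Paired bootstrap comparison of two AUCs
#'
#' Resamples patients with replacement `n_boot` times (resamples with a
#' single outcome class are redrawn), recomputing the AUC difference of two
#' paired prediction vectors each time. The one-sided p-value (alternative:
#' A has higher AUC than B) is the fraction of resamples contradicting the
#' alternative; the two-sided p-value doubles the smaller tail fraction,
#' capped at 1. Both use the (count + 1) / (n_boot + 1) convention, so
#' p is in (0, 1].
#'
#' @param pred_a,pred_b per-patient predicted probabilities on the same
#'   patients
#' @param labels logical diagnosis per patient
#' @param sided `"two"` or `"one"`
#' @param n_boot bootstrap resample count (default 400)
#' @param seed RNG seed
#' @return object of class `auc_comparison`: AUCs, delta, p-value, and the
#'   bootstrap delta distribution
#' @export
bootstrap_auc_compare <- function(pred_a, pred_b, labels,
                                  sided = c("two", "one"), n_boot = 400L,
                                  seed = 1L) {
  sided <- match.arg(sided)
  stopifnot(length(pred_a) == length(pred_b),
            length(pred_a) == length(labels))
  labels <- as.logical(labels)
  set.seed(seed)
  n <- length(labels)
  auc_a <- auc_rank(pred_a, labels)
  auc_b <- auc_rank(pred_b, labels)
  delta <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    delta[b] <- auc_rank(pred_a[idx], labels[idx]) -
      auc_rank(pred_b[idx], labels[idx])
  }
  p <- if (sided == "one") {
    (sum(delta <= 0) + 1) / (n_boot + 1)
  } else {
    lo <- (sum(delta <= 0) + 1) / (n_boot + 1)
    hi <- (sum(delta >= 0) + 1) / (n_boot + 1)
    min(1, 2 * min(lo, hi))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                 p_value = p, sided = sided, n_boot = n_boot,
                 boot_delta = delta),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("<auc_comparison: %.3f vs %.3f (delta %+.3f), %s-sided p=%.3g>\n",
              x$auc_a, x$auc_b, x$delta, x$sided, x$p_value))
  invisible(x)
}

#' Percentile bootstrap confidence interval for one AUC
#'
#' Patient-level bootstrap of a single prediction vector.
#'
#' @inheritParams bootstrap_auc_compare
#' @param pred per-patient predicted probabilities
#' @param level confidence level
#' @return named vector `c(lower, estimate, upper)`
#' @export
bootstrap_auc_ci <- function(pred, labels, n_boot = 400L, level = 0.95,
                             seed = 1L) {
  labels <- as.logical(labels)
  set.seed(seed)
  n <- length(labels)
  est <- auc_rank(pred, labels)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    boots[b] <- auc_rank(pred[idx], labels[idx])
  }
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(lower = qs[1], estimate = est, upper = qs[2])
}

#' Per-assessment contribution analysis
#'
#' For each assessment, builds a single-assessment model and a leave-one-out
#' model through the full selection + training stack and compares each with
#' the all-assessment model on the shared held-out patients using the
#' one-sided bootstrap test.
#'
#' @param baseline,end_of_treatment model tables for selection
#' @param outcome named logical diagnosis vector
#' @param registry feature registry
#' @param full_model the all-assessment `cipn_model` to compare against
#' @param seed RNG seed (split seed is reused from `full_model`)
#' @param n_boot bootstrap resamples
#' @return data frame: assessment, scope (single/leave_one_out), n_features,
#'   auc, auc_full, delta, p_value
#' @export
assessment_contribution <- function(baseline, end_of_treatment, outcome,
                                    registry, full_model, seed = 1L,
                                    n_boot = 400L) {
  test_tab <- end_of_treatment[end_of_treatment$patient_id %in%
                                 full_model$test_patients, , drop = FALSE]
  probs_full <- predict(full_model, test_tab)
  pat_full <- tapply(probs_full, test_tab$patient_id, mean)
  labels <- as.logical(outcome[names(pat_full)])

  assessments <- unique(registry$assessment)
  rows <- list()
  for (a in assessments) {
    for (scope in c("single", "leave_one_out")) {
      keep <- if (scope == "single") a else setdiff(assessments, a)
      reg_sub <- registry[registry$assessment %in% keep, , drop = FALSE]
      # selection restricted to the full model's training patients so the
      # shared held-out set stays unbiased
      sel <- withCallingHandlers(
        select_three_step(
          baseline[baseline$patient_id %in% full_model$train_patients, ,
                   drop = FALSE],
          end_of_treatment[end_of_treatment$patient_id %in%
                             full_model$train_patients, , drop = FALSE],
          outcome, reg_sub),
        cipnsense_empty_selection_warning = function(w)
          invokeRestart("muffleWarning"))
      if (length(sel$selected) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          assessment = a, scope = scope, n_features = 0L, auc = NA_real_,
          auc_full = unname(auc_rank(as.numeric(pat_full), labels)),
          delta = NA_real_, p_value = NA_real_, note = "non_contributory")
        next
      }
      m <- train_cipn_model(end_of_treatment, outcome, sel$selected,
                            seed = full_model$seed,
                            train_patients = full_model$train_patients)
      probs <- predict(m, test_tab)
      pat_prob <- tapply(probs, test_tab$patient_id, mean)
      cmp <- bootstrap_auc_compare(as.numeric(pat_full),
                                   as.numeric(pat_prob[names(pat_full)]),
                                   labels, sided = "one", n_boot = n_boot,
                                   seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        assessment = a, scope = scope, n_features = length(sel$selected),
        auc = cmp$auc_b, auc_full = cmp$auc_a, delta = cmp$auc_a - cmp$auc_b,
        p_value = cmp$p_value, note = "")
    }
  }
  do.call(rbind, rows)
}

#' Assign treatment days to monthly windows
#'
#' M0 = pre-treatment (day < 0), M1 = days 0-29, M2 = days 30-59,
#' M3 = days 60-89; later days are flagged `out_of_range`.
#'
#' @param day integer vector of treatment days
#' @param m3_end final day of M3 (default 89)
#' @return character vector of window ids
#' @export
assign_window <- function(day, m3_end = 89) {
  ifelse(day < 0, "M0",
         ifelse(day <= 29, "M1",
                ifelse(day <= 59, "M2",
                       ifelse(day <= m3_end, "M3", "out_of_range"))))
}

#' Windowed AUC trajectory of a fitted model
#'
#' Applies a trained end-of-treatment model to every sample of each monthly
#' window; each patient is represented by the mean predicted probability
#' over their samples in the window, and patients with no sample in a
#' window are omitted. AUC is computed against the end-of-treatment
#' diagnosis.
#'
#' @param model a `cipn_model`
#' @param tables named list of model tables (one per timepoint, any days)
#' @param outcome named logical diagnosis vector
#' @param windows window ids to report
#' @return data frame: window, n_patients, auc (NA with a flag when a
#'   window holds one class)
#' @export
windowed_auc <- function(model, tables, outcome,
                         windows = c("M0", "M1", "M2", "M3")) {
  tab <- do.call(rbind, tables)
  tab$window <- assign_window(tab$treatment_day)
  rows <- list()
  for (w in windows) {
    sub <- tab[tab$window == w, , drop = FALSE]
    if (nrow(sub) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(window = w, n_patients = 0L,
                                              auc = NA_real_,
                                              undefined = TRUE)
      next
    }
    probs <- predict(model, sub)
    pat_prob <- tapply(probs, sub$patient_id, mean)
    y <- as.logical(outcome[names(pat_prob)])
    undef <- length(unique(y)) < 2L
    rows[[length(rows) + 1L]] <- data.frame(
      window = w, n_patients = length(pat_prob),
      auc = if (undef) NA_real_ else auc_rank(as.numeric(pat_prob), y),
      undefined = undef)
  }
  do.call(rbind, rows)
}
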