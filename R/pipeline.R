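# End-to-end pipeline: configuration, file formats, and the full analysis
# (simulate -> preprocess -> extract -> select -> train sensor-only/CIPN20/
# Combined models for both outcomes -> compare -> windowed AUC -> detection
# timeline).

#' Pipeline configuration
#'
#' Nested configuration covering every stage, with defaults reproducing the
#' analysis constants: 7.5 / 10.5 s walking-duration filters, 5/5/15 mRMR
#' solution sets, 70% training fraction, 1.5x infinite-value imputation,
#' 400 bootstrap resamples, M0-M3 monthly windows and alpha = 0.05.
#'
#' @param simulation list of [sim_config()] arguments
#' @param preprocessing list: trim_threshold (m/s^2), trim_window (s)
#' @param registry list: n_bands
#' @param selection list: n_sets_step1, n_sets_step2, n_sets_step3, n_bins
#' @param training list: split_fraction, n_alpha, n_lambda
#' @param comparison list: n_boot
#' @param timeline list: alpha, min_run (-1 = sustained through follow-up)
#' @param seed master seed; per-stage seeds are derived from it
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(simulation = list(),
                            preprocessing = list(trim_threshold = 0.05,
                                                 trim_window = 1),
                            registry = list(n_bands = 4L),
                            selection = list(n_sets_step1 = 5L,
                                             n_sets_step2 = 5L,
                                             n_sets_step3 = 15L,
                                             n_bins = 4L),
                            training = list(split_fraction = 0.7,
                                            n_alpha = 10L, n_lambda = 100L),
                            comparison = list(n_boot = 400L),
                            timeline = list(alpha = 0.05, min_run = -1),
                            seed = 1L) {
  defaults <- formals(pipeline_config)
  cfg <- list(simulation = simulation,
              preprocessing = utils::modifyList(eval(defaults$preprocessing),
                                                preprocessing),
              registry = utils::modifyList(eval(defaults$registry), registry),
              selection = utils::modifyList(eval(defaults$selection),
                                            selection),
              training = utils::modifyList(eval(defaults$training), training),
              comparison = utils::modifyList(eval(defaults$comparison),
                                             comparison),
              timeline = utils::modifyList(eval(defaults$timeline), timeline),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration (YAML)
#'
#' Round-trip safe: `load_pipeline_config(save_pipeline_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a `pipeline_config`
#' @param path file path
#' @return the path (save) or the configuration (load)
#' @export
save_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Stable short hash of a configuration (recorded in every output).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 512)))
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# ---- session / cohort file formats ----------------------------------------

#' Write one assessment session as JSON
#'
#' Inertial sessions are stored as a metadata header plus columnar arrays
#' (timestamp, acceleration, rotation_rate, attitude, phase); tapping and
#' peg sessions as event lists.
#'
#' @param session an assessment session
#' @param path output file
#' @export
write_session_json <- function(session, path) {
  meta <- list(session_id = session$session_id,
               patient_id = session$patient_id, kind = session$kind,
               treatment_day = session$treatment_day,
               timepoint = session$timepoint)
  body <- if (inherits(session$data, "sensor_stream")) {
    s <- session$data
    list(timestamps = s$timestamps, acceleration = s$acceleration,
         rotation_rate = s$rotation_rate, attitude = s$attitude,
         phase = s$phase)
  } else if (session$kind == "finger_tapping") {
    lapply(session$data, function(tp) {
      list(hand = tp$hand, timestamps = tp$timestamps, button = tp$button,
           intended = tp$intended, x = tp$x, y = tp$y,
           button_centers = tp$button_centers)
    })
  } else {
    list(repetitions = session$data$repetitions)
  }
  jsonlite::write_json(list(meta = meta, data = body), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an assessment session written by [write_session_json()]
#' @param path JSON file path
#' @return an assessment session list
#' @export
read_session_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- j$meta
  data <- if (!is.null(j$data$timestamps)) {
    sensor_stream(j$data$timestamps, as.matrix(j$data$acceleration),
                  as.matrix(j$data$rotation_rate), as.matrix(j$data$attitude),
                  phase = j$data$phase, kind = meta$kind)
  } else if (meta$kind == "finger_tapping") {
    lapply(j$data, function(tp) {
      structure(list(timestamps = tp$timestamps, button = tp$button,
                     intended = tp$intended, x = tp$x, y = tp$y,
                     hand = tp$hand,
                     button_centers = as.matrix(tp$button_centers)),
                class = "tap_session")
    })
  } else {
    structure(list(repetitions = as.data.frame(j$data$repetitions)),
              class = "peg_session")
  }
  c(meta, list(data = data))
}

#' Write the cohort-level CSV
#'
#' One row per patient and questionnaire: patient_id, treatment_day,
#' diagnoses and the 20 CIPN20 items.
#'
#' @param cohort a `cipn_cohort`
#' @param path output CSV path
#' @export
write_cohort_csv <- function(cohort, path) {
  lab <- cohort_labels(cohort)
  rows <- do.call(rbind, lapply(seq_along(cohort$timepoint_days) - 1L,
                                function(tp) cohort_cipn20(cohort, tp)))
  rows <- merge(lab, rows, by = "patient_id")
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' One JSON file per session plus `cohort.csv` with labels and
#' questionnaires.
#'
#' @param cohort a `cipn_cohort`
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients)
    for (s in p$sessions)
      write_session_json(s, file.path(dir, paste0(s$session_id, ".json")))
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' Write a feature table and its registry manifest as CSV
#'
#' @param features a `feature_table` from [extract_all()]
#' @param path CSV path for the table; the registry manifest is written
#'   alongside with suffix `_registry.csv`
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  utils::write.csv(attr(features, "registry"),
                   sub("\\.csv$", "_registry.csv", path), row.names = FALSE)
  invisible(path)
}

#' Write three-step selection results as CSV
#'
#' One row per (step, assessment, feature) with its vote count and whether
#' it was retained.
#'
#' @param selection result of [select_three_step()]
#' @param path output CSV path
#' @export
write_selection_csv <- function(selection, path) {
  rows <- list()
  add_votes <- function(step, scope, kept) {
    v <- attr(kept, "votes")
    if (is.null(v) || length(v) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      step = step, scope = scope, feature_id = names(v),
      votes = as.integer(v), retained = names(v) %in% as.character(kept))
  }
  for (a in names(selection$step1)) add_votes(1L, a, selection$step1[[a]])
  for (a in names(selection$step2)) add_votes(2L, a, selection$step2[[a]])
  add_votes(3L, "pooled", selection$step3)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), scope = character(),
               feature_id = character(), votes = integer(),
               retained = logical())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- full analysis ---------------------------------------------------------

# Build the CIPN20 item table for a timepoint, column-compatible with the
# classifier interface.
cipn20_table <- function(cohort, timepoint) {
  tab <- cohort_cipn20(cohort, timepoint)
  tab$leg <- "cipn20"
  tab
}

cipn20_item_ids <- function() sprintf("item%02d", 1:20)

# Join the sensor model table with the CIPN20 items per patient.
combined_table <- function(model_tab, items_tab) {
  m <- merge(model_tab, items_tab[, c("patient_id", cipn20_item_ids())],
             by = "patient_id", sort = FALSE)
  m
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, extracts all features, runs three-step mRMR
#' selection, trains sensor-only, CIPN20-only and Combined elastic-net
#' models for both outcomes (CIPN-f, CIPN-h), evaluates them on the shared
#' held-out patients, compares AUCs with the paired bootstrap, computes the
#' monthly-window (M0-M3) AUC trajectory and the earliest-detection
#' timeline for each model. Fully reproducible given `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for artifacts (summary JSON and
#'   CSV reports)
#' @param contribution also run the per-assessment contribution analysis
#'   (slow; default FALSE)
#' @return run report list (invisibly written to `out_dir` when given)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         contribution = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cipn_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 "cipnsense_stage_error")
    })
  }
  cohort <- stage("simulate", {
    scfg <- do.call(sim_config,
                    utils::modifyList(config$simulation,
                                      list(seed = derive_seed(config$seed, 1))))
    simulate_cohort(scfg)
  })
  registry <- feature_registry(config$registry$n_bands)
  features <- stage("extract",
                    extract_all(cohort, registry = registry,
                                trim_threshold = config$preprocessing$trim_threshold))

  tps <- sort(unique(features$timepoint))
  eot_tp <- max(tps)
  tables <- lapply(tps, function(tp) build_model_table(features, tp))
  names(tables) <- as.character(tps)
  baseline_tab <- tables[["0"]]
  eot_tab <- tables[[as.character(eot_tp)]]
  items <- lapply(tps, function(tp) cipn20_table(cohort, tp))
  names(items) <- as.character(tps)
  combined <- lapply(as.character(tps), function(tp)
    combined_table(tables[[tp]], items[[tp]]))
  names(combined) <- as.character(tps)

  lab <- cohort_labels(cohort)
  outcomes <- list(cipn_f = stats::setNames(lab$cipn_f, lab$patient_id),
                   cipn_h = stats::setNames(lab$cipn_h, lab$patient_id))

  report <- list(config_hash = config_hash(config),
                 seed = config$seed,
                 n_patients = length(cohort$patients),
                 registry_size = nrow(registry),
                 qc = attr(features, "qc"))
  min_run <- if (config$timeline$min_run < 0) Inf else config$timeline$min_run

  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    train_seed <- derive_seed(config$seed, 2 + match(oc, names(outcomes)))
    # the patient-level split is drawn before feature selection, and
    # selection sees training patients only, so the held-out 30% stays
    # untouched until evaluation
    set.seed(train_seed)
    all_pats <- lab$patient_id
    train_pats <- split_patients(all_pats, as.logical(y[all_pats]),
                                 config$training$split_fraction)
    sel <- stage("select",
                 withCallingHandlers(
                   select_three_step(
                     baseline_tab[baseline_tab$patient_id %in% train_pats, ,
                                  drop = FALSE],
                     eot_tab[eot_tab$patient_id %in% train_pats, ,
                             drop = FALSE],
                     y, registry,
                     config$selection$n_sets_step1,
                     config$selection$n_sets_step2,
                     config$selection$n_sets_step3,
                     config$selection$n_bins),
                   cipnsense_empty_selection_warning = function(w)
                     invokeRestart("muffleWarning")))
    sensor_feats <- if (length(sel$selected) > 0) sel$selected else
      registry$feature_id

    specs <- list(
      sensor = list(tabs = tables, feats = sensor_feats),
      cipn20 = list(tabs = items, feats = cipn20_item_ids()),
      combined = list(tabs = combined,
                      feats = c(sensor_feats, cipn20_item_ids())))

    models <- list()
    evals <- list()
    for (src in names(specs)) {
      sp <- specs[[src]]
      m <- stage(paste0("train_", src),
                 train_cipn_model(sp$tabs[[as.character(eot_tp)]], y,
                                  sp$feats, seed = train_seed,
                                  split_fraction = config$training$split_fraction,
                                  alpha_grid = seq(0.1, 1,
                                                   length.out = config$training$n_alpha),
                                  n_lambda = config$training$n_lambda,
                                  train_patients = train_pats))
      test_tab <- sp$tabs[[as.character(eot_tp)]]
      test_tab <- test_tab[test_tab$patient_id %in% m$test_patients, ,
                           drop = FALSE]
      ev <- evaluate_cipn_model(m, test_tab, y)
      models[[src]] <- m
      evals[[src]] <- ev
    }

    # paired comparisons on the shared held-out patients
    shared <- Reduce(intersect, lapply(evals, function(e) names(e$probabilities)))
    ylab <- as.logical(y[shared])
    cmp_seed <- derive_seed(config$seed, 10 + match(oc, names(outcomes)))
    comparisons <- list(
      sensor_vs_cipn20 = bootstrap_auc_compare(
        evals$sensor$probabilities[shared],
        evals$cipn20$probabilities[shared], ylab, sided = "two",
        n_boot = config$comparison$n_boot, seed = cmp_seed),
      combined_vs_sensor = bootstrap_auc_compare(
        evals$combined$probabilities[shared],
        evals$sensor$probabilities[shared], ylab, sided = "two",
        n_boot = config$comparison$n_boot, seed = cmp_seed + 1L),
      combined_vs_cipn20 = bootstrap_auc_compare(
        evals$combined$probabilities[shared],
        evals$cipn20$probabilities[shared], ylab, sided = "two",
        n_boot = config$comparison$n_boot, seed = cmp_seed + 2L))

    windows <- lapply(names(specs), function(src)
      cbind(model = src,
            windowed_auc(models[[src]], specs[[src]]$tabs, y)))
    names(windows) <- names(specs)

    timelines <- list()
    cls_by_src <- list()
    for (src in names(specs)) {
      cls <- do.call(rbind, lapply(as.character(tps), function(tp) {
        tab <- specs[[src]]$tabs[[tp]]
        pr <- predict(models[[src]], tab)
        pat <- tapply(pr, tab$patient_id, mean)
        data.frame(patient_id = names(pat),
                   day = tab$treatment_day[match(names(pat),
                                                 tab$patient_id)],
                   predicted = as.numeric(pat) >= 0.5)
      }))
      cls_by_src[[src]] <- cls
      timelines[[src]] <- detection_timeline(cls, y,
                                             alpha = config$timeline$alpha,
                                             min_run = min_run)
    }

    contrib <- NULL
    if (contribution) {
      contrib <- assessment_contribution(baseline_tab, eot_tab, y, registry,
                                         models$sensor,
                                         seed = cmp_seed + 3L,
                                         n_boot = config$comparison$n_boot)
    }

    report[[oc]] <- list(
      n_selected = length(sel$selected),
      selected = sel$selected,
      models = lapply(names(specs), function(src) {
        ev <- evals[[src]]
        vi <- withCallingHandlers(
          variable_importance(models[[src]], registry),
          cipnsense_zero_importance_warning = function(w)
            invokeRestart("muffleWarning"))
        list(source = src, auc = ev$auc, accuracy = ev$accuracy,
             sensitivity = ev$sensitivity, specificity = ev$specificity,
             nir = ev$nir, p_vs_nir = ev$p_vs_nir,
             n_nonzero = sum(models[[src]]$coefficients != 0),
             importance_by_assessment = as.list(vi$by_assessment))
      }),
      comparisons = lapply(comparisons, function(cc)
        list(auc_a = cc$auc_a, auc_b = cc$auc_b, delta = cc$delta,
             p = cc$p_value)),
      windows = do.call(rbind, windows),
      earliest_day = lapply(timelines, `[[`, "earliest_day"),
      timelines = lapply(timelines, `[[`, "timeline"),
      classifications = cls_by_src,
      contribution = contrib,
      probabilities = lapply(evals, `[[`, "probabilities"))
    names(report[[oc]]$models) <- names(specs)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_json <- report
    for (oc in names(outcomes)) {
      summary_json[[oc]]$probabilities <- NULL
      summary_json[[oc]]$timelines <- NULL
      summary_json[[oc]]$classifications <- NULL
      summary_json[[oc]]$selected <- NULL
      utils::write.csv(cbind(config_hash = report$config_hash,
                             report[[oc]]$windows),
                       file.path(out_dir, paste0("windows_", oc, ".csv")),
                       row.names = FALSE)
      for (src in names(report[[oc]]$timelines))
        utils::write.csv(cbind(config_hash = report$config_hash,
                               report[[oc]]$timelines[[src]]),
                         file.path(out_dir,
                                   paste0("timeline_", oc, "_", src, ".csv")),
                         row.names = FALSE)
    }
    summary_json$qc <- NULL
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(attr(features, "qc")))
      utils::write.csv(attr(features, "qc"), file.path(out_dir, "qc.csv"),
                       row.names = FALSE)
  }
  invisible(report)
}
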