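# Elastic-net CIPN classifiers: preprocessing (infinite-value imputation at
# 1.5x the finite maximum, centring/scaling learned on training rows only),
# a stratified patient-level 70/30 split, repeated cross-validation with
# sqrt(n) folds and repeats over a two-stage hyperparameter grid, and
# evaluation against the no-information rate.

#' Imputation and scaling preprocessing
#'
#' Learns, per column and on the fitting rows only: an imputation cap for
#' infinite values (1.5x the finite column maximum; -Inf uses 1.5x the
#' finite minimum), a mean-imputation value for missing entries, and
#' centre/scale statistics (constant columns scale by 1). Columns with no
#' finite fitting value are dropped with a warning.
#'
#' @param table numeric matrix or data frame of features
#' @param fit_rows integer/logical index of the rows statistics are learned
#'   from
#' @return list with `state` and `transformed` (all rows transformed with
#'   the fit-row statistics)
#' @export
impute_and_scale <- function(table, fit_rows) {
  X <- as.matrix(table)
  stopifnot(length(fit_rows) > 0)
  Xf <- X[fit_rows, , drop = FALSE]
  p <- ncol(X)
  cap_hi <- cap_lo <- fill <- centre <- scale_ <- numeric(p)
  keep <- logical(p)
  for (j in seq_len(p)) {
    v <- Xf[, j]
    fin <- v[is.finite(v)]
    if (length(fin) == 0L) next
    keep[j] <- TRUE
    cap_hi[j] <- 1.5 * max(fin)
    cap_lo[j] <- 1.5 * min(fin)
    v[v == Inf] <- cap_hi[j]
    v[v == -Inf] <- cap_lo[j]
    fill[j] <- mean(v, na.rm = TRUE)
    v[is.na(v)] <- fill[j]
    centre[j] <- mean(v)
    s <- stats::sd(v)
    scale_[j] <- if (is.na(s) || s == 0) 1 else s
  }
  if (any(!keep))
    cipn_warning(sprintf("%d all-non-finite column(s) dropped", sum(!keep)),
                 "cipnsense_dropped_column_warning")
  cols <- colnames(X)[keep]
  nm <- function(v) stats::setNames(v[keep], cols)
  state <- list(columns = cols, cap_hi = nm(cap_hi), cap_lo = nm(cap_lo),
                fill = nm(fill), centre = nm(centre), scale = nm(scale_))
  list(state = state, transformed = apply_preprocess(state, X))
}

#' Apply a learned preprocessing state to new rows
#' @param state preprocessing state from [impute_and_scale()]
#' @param table matrix/data frame containing at least the state's columns
#' @return transformed numeric matrix with the state's columns
#' @export
apply_preprocess <- function(state, table) {
  X <- as.matrix(as.data.frame(table)[, state$columns, drop = FALSE])
  for (j in seq_along(state$columns)) {
    v <- X[, j]
    v[v == Inf] <- state$cap_hi[j]
    v[v == -Inf] <- state$cap_lo[j]
    v[is.na(v)] <- state$fill[j]
    X[, j] <- (v - state$centre[j]) / state$scale[j]
  }
  X
}

#' Cross-validation shape from the training-set size
#'
#' Both the number of folds and the number of repeats equal the rounded
#' square root of the sample size, clipped to \[2, n\].
#'
#' @param n_train training sample count (>= 4)
#' @return named integer vector `c(folds =, repeats =)`
#' @export
cv_shape <- function(n_train) {
  stopifnot(n_train >= 4)
  k <- as.integer(min(max(round(sqrt(n_train)), 2L), n_train))
  c(folds = k, repeats = k)
}

# Stratified patient-level index split; returns patient ids of the training
# portion.
split_patients <- function(patients, labels, fraction = 0.7) {
  train <- character(0)
  for (cl in sort(unique(labels))) {
    ids <- sort(patients[labels == cl])
    n_tr <- round(fraction * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  train
}

# Repeated stratified patient-level CV fold assignment: list (repeats) of
# integer fold ids per row.
cv_folds <- function(patient_ids, labels_by_row, folds, repeats) {
  pats <- unique(patient_ids)
  pat_lab <- labels_by_row[match(pats, patient_ids)]
  lapply(seq_len(repeats), function(r) {
    fold_of <- stats::setNames(integer(length(pats)), pats)
    for (cl in unique(pat_lab)) {
      ids <- sample(pats[pat_lab == cl])
      fold_of[ids] <- rep_len(sample(folds), length(ids))
    }
    unname(fold_of[patient_ids])
  })
}

# glmnet emits an informational warning for folds with < 8 observations per
# class; routine at the fold sizes the sqrt(n) rule produces on small
# cohorts, so muffled here.
quiet_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Mean cross-validated AUC for one alpha over a lambda sequence.
cv_auc_path <- function(X, y, patient_ids, alpha, lambdas, fold_list) {
  auc_sum <- numeric(length(lambdas))
  n_eval <- 0L
  for (fold_ids in fold_list) {
    preds <- matrix(NA_real_, length(y), length(lambdas))
    for (f in unique(fold_ids)) {
      hold <- fold_ids == f
      if (length(unique(y[!hold])) < 2L || min(table(y[!hold])) < 2L) next
      fit <- quiet_glmnet(X[!hold, , drop = FALSE], y[!hold],
                            family = "binomial", alpha = alpha,
                            lambda = lambdas, standardize = FALSE)
      pr <- stats::predict(fit, X[hold, , drop = FALSE], s = lambdas,
                           type = "response")
      preds[hold, seq_len(ncol(pr))] <- pr
    }
    aucs <- apply(preds, 2, function(pp) {
      ok <- !is.na(pp)
      if (length(unique(y[ok])) < 2L) return(NA_real_)
      auc_rank(pp[ok], y[ok])
    })
    ok <- !is.na(aucs)
    auc_sum[ok] <- auc_sum[ok] + aucs[ok]
    n_eval <- n_eval + 1L
  }
  auc_sum / max(n_eval, 1L)
}

#' Train an elastic-net CIPN classifier
#'
#' Stratified patient-level 70/30 split; preprocessing learned on the
#' training rows only; hyperparameters chosen to maximize repeated
#' cross-validated AUC (folds = repeats = round(sqrt(n_train))) over a
#' two-stage grid: a coarse stage pairing 10 mixing values with the
#' glmnet-generated penalty sequence, then a refinement of the penalty
#' within the winning order of magnitude. The final model is refit on all
#' training rows at the selected hyperparameters.
#'
#' @param table model table (from [build_model_table()]) or plain feature
#'   data frame with a `patient_id` column
#' @param outcome named logical vector of diagnoses (names = patient ids)
#' @param feature_ids character vector of feature columns to use
#' @param seed integer seed controlling split and folds
#' @param split_fraction training fraction (default 0.7)
#' @param alpha_grid elastic-net mixing values
#' @param n_lambda coarse penalty-sequence length
#' @param train_patients optional fixed set of training patient ids; when
#'   given the stratified split is skipped (used to share one partition
#'   across models)
#' @return object of class `cipn_model`
#' @export
train_cipn_model <- function(table, outcome, feature_ids, seed = 1L,
                             split_fraction = 0.7,
                             alpha_grid = seq(0.1, 1, length.out = 10),
                             n_lambda = 100L, train_patients = NULL) {
  stopifnot(length(feature_ids) >= 1L)
  set.seed(seed)
  pats <- unique(table$patient_id)
  pat_lab <- as.logical(outcome[pats])
  if (length(unique(pat_lab)) < 2L)
    cipn_error("outcome has a single class", "cipnsense_degenerate_outcome_error")

  train_pats <- if (is.null(train_patients))
    split_patients(pats, pat_lab, split_fraction) else train_patients
  if (length(unique(as.logical(outcome[train_pats]))) < 2L)
    cipn_error("training split has a single class",
               "cipnsense_degenerate_outcome_error")
  tr <- table$patient_id %in% train_pats
  y <- as.numeric(outcome[table$patient_id])

  prep <- withCallingHandlers(
    impute_and_scale(table[, feature_ids, drop = FALSE], which(tr)),
    cipnsense_dropped_column_warning = function(w) invokeRestart("muffleWarning"))
  X <- prep$transformed
  if (ncol(X) == 1L)  # glmnet requires >= 2 columns; pad with a null feature
    X <- cbind(X, .null_pad = 0)
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  pid_tr <- table$patient_id[tr]

  shape <- cv_shape(sum(tr))
  fold_list <- cv_folds(pid_tr, ytr, shape["folds"], shape["repeats"])

  lam0 <- quiet_glmnet(Xtr, ytr, family = "binomial", alpha = 0.5,
                       nlambda = n_lambda, standardize = FALSE)$lambda
  best <- list(auc = -Inf, alpha = NA, lambda = NA)
  trace <- list()
  for (a in alpha_grid) {
    aucs <- cv_auc_path(Xtr, ytr, pid_tr, a, lam0, fold_list)
    i <- which.max(aucs)
    trace[[length(trace) + 1L]] <-
      data.frame(stage = 1L, alpha = a, lambda = lam0[i], auc = aucs[i])
    if (aucs[i] > best$auc)
      best <- list(auc = aucs[i], alpha = a, lambda = lam0[i])
  }
  # refinement at the winning order of magnitude
  lam1 <- 10^seq(log10(best$lambda) - 0.5, log10(best$lambda) + 0.5,
                 length.out = 20)
  lam1 <- sort(lam1, decreasing = TRUE)
  aucs <- cv_auc_path(Xtr, ytr, pid_tr, best$alpha, lam1, fold_list)
  i <- which.max(aucs)
  trace[[length(trace) + 1L]] <-
    data.frame(stage = 2L, alpha = best$alpha, lambda = lam1[i], auc = aucs[i])
  if (aucs[i] >= best$auc)
    best <- list(auc = aucs[i], alpha = best$alpha, lambda = lam1[i])

  fit <- quiet_glmnet(Xtr, ytr, family = "binomial", alpha = best$alpha,
                      lambda = sort(unique(c(lam0, best$lambda)),
                                    decreasing = TRUE),
                      standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = best$lambda))
  coefs <- stats::setNames(cf[-1, 1], rownames(cf)[-1])
  coefs <- coefs[names(coefs) != ".null_pad"]
  structure(list(intercept = cf[1, 1],
                 coefficients = coefs,
                 alpha = best$alpha, lambda = best$lambda,
                 cv_auc = best$auc, cv_trace = do.call(rbind, trace),
                 preprocess = prep$state,
                 train_patients = sort(train_pats),
                 test_patients = sort(setdiff(pats, train_pats)),
                 feature_ids = prep$state$columns, seed = seed),
            class = "cipn_model")
}

#' @export
print.cipn_model <- function(x, ...) {
  cat(sprintf("<cipn_model: %d features (%d nonzero), alpha=%.2f, lambda=%.4g, cv AUC=%.3f>\n",
              length(x$coefficients), sum(x$coefficients != 0), x$alpha,
              x$lambda, x$cv_auc))
  invisible(x)
}

#' Predict CIPN probabilities
#' @param object a `cipn_model`
#' @param table feature table rows to predict
#' @param ... unused
#' @return numeric vector of probabilities
#' @export
predict.cipn_model <- function(object, table, ...) {
  X <- apply_preprocess(object$preprocess, table[, , drop = FALSE])
  eta <- object$intercept + as.numeric(X %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' Evaluate a fitted model on held-out rows
#'
#' Multiple rows per patient (e.g. the two walking legs) are first averaged
#' into one predicted probability per patient. AUC is the rank statistic
#' over these per-patient probabilities; accuracy uses a 0.5 threshold; the
#' no-information rate (NIR) is the majority-class fraction; the
#' accuracy-vs-NIR p-value is a one-sided exact binomial test with success
#' probability NIR.
#'
#' @param model a `cipn_model`
#' @param table rows to evaluate (with `patient_id`)
#' @param outcome named logical diagnosis vector
#' @return object of class `cipn_evaluation`
#' @export
evaluate_cipn_model <- function(model, table, outcome) {
  probs <- predict(model, table)
  pat_prob <- tapply(probs, table$patient_id, mean)
  pats <- names(pat_prob)
  y <- as.logical(outcome[pats])
  single_class <- length(unique(y)) < 2L
  auc <- if (single_class) NA_real_ else auc_rank(as.numeric(pat_prob), y)
  pred <- as.numeric(pat_prob) >= 0.5
  acc <- mean(pred == y)
  nir <- max(mean(y), 1 - mean(y))
  k <- sum(pred == y)
  p_nir <- stats::binom.test(k, length(y), p = nir,
                             alternative = "greater")$p.value
  sens <- if (any(y)) mean(pred[y]) else NA_real_
  spec <- if (any(!y)) mean(!pred[!y]) else NA_real_
  ord <- order(-as.numeric(pat_prob))
  roc <- data.frame(
    threshold = c(Inf, as.numeric(pat_prob)[ord]),
    tpr = c(0, cumsum(y[ord]) / max(sum(y), 1L)),
    fpr = c(0, cumsum(!y[ord]) / max(sum(!y), 1L)))
  structure(list(auc = auc, accuracy = acc, sensitivity = sens,
                 specificity = spec, nir = nir, p_vs_nir = p_nir,
                 roc = roc, auc_undefined = single_class,
                 probabilities = stats::setNames(as.numeric(pat_prob), pats),
                 labels = stats::setNames(y, pats)),
            class = "cipn_evaluation")
}

#' @export
print.cipn_evaluation <- function(x, ...) {
  cat(sprintf("<cipn_evaluation: AUC=%.3f, accuracy=%.2f vs NIR=%.2f (p=%.3g)>\n",
              x$auc, x$accuracy, x$nir, x$p_vs_nir))
  invisible(x)
}

#' Variable importance of a fitted model
#'
#' Importance is the absolute standardized regression coefficient,
#' normalized to percentages summing to 100 over the nonzero coefficients.
#' With a registry, importances are also aggregated by assessment (and
#' phase for the Romberg stance).
#'
#' @param model a `cipn_model`
#' @param registry optional feature registry for aggregation
#' @return list with `per_feature` (named percentages) and, when a registry
#'   is given, `by_assessment`
#' @export
variable_importance <- function(model, registry = NULL) {
  co <- abs(model$coefficients)
  if (sum(co) == 0) {
    cipn_warning("all coefficients are zero; importance undefined",
                 "cipnsense_zero_importance_warning")
    return(list(per_feature = stats::setNames(rep(NA_real_, length(co)),
                                              names(co))))
  }
  pct <- 100 * co / sum(co)
  out <- list(per_feature = sort(pct[pct > 0], decreasing = TRUE))
  if (!is.null(registry)) {
    grp <- registry$assessment[match(names(pct), registry$feature_id)]
    grp[is.na(grp)] <- "other"
    ph <- registry$phase[match(names(pct), registry$feature_id)]
    grp <- ifelse(grp == "romberg_stance" & !is.na(ph),
                  paste0("romberg_stance.", ph), grp)
    agg <- c(tapply(pct, grp, sum))  # drop the 1-d array shape
    out$by_assessment <- sort(agg, decreasing = TRUE)
  }
  out
}
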