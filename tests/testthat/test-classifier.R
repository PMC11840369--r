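# Elastic-net classifier: preprocessing semantics, leakage control, CV
# shape, training determinism, evaluation against the no-information rate,
# and variable importance arithmetic.

test_that("infinite values are imputed at 1.5x the finite extremum", {
  X <- cbind(a = c(1, 2, Inf), b = c(-Inf, 1, 3), const = c(5, 5, 5))
  pr <- impute_and_scale(X, fit_rows = 1:3)
  expect_equal(pr$state$cap_hi[["a"]], 3)        # 1.5 * finite max 2
  expect_equal(pr$state$cap_lo[["b"]], 1.5)  # 1.5 * finite min 1
  # imputed-then-scaled column a: (1, 2, 3) centred and scaled
  expect_equal(unname(pr$transformed[, "a"]), scale(c(1, 2, 3))[, 1])
  # constant column: scaled by 1, centred to 0
  expect_equal(unname(pr$transformed[, "const"]), c(0, 0, 0))
  expect_equal(pr$state$scale[["const"]], 1)
})

test_that("an all-non-finite column is dropped with a warning", {
  X <- cbind(a = c(1, 2, 3), bad = c(Inf, Inf, Inf))
  expect_warning(pr <- impute_and_scale(X, 1:3),
                 class = "cipnsense_dropped_column_warning")
  expect_identical(pr$state$columns, "a")
})

test_that("held-out rows are transformed with fit-row statistics only", {
  set.seed(201)
  X <- matrix(rnorm(40, mean = 5), 20, 2, dimnames = list(NULL, c("a", "b")))
  X[16:20, ] <- X[16:20, ] + 50          # shifted held-out block
  fit_only <- impute_and_scale(X, 1:15)
  joint <- impute_and_scale(X, 1:20)
  # no leakage: transforming train+test jointly is detectably different
  expect_gt(max(abs(fit_only$transformed[16:20, ] -
                      joint$transformed[16:20, ])), 0.5)
  expect_equal(apply_preprocess(fit_only$state, X[16:20, , drop = FALSE]),
               fit_only$transformed[16:20, ])
})

test_that("cross-validation shape follows the square-root rule", {
  expect_identical(cv_shape(49), c(folds = 7L, repeats = 7L))
  expect_identical(cv_shape(31), c(folds = 6L, repeats = 6L))
  expect_identical(cv_shape(4), c(folds = 2L, repeats = 2L))
})

# deterministic separable training fixture: two rows (legs) per patient
separable_fixture <- function(n_pat = 20, shift = 3, seed = 601) {
  set.seed(seed)
  pats <- sprintf("P%02d", 1:n_pat)
  y <- stats::setNames(rep(c(TRUE, FALSE), n_pat / 2), pats)
  tab <- data.frame(patient_id = rep(pats, each = 2),
                    treatment_day = 60L,
                    leg = rep(c("forth", "back"), n_pat))
  tab$f1 <- rnorm(nrow(tab)) + shift * y[tab$patient_id]
  tab$f2 <- rnorm(nrow(tab))
  tab$f3 <- rnorm(nrow(tab))
  list(tab = tab, y = y)
}

test_that("training recovers a separable signal deterministically", {
  fx <- separable_fixture()
  m1 <- train_cipn_model(fx$tab, fx$y, c("f1", "f2", "f3"), seed = 5)
  m2 <- train_cipn_model(fx$tab, fx$y, c("f1", "f2", "f3"), seed = 5)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$lambda, m2$lambda)
  # training rows are separable: training AUC 1
  tr <- fx$tab[fx$tab$patient_id %in% m1$train_patients, ]
  ev_tr <- evaluate_cipn_model(m1, tr, fx$y)
  expect_equal(ev_tr$auc, 1)
  # the signal feature carries the model
  expect_gt(abs(m1$coefficients["f1"]), max(abs(m1$coefficients[c("f2", "f3")])))
  # patient-level split: both legs of a patient stay on one side
  expect_length(intersect(m1$train_patients, m1$test_patients), 0)
})

test_that("flipping held-out labels cannot change the fitted model", {
  fx <- separable_fixture()
  m <- train_cipn_model(fx$tab, fx$y, c("f1", "f2", "f3"), seed = 5)
  y_flip <- fx$y
  y_flip[m$test_patients] <- !y_flip[m$test_patients]
  # refit on the same fixed partition with original and with shuffled
  # held-out labels: the fitted models must coincide
  m_ref <- train_cipn_model(fx$tab, fx$y, c("f1", "f2", "f3"), seed = 5,
                            train_patients = m$train_patients)
  m_flip <- train_cipn_model(fx$tab, y_flip, c("f1", "f2", "f3"), seed = 5,
                             train_patients = m$train_patients)
  expect_identical(m_ref$train_patients, m_flip$train_patients)
  expect_identical(m_ref$coefficients, m_flip$coefficients)
})

test_that("predictions are invariant to affine rescaling of a feature", {
  fx <- separable_fixture()
  m <- train_cipn_model(fx$tab, fx$y, c("f1", "f2", "f3"), seed = 7)
  tab2 <- fx$tab
  tab2$f1 <- 10 * tab2$f1 + 5
  m2 <- train_cipn_model(tab2, fx$y, c("f1", "f2", "f3"), seed = 7)
  expect_equal(predict(m2, tab2), predict(m, fx$tab), tolerance = 1e-8)
})

test_that("evaluation reports NIR, accuracy and the exact binomial test", {
  # 45 patients, 24 positive: NIR prints as 53%
  m <- make_linear_model("f1", weight = 4)
  pats <- sprintf("P%02d", 1:45)
  y45 <- stats::setNames(rep(c(TRUE, FALSE), c(24, 21)), pats)
  tab <- data.frame(patient_id = pats, f1 = ifelse(y45, 1, -1))
  ev <- evaluate_cipn_model(m, tab, y45)
  expect_equal(ev$nir, 24 / 45)
  expect_identical(round(100 * ev$nir), 53)
  expect_equal(ev$auc, 1)
  # 45 patients, 29 positive: NIR prints as 64%
  y29 <- stats::setNames(rep(c(TRUE, FALSE), c(29, 16)), pats)
  ev29 <- evaluate_cipn_model(m, data.frame(patient_id = pats,
                                            f1 = ifelse(y29, 1, -1)), y29)
  expect_identical(round(100 * ev29$nir), 64)
  # perfect predictions on n patients at NIR 0.5: p = 0.5^n
  pats14 <- sprintf("Q%02d", 1:14)
  y14 <- stats::setNames(rep(c(TRUE, FALSE), 7), pats14)
  ev14 <- evaluate_cipn_model(m, data.frame(patient_id = pats14,
                                            f1 = ifelse(y14, 1, -1)), y14)
  expect_equal(ev14$p_vs_nir, 0.5^14)
  # multiple rows per patient are averaged before scoring
  tab2 <- data.frame(patient_id = rep(pats14, each = 2),
                     f1 = as.vector(rbind(ifelse(y14, 3, -3),
                                          ifelse(y14, -1, 1))))
  ev2 <- evaluate_cipn_model(m, tab2, y14)
  expect_equal(ev2$auc, 1)  # means still separate
})

test_that("a single-class test set flags AUC undefined", {
  m <- make_linear_model()
  tab <- data.frame(patient_id = c("A", "B"), f1 = c(1, 2))
  y <- stats::setNames(c(TRUE, TRUE), c("A", "B"))
  ev <- evaluate_cipn_model(m, tab, y)
  expect_true(ev$auc_undefined)
  expect_true(is.na(ev$auc))
})

test_that("variable importance normalizes absolute coefficients", {
  m <- make_linear_model()
  m$coefficients <- c(a = 2, b = -1, c = 1, d = 0)
  vi <- variable_importance(m)
  expect_equal(unname(vi$per_feature[c("a", "b", "c")]), c(50, 25, 25))
  expect_false("d" %in% names(vi$per_feature))
  m$coefficients <- c(a = 0.7, b = 0)
  expect_equal(unname(variable_importance(m)$per_feature["a"]), 100)
  # assessment aggregation sums member percentages
  reg <- data.frame(feature_id = c("a", "b", "c", "d"),
                    assessment = c("t1", "t1", "t2", "t2"),
                    phase = NA_character_)
  m$coefficients <- c(a = 2, b = -1, c = 1, d = 0)
  vi <- variable_importance(m, reg)
  expect_equal(unname(vi$by_assessment[c("t1", "t2")]), c(75, 25))
  m$coefficients <- c(a = 0, b = 0)
  expect_warning(variable_importance(m),
                 class = "cipnsense_zero_importance_warning")
})
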