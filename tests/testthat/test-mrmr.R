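# Ensemble mRMR: oracle equivalence against brute-force greedy chains,
# vote semantics, anti-redundancy, and the three-step protocol.

test_that("greedy chains equal brute-force enumeration on discrete data", {
  set.seed(101)
  for (rep in 1:12) {
    p <- sample(3:8, 1)
    n <- sample(15:30, 1)
    X <- matrix(sample(1:4, n * p, replace = TRUE), n, p,
                dimnames = list(NULL, sprintf("f%02d", 1:p)))
    y <- runif(n) < 0.5
    if (length(unique(y)) < 2) y[1] <- !y[1]
    n_sets <- sample(1:3, 1)
    sets <- mrmr_select(X, y, n_sets = n_sets, n_bins = 4)
    for (k in seq_len(n_sets)) {
      expect_identical(sets[[k]]$features,
                       oracle_mrmr_chain(X, y, seed_rank = k))
    }
  }
})

test_that("the first selected feature maximizes relevance", {
  set.seed(102)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(strong = rnorm(n) + 3 * y,
             weak = rnorm(n) + 0.3 * y,
             noise = rnorm(n))
  sets <- mrmr_select(X, y, n_sets = 1)
  expect_identical(sets[[1]]$features[1], "strong")
  expect_true(all(sets[[1]]$scores > 0))
})

test_that("a duplicated feature is never selected after its twin", {
  set.seed(103)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  base <- rnorm(n) + 2 * y
  X <- cbind(a_sig = base, b_twin = base, c_other = rnorm(n) + y)
  sets <- mrmr_select(X, y, n_sets = 3)
  for (s in sets)
    expect_lte(sum(c("a_sig", "b_twin") %in% s$features), 1)
})

test_that("column order only permutes tie-broken output", {
  set.seed(104)
  n <- 50
  y <- runif(n) < 0.5
  if (length(unique(y)) < 2) y[1] <- !y[1]
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  X[, "a"] <- X[, "a"] + 2 * y
  sets1 <- mrmr_select(X, y, n_sets = 2)
  sets2 <- mrmr_select(X[, c(4, 2, 5, 1, 3)], y, n_sets = 2)
  for (k in 1:2)
    expect_identical(sets1[[k]]$features, sets2[[k]]$features)
})

test_that("majority voting requires strictly more than half", {
  mk <- function(feats) list(features = feats, scores = rep(1, length(feats)))
  five <- list(mk(c("x", "y")), mk("x"), mk(c("x", "z")), mk("y"), mk("z"))
  v <- vote(five)                      # x in 3/5 kept; y, z in 2/5 dropped
  expect_identical(as.character(v), "x")
  fifteen <- c(lapply(1:8, function(i) mk("w")),
               lapply(1:7, function(i) mk("v")))
  expect_identical(as.character(vote(fifteen)), "w")  # 8/15 retained
  expect_length(vote(list(mk("a"), mk("b"))), 0)      # 1/2 is a tie: dropped
})

test_that("a constant outcome raises a degenerate-outcome error", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(mrmr_select(X, rep(TRUE, 20)),
               class = "cipnsense_degenerate_outcome_error")
})

test_that("the requested ensemble sizes are honoured", {
  set.seed(105)
  X <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- rep(c(TRUE, FALSE), 15)
  expect_length(mrmr_select(X, y, n_sets = 5), 5)
  expect_length(mrmr_select(X, y, n_sets = 15), 15)
})

# small two-assessment setting for the three-step protocol
three_step_fixture <- function(seed, n = 60, informative = TRUE) {
  set.seed(seed)
  pats <- sprintf("P%02d", 1:n)
  y <- stats::setNames(rep(c(TRUE, FALSE), n / 2), pats)
  reg <- data.frame(
    feature_id = c(sprintf("taskA.f%02d", 1:6), sprintf("taskB.f%02d", 1:6)),
    assessment = rep(c("taskA", "taskB"), each = 6))
  mk_tab <- function(signal) {
    m <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, reg$feature_id))
    if (signal && informative) m[, "taskA.f01"] <- m[, "taskA.f01"] + 2.5 * y
    data.frame(patient_id = pats, treatment_day = if (signal) 60L else -7L,
               leg = "forth", m, check.names = FALSE)
  }
  list(baseline = mk_tab(FALSE), eot = mk_tab(TRUE), y = y, reg = reg)
}

test_that("an informative feature survives all three steps", {
  hits <- vapply(1:10, function(s) {
    fx <- three_step_fixture(s)
    sel <- suppressWarnings(
      select_three_step(fx$baseline, fx$eot, fx$y, fx$reg))
    "taskA.f01" %in% sel$selected
  }, NA)
  expect_gte(sum(hits), 9)
})

test_that("an end-of-treatment copy of a selected baseline feature is
           eliminated at step 2", {
  set.seed(301)
  n <- 60
  pats <- sprintf("P%02d", 1:n)
  y <- stats::setNames(rep(c(TRUE, FALSE), n / 2), pats)
  reg <- data.frame(feature_id = sprintf("taskA.f%02d", 1:5),
                    assessment = "taskA")
  base_val <- rnorm(n) + 2 * y  # baseline feature carrying the signal
  base <- data.frame(patient_id = pats, treatment_day = -7L, leg = "forth",
                     matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, reg$feature_id)),
                     check.names = FALSE)
  base[, "taskA.f01"] <- base_val
  eot <- base
  eot$treatment_day <- 60L
  eot[, reg$feature_id] <- matrix(rnorm(n * 5), n, 5)
  eot[, "taskA.f01"] <- base_val  # identical to the baseline survivor
  sel <- suppressWarnings(select_three_step(base, eot, y, reg))
  expect_true("taskA.f01" %in% sel$step1$taskA)
  expect_false("taskA.f01" %in% sel$step2$taskA)
})

test_that("pure-noise tables produce an empty-selection warning or a small
           noise set, never an error", {
  fx <- three_step_fixture(7, informative = FALSE)
  expect_no_error(suppressWarnings(
    sel <- select_three_step(fx$baseline, fx$eot, fx$y, fx$reg)))
})
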