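# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately avoid the package's code paths.

# --- brute-force greedy mRMR (entropy-based MI, direct scans) --------------

oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

oracle_mi <- function(a, b) {
  oracle_entropy(a) + oracle_entropy(b) - oracle_entropy(paste(a, b))
}

# Greedy mRMR chain on already-discrete columns, seeded with the seed_rank-th
# most relevant feature; lexicographic tie-break; stops at score <= 0.
oracle_mrmr_chain <- function(X, y, seed_rank = 1L) {
  ids <- colnames(X)
  rel <- vapply(ids, function(j) oracle_mi(X[, j], y), 0)
  ord <- ids[order(-rel, ids)]
  seed <- ord[seed_rank]
  if (rel[seed] <= 0) return(character(0))
  chain <- seed
  repeat {
    cand <- setdiff(ids, chain)
    if (!length(cand)) break
    scores <- vapply(cand, function(j) {
      red <- mean(vapply(chain, function(s) oracle_mi(X[, j], X[, s]), 0))
      rel[j] - red
    }, 0)
    best <- cand[order(-scores, cand)][1]
    if (scores[best] <= 0) break
    chain <- c(chain, best)
  }
  chain
}

# --- Fisher exact oracle: full hypergeometric enumeration ------------------

oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Benjamini-Hochberg step-up by the definition --------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- fixture builders ------------------------------------------------------

# Minimal sensor stream with identity attitude.
make_stream <- function(t, acc, rot = NULL, phase = NULL, kind = "test") {
  n <- length(t)
  if (is.null(rot)) rot <- matrix(0, n, 3)
  sensor_stream(t, acc, rot, matrix(rep(c(1, 0, 0, 0), each = n), n, 4),
                phase = phase, kind = kind)
}

# Still/walk/still stream: sinusoidal activity between pads, gravity on z.
make_padded_walk <- function(pad = 2, active = 10, fs = 50, amp = 1) {
  t <- seq(0, 2 * pad + active, by = 1 / fs)
  on <- as.numeric(t >= pad & t <= pad + active)
  acc <- cbind(0.3 * on * sin(2 * pi * 0.9 * t),
               amp * on * sin(2 * pi * 1.8 * t),
               1.2 * on * sin(2 * pi * 1.8 * t) - 9.80665)
  make_stream(t, acc, kind = "natural_walk")
}

# A hand-built tap session from explicit timestamps.
make_tap_session <- function(times, hand = "dominant",
                             buttons = rep(c("left", "right"),
                                           length.out = length(times))) {
  centers <- rbind(left = c(100, 400), right = c(220, 400))
  structure(list(timestamps = times, button = buttons, intended = buttons,
                 x = centers[buttons, 1], y = centers[buttons, 2],
                 hand = hand, button_centers = centers),
            class = "tap_session")
}

# A deterministic linear "model" usable with predict/evaluate: probability
# plogis(weight * feature).
make_linear_model <- function(feature = "f1", weight = 4) {
  structure(list(intercept = 0,
                 coefficients = stats::setNames(weight, feature),
                 alpha = 1, lambda = 0, cv_auc = NA_real_,
                 preprocess = list(columns = feature, cap_hi = Inf,
                                   cap_lo = -Inf, fill = 0, centre = 0,
                                   scale = 1),
                 train_patients = character(0), test_patients = character(0),
                 feature_ids = feature, seed = 1L),
            class = "cipn_model")
}

# Small cohort used by several structural tests (cached per session).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_patients = 5, n_cycles = 1,
                                           sampling_rate = 50, seed = 404))
    cache
  }
})
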