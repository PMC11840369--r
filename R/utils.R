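# Shared internal helpers.

GRAVITY <- 9.80665  # m/s^2

cipn_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cipnsense_error")))
}

cipn_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cipnsense_warning")))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the probability that a randomly chosen positive scores above a randomly
#' chosen negative (ties counted half).
#'
#' @param scores numeric predicted scores/probabilities
#' @param labels logical or 0/1 outcome (TRUE/1 = positive)
#' @return AUC in \[0, 1\], or `NA` if only one class is present
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic derived seed for a named pipeline stage; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

# Moving average with zero padding at the ends (used for activity RMS and
# yaw-rate smoothing).
moving_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  k <- rep(1 / width, width)
  as.numeric(stats::filter(c(rep(0, width), x, rep(0, width)),
                           k, sides = 2))[(width + 1):(width + length(x))]
}
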