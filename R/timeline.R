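# Longitudinal earliest-detection analysis: daily 2x2 contingency tables of
# model classification (most recent assessment at or before each day,
# last-observation-carried-forward) versus end-of-treatment diagnosis,
# Fisher exact tests with Benjamini-Hochberg correction, and the earliest
# sustained-significance day.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value obtained by summing hypergeometric probabilities no larger
#' than that of the observed table (the standard two-sided convention).
#' Tables with a zero margin carry no information; they return p = 1 with a
#' `degenerate` attribute.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#' @return p-value in (0, 1\]
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(structure(1, degenerate = TRUE))
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min over j >= i of (m / j) p_(j)`,
#' order-preserving and capped at 1.
#'
#' @param pvalues numeric p-values in \[0, 1\]
#' @return q-values, same order as the input
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a detection timeline
#'
#' `classifications` holds one row per patient assessment with the model's
#' predicted status. Every day on which at least one patient's carried-
#' forward classification could change (i.e. every distinct assessment day)
#' is evaluated: patients are classified by their most recent assessment at
#' or before the day, cross-tabulated against the end-of-treatment
#' diagnosis, and tested with [fisher_exact()]; q-values are BH-adjusted
#' across all evaluated days.
#'
#' @param classifications data frame with columns patient_id, day,
#'   predicted (logical)
#' @param outcome named logical diagnosis vector
#' @param alpha significance level for the sustained-significance day
#' @param min_run minimum run length of significant days required
#'   (default `Inf`: significance must be sustained through end of
#'   follow-up)
#' @return object of class `detection_timeline`: per-day data frame (day,
#'   counts, p, q, significant) and `earliest_day`
#' @export
detection_timeline <- function(classifications, outcome, alpha = 0.05,
                               min_run = Inf) {
  stopifnot(all(c("patient_id", "day", "predicted") %in%
                  names(classifications)))
  days <- sort(unique(classifications$day))
  rows <- lapply(days, function(d) {
    sub <- classifications[classifications$day <= d, , drop = FALSE]
    sub <- sub[order(sub$patient_id, sub$day), ]
    last <- !duplicated(sub$patient_id, fromLast = TRUE)
    cls <- sub$predicted[last]
    pids <- sub$patient_id[last]
    y <- as.logical(outcome[pids])
    tab <- table(factor(cls, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    p <- fisher_exact(tab)
    data.frame(day = d, n = length(pids),
               pred_pos_dx_pos = tab["TRUE", "TRUE"],
               pred_pos_dx_neg = tab["TRUE", "FALSE"],
               pred_neg_dx_pos = tab["FALSE", "TRUE"],
               pred_neg_dx_neg = tab["FALSE", "FALSE"],
               p = as.numeric(p),
               degenerate = isTRUE(attr(p, "degenerate")))
  })
  tl <- do.call(rbind, rows)
  tl$q <- bh_adjust(tl$p)
  tl$significant <- tl$q < alpha
  out <- structure(list(timeline = tl, alpha = alpha),
                   class = "detection_timeline")
  out$earliest_day <- earliest_detection_day(out, alpha = alpha,
                                             min_run = min_run)
  out
}

#' Earliest sustained-significance day
#'
#' Returns the first evaluated day whose BH-adjusted q-value is below
#' `alpha` and stays below `alpha` on every subsequent evaluated day for at
#' least `min_run` evaluated days (default: through the end of follow-up);
#' `NA` if significance is never sustained.
#'
#' @param timeline a `detection_timeline` (or its `timeline` data frame)
#' @param alpha significance level
#' @param min_run minimum number of consecutive significant evaluated days
#' @return integer day or `NA`
#' @export
earliest_detection_day <- function(timeline, alpha = 0.05, min_run = Inf) {
  tl <- if (inherits(timeline, "detection_timeline")) timeline$timeline
        else timeline
  sig <- tl$q < alpha
  n <- length(sig)
  if (n == 0L) return(NA_integer_)
  # run_len[i] = number of consecutive significant evaluated days starting
  # at i (0 when day i itself is not significant)
  run_len <- integer(n)
  count <- 0L
  for (i in n:1) {
    count <- if (sig[i]) count + 1L else 0L
    run_len[i] <- count
  }
  for (i in seq_len(n)) {
    need <- if (is.infinite(min_run)) n - i + 1L else min(min_run, n - i + 1L)
    if (run_len[i] >= need) return(tl$day[i])
  }
  NA_integer_
}

#' @export
print.detection_timeline <- function(x, ...) {
  cat(sprintf("<detection_timeline: %d days, earliest sustained day: %s>\n",
              nrow(x$timeline),
              if (is.na(x$earliest_day)) "none" else x$earliest_day))
  invisible(x)
}
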