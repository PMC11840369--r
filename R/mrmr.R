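# Ensemble minimum-redundancy-maximum-relevance feature selection with
# positive-score stopping and a three-step majority-voting protocol
# (baseline within-assessment -> end-of-treatment vs baseline
# within-assessment -> cross-assessment pooling).

# Equal-frequency discretization into at most n_bins levels (integer codes).
# Constant columns collapse to a single level; NA/Inf are assigned their own
# level so the estimator never drops rows.
discretize_ef <- function(x, n_bins = 4L) {
  out <- rep(1L, length(x))
  ok <- is.finite(x)
  if (any(ok)) {
    u <- sort(unique(x[ok]))
    if (length(u) <= n_bins) {
      # already (near-)discrete: use the values as categories
      out[ok] <- match(x[ok], u)
    } else {
      qs <- unique(stats::quantile(x[ok],
                                   probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE, type = 7))
      if (length(qs) > 2L) {
        out[ok] <- findInterval(x[ok], qs[-c(1L, length(qs))]) + 1L
      } else {
        out[ok] <- 1L
      }
    }
  }
  if (any(!ok)) out[!ok] <- max(out[ok], 0L) + 1L
  out
}

# Mutual information (bits) between two integer-coded vectors.
mi_discrete <- function(a, b) {
  na <- max(a)
  nb <- max(b)
  n <- length(a)
  joint <- tabulate((a - 1L) * nb + b, na * nb) / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  pp <- joint[joint > 0]
  ee <- (pa[rep(seq_len(na), each = nb)] * pb[rep(seq_len(nb), na)])[joint > 0]
  sum(pp * log2(pp / ee))
}

#' Ensemble mRMR selection
#'
#' Greedy minimum-redundancy-maximum-relevance chains over discretized
#' features (equal-frequency bins, default 4). The score of a candidate is
#' its mutual information with the outcome minus its mean mutual information
#' with the already-selected features; selection stops when the best
#' available score drops to 0 or below. The ensemble consists of `n_sets`
#' chains, the k-th seeded with the k-th most relevant feature. Ties are
#' broken lexicographically by feature id.
#'
#' @param features numeric matrix (rows = samples) with column names
#' @param outcome binary outcome (logical or 0/1), both classes present
#' @param n_sets number of solution sets
#' @param n_bins equal-frequency bin count for discretization
#' @return list of solution sets, each a list with `features` (ordered ids),
#'   `scores` and `seed_rank`
#' @export
mrmr_select <- function(features, outcome, n_sets = 5L, n_bins = 4L) {
  outcome <- as.integer(as.logical(outcome)) + 1L
  if (length(unique(outcome)) < 2L)
    cipn_error("outcome has a single class", "cipnsense_degenerate_outcome_error")
  stopifnot(ncol(features) >= 2L)
  ids <- colnames(features)
  p <- ncol(features)
  xb <- apply(features, 2, discretize_ef, n_bins = n_bins)

  rel <- vapply(seq_len(p), function(j) mi_discrete(xb[, j], outcome), 0)
  names(rel) <- ids
  rel_order <- order(-rel, ids)

  red_cache <- matrix(NA_real_, p, p)
  red <- function(i, j) {
    v <- red_cache[i, j]
    if (is.na(v)) {
      v <- mi_discrete(xb[, i], xb[, j])
      red_cache[i, j] <<- v
      red_cache[j, i] <<- v
    }
    v
  }

  n_sets_eff <- min(n_sets, p)
  sets <- vector("list", n_sets_eff)
  for (k in seq_len(n_sets_eff)) {
    seed <- rel_order[k]
    if (rel[seed] <= 0) {
      sets[[k]] <- list(features = character(0), scores = numeric(0),
                        seed_rank = k)
      next
    }
    selected <- seed
    scores <- rel[seed]
    red_sum <- rep(0, p)  # running sum of redundancy against selected
    repeat {
      for (j in setdiff(seq_len(p), selected))
        red_sum[j] <- red_sum[j] + red(selected[length(selected)], j)
      cand <- setdiff(seq_len(p), selected)
      if (length(cand) == 0L) break
      sc <- rel[cand] - red_sum[cand] / length(selected)
      best <- cand[order(-sc, ids[cand])][1]
      best_sc <- rel[best] - red_sum[best] / length(selected)
      if (best_sc <= 0) break
      selected <- c(selected, best)
      scores <- c(scores, best_sc)
    }
    sets[[k]] <- list(features = ids[selected],
                      scores = unname(scores), seed_rank = k)
  }
  sets
}

#' Majority vote across solution sets
#'
#' A feature is retained iff it appears in strictly more than half of the
#' solution sets (ties at exactly half are dropped).
#'
#' @param sets list of solution sets from [mrmr_select()]
#' @return character vector of retained feature ids (vote counts as the
#'   `votes` attribute)
#' @export
vote <- function(sets) {
  stopifnot(length(sets) >= 1L)
  all_feats <- unlist(lapply(sets, `[[`, "features"))
  if (length(all_feats) == 0L)
    return(structure(character(0), votes = integer(0)))
  counts <- table(all_feats)
  kept <- sort(names(counts[counts > length(sets) / 2]))
  structure(kept, votes = counts)
}

#' Three-step majority-voting feature selection
#'
#' Step 1: per assessment, ensemble mRMR over the baseline features with
#' `n_sets_step1` solution sets, majority vote. Step 2: per assessment,
#' ensemble mRMR over the union of the end-of-treatment features and the
#' step-1 baseline survivors (joined per patient, `baseline.` prefix),
#' voting with `n_sets_step2` sets; only end-of-treatment features advance,
#' which removes features explained by the pre-treatment state. Step 3: the
#' pooled survivors of all assessments are filtered jointly with
#' `n_sets_step3` sets to remove cross-assessment redundancy.
#'
#' @param baseline,end_of_treatment model tables from [build_model_table()]
#'   for the baseline and end-of-treatment timepoints
#' @param outcome named logical vector of diagnoses, names = patient ids
#' @param registry feature registry (provides assessment tags)
#' @param n_sets_step1,n_sets_step2,n_sets_step3 solution-set counts
#' @param n_bins discretization bins
#' @return list with per-step results (`step1`, `step2` per assessment,
#'   `step3`) and `selected`, the final feature ids
#' @export
select_three_step <- function(baseline, end_of_treatment, outcome, registry,
                              n_sets_step1 = 5L, n_sets_step2 = 5L,
                              n_sets_step3 = 15L, n_bins = 4L) {
  assessments <- unique(registry$assessment)
  y_eot <- outcome[end_of_treatment$patient_id]
  y_base <- outcome[baseline$patient_id]

  # patient-level baseline means for the step-2 join
  base_mat <- as.matrix(baseline[, registry$feature_id, drop = FALSE])
  base_by_pat <- rowsum(base_mat, baseline$patient_id, na.rm = TRUE) /
    as.vector(table(baseline$patient_id)[sort(unique(baseline$patient_id))])

  usable <- function(mat) {
    ok <- apply(mat, 2, function(x) {
      x <- x[is.finite(x)]
      length(x) > 1 && stats::sd(x) > 0
    })
    mat[, ok, drop = FALSE]
  }

  step1 <- list()
  step2 <- list()
  for (a in assessments) {
    cols <- registry$feature_id[registry$assessment == a]
    bmat <- usable(as.matrix(baseline[, cols, drop = FALSE]))
    s1 <- if (ncol(bmat) >= 2L) {
      vote(mrmr_select(bmat, y_base, n_sets = n_sets_step1, n_bins = n_bins))
    } else structure(character(0), votes = integer(0))
    step1[[a]] <- s1

    emat <- usable(as.matrix(end_of_treatment[, cols, drop = FALSE]))
    if (length(s1) > 0L) {
      bjoin <- base_by_pat[match(end_of_treatment$patient_id,
                                 rownames(base_by_pat)), s1, drop = FALSE]
      colnames(bjoin) <- paste0("baseline.", s1)
      cand <- cbind(emat, bjoin)
    } else {
      cand <- emat
    }
    s2 <- if (ncol(cand) >= 2L) {
      vote(mrmr_select(cand, y_eot, n_sets = n_sets_step2, n_bins = n_bins))
    } else structure(character(0), votes = integer(0))
    step2[[a]] <- structure(s2[!startsWith(as.character(s2), "baseline.")],
                            votes = attr(s2, "votes"))
  }

  pooled <- unlist(step2, use.names = FALSE)
  if (length(pooled) == 0L) {
    cipn_warning("empty survivor set after step 2; selection skipped",
                 "cipnsense_empty_selection_warning")
    return(list(step1 = step1, step2 = step2, step3 = character(0),
                selected = character(0)))
  }
  pmat <- usable(as.matrix(end_of_treatment[, pooled, drop = FALSE]))
  step3 <- if (ncol(pmat) >= 2L) {
    vote(mrmr_select(pmat, y_eot, n_sets = n_sets_step3, n_bins = n_bins))
  } else structure(colnames(pmat), votes = NULL)
  if (length(step3) == 0L)
    cipn_warning("empty survivor set after step 3; selection skipped",
                 "cipnsense_empty_selection_warning")
  list(step1 = step1, step2 = step2, step3 = as.character(step3),
       selected = as.character(step3))
}
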