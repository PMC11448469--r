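# Independent brute-force reference implementations used to cross-check
# the package's vectorised/streamlined code paths. These deliberately use
# different algorithms (pairwise scans, sweep lines, explicit per-item
# recounts) than the implementation.

PAIRS <- c("BAS>ACC", "ACC>BAS", "BAS>DEC", "DEC>BAS", "ACC>DEC", "DEC>ACC")

# Epoch containing instant t (> 0) by linear search over the grid.
oracle_epoch_of <- function(t, w = 1200) {
  k <- 0L
  while (!(t > k * w && t <= (k + 1) * w)) k <- k + 1L
  k
}

# O(n^2) transition counter: a pair (i, j) is a transition iff j starts
# strictly later than i (chronologically: smaller start), no third event
# starts between them, labels differ, and the gap end_i - start_j is
# within tolerance. Assigned to the epoch holding start_j.
oracle_transitions <- function(fhr, epoch_index, gap_tol = 60, w = 1200) {
  counts <- stats::setNames(rep(0L, 6), PAIRS)
  n <- nrow(fhr)
  if (n < 2) return(counts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || fhr$start[j] >= fhr$start[i]) next
      between <- any(fhr$start > fhr$start[j] & fhr$start < fhr$start[i])
      if (between) next
      if (fhr$label[i] == fhr$label[j]) next
      if (fhr$end[i] - fhr$start[j] > gap_tol) next
      if (oracle_epoch_of(fhr$start[j], w) != epoch_index) next
      key <- paste0(fhr$label[i], ">", fhr$label[j])
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# Sweep-line dwell totals: decompose the epoch window into elementary
# segments at every event boundary and attribute each segment to the label
# of the event covering its midpoint.
oracle_dwells <- function(events, epoch_index, w = 1200) {
  labels <- c("BAS", "ACC", "DEC", "CON", "RIN")
  out <- stats::setNames(rep(0, 5), labels)
  lo <- epoch_index * w
  hi <- (epoch_index + 1) * w
  cuts <- sort(unique(c(lo, hi, pmin(pmax(events$start, lo), hi),
                        pmin(pmax(events$end, lo), hi))))
  for (s in seq_len(length(cuts) - 1)) {
    mid <- (cuts[s] + cuts[s + 1]) / 2
    for (i in seq_len(nrow(events))) {
      if (mid <= events$start[i] && mid > events$end[i]) {
        out[events$label[i]] <- out[events$label[i]] + cuts[s + 1] - cuts[s]
      }
    }
  }
  out
}

# Expected window decision by direct application of the rule: full last-n
# windows only; > floor(n/2) missing slots defers; all observed slots
# alerting (at least one observed) recommends.
oracle_window_state <- function(window) {
  n <- length(window)
  n_missing <- sum(window == "missing")
  if (n_missing > n %/% 2) return("deferred")
  observed <- window[window != "missing"]
  if (length(observed) > 0 && all(observed == "alert")) return("recommend")
  "no-recommend"
}

# Per-epoch OOB recount: for each row, loop over the trees that excluded
# it and average their pathological votes.
oracle_oob <- function(votes, inbag) {
  n <- nrow(votes)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- c()
    for (t in seq_len(ncol(votes))) {
      if (inbag[i, t] == 0) v <- c(v, votes[i, t])
    }
    if (length(v) > 0) out[i] <- mean(v)
  }
  out
}

# Brute-force ROC/AUC for the n = 1 reduction: subjects ranked by their
# end-of-record maximum probability; explicit threshold loop + trapezoid.
oracle_auc_n1 <- function(phie_by_subject, groups, thresholds) {
  maxima <- vapply(phie_by_subject, function(p) {
    if (all(is.na(p))) -Inf else max(p, na.rm = TRUE)
  }, numeric(1))
  path <- groups[names(phie_by_subject)] != "healthy"
  fpr <- tpr <- numeric(length(thresholds))
  for (g in seq_along(thresholds)) {
    tpr[g] <- mean(maxima[path] > thresholds[g])
    fpr[g] <- mean(maxima[!path] > thresholds[g])
  }
  ord <- order(fpr, tpr)
  fx <- c(0, fpr[ord], 1)
  fy <- c(0, tpr[ord], 1)
  a <- 0
  for (s in seq_len(length(fx) - 1)) {
    a <- a + (fx[s + 1] - fx[s]) * (fy[s] + fy[s + 1]) / 2
  }
  a
}

# Direct recount of the cumulative recommendation curve.
oracle_curve <- function(decisions, group, epoch_range) {
  sub <- decisions[decisions$group == group, , drop = FALSE]
  out <- numeric(length(epoch_range))
  for (ki in seq_along(epoch_range)) {
    cnt <- 0
    for (i in seq_len(nrow(sub))) {
      if (isTRUE(sub$recommended[i]) &&
          sub$first_recommendation_epoch[i] >= epoch_range[ki]) {
        cnt <- cnt + 1
      }
    }
    out[ki] <- cnt / nrow(sub)
  }
  out
}

# Random non-overlapping FHR event sequence for oracle-equivalence tests:
# chronological events with random gaps, labels, and durations.
random_fhr_events <- function(total_span = 7200, mean_len = 120) {
  pos <- total_span
  starts <- ends <- numeric(0)
  labels <- character(0)
  while (pos > 1) {
    len <- min(pos, stats::rexp(1, 1 / mean_len) + 1)
    starts <- c(starts, pos)
    ends <- c(ends, pos - len)
    labels <- c(labels, sample(c("BAS", "ACC", "DEC"), 1))
    pos <- pos - len - stats::rexp(1, 1 / 30)  # gap, sometimes > tolerance
  }
  data.frame(channel = "FHR", label = labels, start = starts,
             end = pmax(ends, 0))
}
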