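#' Epoch grid with validity fractions
#'
#' Splits a record into 20-minute epochs anchored at delivery: epoch `k`
#' spans `((k)*w, (k+1)*w]` seconds before delivery (`w` = epoch length),
#' so epoch 0 ends at delivery and indices grow backwards in time. Only
#' complete epochs inside `[0, duration]` are kept; a trailing partial
#' epoch at the record start is dropped. The validity fraction of an epoch
#' is the proportion of its span not covered by uninterpretable segments.
#'
#' @param record A [labor_record()].
#' @param epoch_seconds Epoch length in seconds (default 1200 = 20 min).
#' @return `data.frame(epoch_index, valid_fraction)` in chronological
#'   order (decreasing `epoch_index`).
#' @export
epoch_grid <- function(record, epoch_seconds = 1200) {
  n_epochs <- floor(record$duration / epoch_seconds)
  if (n_epochs < 1) {
    return(data.frame(epoch_index = integer(0), valid_fraction = numeric(0)))
  }
  k <- seq.int(n_epochs - 1L, 0L)
  ep_start <- (k + 1) * epoch_seconds
  ep_end <- k * epoch_seconds
  inv <- record$invalid_intervals
  covered <- numeric(length(k))
  if (nrow(inv) > 0) {
    for (i in seq_len(nrow(inv))) {
      covered <- covered +
        interval_overlap(inv$start[i], inv$end[i], ep_start, ep_end)
    }
  }
  data.frame(epoch_index = k, valid_fraction = 1 - covered / epoch_seconds)
}

# Tabulate FHR transitions: for each chronologically consecutive pair of
# FHR events with differing labels and inter-event gap <= gap_tolerance,
# record the ordered pair and the epoch containing the later event's start
# instant. Returns data.frame(epoch_index, pair).
fhr_transitions <- function(fhr_events, gap_tolerance = 60,
                            epoch_seconds = 1200) {
  ev <- fhr_events[order(-fhr_events$start), , drop = FALSE]
  n <- nrow(ev)
  if (n < 2) return(data.frame(epoch_index = integer(0), pair = character(0)))
  from <- ev$label[-n]
  to <- ev$label[-1]
  gap <- ev$end[-n] - ev$start[-1]
  keep <- which(from != to & gap <= gap_tolerance)
  if (length(keep) == 0) {
    return(data.frame(epoch_index = integer(0), pair = character(0)))
  }
  data.frame(epoch_index = epoch_of(ev$start[-1][keep], epoch_seconds),
             pair = paste0(from[keep], ">", to[keep]))
}

#' Count FHR transitions within one epoch
#'
#' A transition occurs between chronologically consecutive FHR events with
#' differing labels whose inter-event gap does not exceed `gap_tolerance`
#' seconds (transitions across longer uninterpretable gaps are not
#' counted; same-label successions, possible after a gap, never count).
#' Each transition is assigned to the epoch containing the later event's
#' start instant; grid-boundary instants belong to the later
#' (closer-to-delivery) epoch.
#'
#' @param fhr_events `data.frame(channel, label, start, end)` of FHR
#'   events, non-overlapping.
#' @param epoch_index Epoch to count in (0 = the epoch ending at delivery).
#' @param gap_tolerance Maximum inter-event gap in seconds (default 60).
#' @param epoch_seconds Epoch length in seconds.
#' @return Named integer vector over the six ordered pairs
#'   `BAS>ACC, ACC>BAS, BAS>DEC, DEC>BAS, ACC>DEC, DEC>ACC`.
#' @export
count_transitions <- function(fhr_events, epoch_index, gap_tolerance = 60,
                              epoch_seconds = 1200) {
  tr <- fhr_transitions(fhr_events, gap_tolerance, epoch_seconds)
  tr <- tr[tr$epoch_index == epoch_index, , drop = FALSE]
  counts <- table(factor(tr$pair, levels = TRANSITION_PAIRS))
  stats::setNames(as.integer(counts), TRANSITION_PAIRS)
}

#' Total dwell time per event label within one epoch
#'
#' For each of the five labels (`BAS`, `ACC`, `DEC`, `CON`, `RIN`), the
#' total duration in seconds of the intersection of that label's event
#' intervals with the epoch window.
#'
#' @param events `data.frame(channel, label, start, end)` covering either
#'   or both channels.
#' @param epoch_index Epoch to intersect with.
#' @param epoch_seconds Epoch length in seconds.
#' @return Named numeric vector over `BAS, ACC, DEC, CON, RIN`.
#' @export
dwell_times <- function(events, epoch_index, epoch_seconds = 1200) {
  labels <- c(FHR_LABELS, UP_LABELS)
  ep_start <- (epoch_index + 1) * epoch_seconds
  ep_end <- epoch_index * epoch_seconds
  ol <- interval_overlap(events$start, events$end, ep_start, ep_end)
  out <- vapply(labels, function(l) sum(ol[events$label == l]), numeric(1))
  stats::setNames(out, labels)
}

#' Extract the 11-feature table of one record
#'
#' One row per epoch on the record's delivery-anchored grid. Epochs with
#' validity fraction below `min_valid` are retained as placeholders
#' (`valid = FALSE`, features `NA`) — the decision rule needs to know which
#' grid slots are missing — while valid epochs carry the 11 features: six
#' ordered FHR transition counts and five per-label dwell totals.
#'
#' @param record A [labor_record()].
#' @param epoch_seconds Epoch length (default 1200 s).
#' @param gap_tolerance Transition gap tolerance (default 60 s), see
#'   [count_transitions()].
#' @param min_valid Minimum validity fraction for an epoch to be used
#'   (default 0.8).
#' @return `data.frame` with columns `subject_id, group, epoch_index,
#'   valid, valid_fraction` and the 11 feature columns
#'   `t_bas_acc, t_acc_bas, t_bas_dec, t_dec_bas, t_acc_dec, t_dec_acc,
#'   d_bas, d_acc, d_dec, d_con, d_rin`, chronologically ordered.
#' @export
featurize_record <- function(record, epoch_seconds = 1200,
                             gap_tolerance = 60, min_valid = 0.8) {
  grid <- epoch_grid(record, epoch_seconds)
  n <- nrow(grid)
  feat <- matrix(NA_real_, nrow = n, ncol = length(FEATURE_NAMES),
                 dimnames = list(NULL, FEATURE_NAMES))
  valid <- grid$valid_fraction >= min_valid
  if (any(valid)) {
    ev <- record$events
    fhr <- ev[ev$channel == "FHR", , drop = FALSE]
    tr <- fhr_transitions(fhr, gap_tolerance, epoch_seconds)
    ep_start <- (grid$epoch_index + 1) * epoch_seconds
    ep_end <- grid$epoch_index * epoch_seconds
    for (i in which(valid)) {
      k <- grid$epoch_index[i]
      cnt <- table(factor(tr$pair[tr$epoch_index == k],
                          levels = TRANSITION_PAIRS))
      ol <- interval_overlap(ev$start, ev$end, ep_start[i], ep_end[i])
      dw <- vapply(c(FHR_LABELS, UP_LABELS),
                   function(l) sum(ol[ev$label == l]), numeric(1))
      feat[i, ] <- c(as.numeric(cnt), dw)
    }
  }
  cbind(data.frame(subject_id = rep(record$subject_id, n),
                   group = rep(record$group, n),
                   epoch_index = grid$epoch_index,
                   valid = valid,
                   valid_fraction = grid$valid_fraction),
        as.data.frame(feat))
}

#' Extract features for a whole cohort
#'
#' Applies [featurize_record()] to every record and binds the rows.
#'
#' @param records List of [labor_record()] objects.
#' @inheritParams featurize_record
#' @return A single feature `data.frame` (see [featurize_record()]).
#' @export
featurize_cohort <- function(records, epoch_seconds = 1200,
                             gap_tolerance = 60, min_valid = 0.8) {
  out <- do.call(rbind, lapply(records, featurize_record,
                               epoch_seconds = epoch_seconds,
                               gap_tolerance = gap_tolerance,
                               min_valid = min_valid))
  rownames(out) <- NULL
  out
}

#' Feature column names
#'
#' The 11 feature columns in canonical order: six FHR transition counts
#' followed by five dwell totals.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() FEATURE_NAMES
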