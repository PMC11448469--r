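#' Consecutive-alert decision policy
#'
#' The alerting rule: an epoch raises an alert when its risk probability
#' strictly exceeds `pt`; intervention is recommended the first time the
#' last `n` consecutive grid epochs all alert, tolerating at most
#' `floor(n/2)` missing epochs in the window (missing = invalid epoch or
#' no out-of-bag estimate). With more missing epochs, or before `n` grid
#' epochs have elapsed, the system defers — it does not decide until
#' there are more observations. With `latch = TRUE` (default) a
#' recommendation, once issued, persists to the end of the record.
#'
#' @param n Run length, an integer in 1..10.
#' @param pt Alert threshold in `[0, 1]`.
#' @param latch Should the first recommendation persist?
#' @return Object of class `decision_policy` with fields `n`, `pt`,
#'   `max_missing = floor(n/2)`, `latch`.
#' @export
decision_policy <- function(n, pt, latch = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 1, n <= 10, pt >= 0, pt <= 1)
  structure(list(n = n, pt = pt, max_missing = n %/% 2L, latch = latch),
            class = "decision_policy")
}

#' @export
print.decision_policy <- function(x, ...) {
  cat(sprintf("<decision_policy: n=%d, pt=%.4f, max_missing=%d, latch=%s>\n",
              x$n, x$pt, x$max_missing, x$latch))
  invisible(x)
}

#' Per-epoch alert flags from a probability stream
#'
#' @param phie Numeric vector of epoch risk probabilities in chronological
#'   order (earliest epoch first, delivery last); `NA` marks a missing
#'   epoch.
#' @param pt Alert threshold; an epoch alerts iff `phie > pt` (strict).
#' @return Character vector over `"alert"`, `"no-alert"`, `"missing"`.
#' @export
alert_stream <- function(phie, pt) {
  if (any(phie < 0 | phie > 1, na.rm = TRUE)) {
    stop("phie values must lie in [0, 1]")
  }
  out <- ifelse(is.na(phie), "missing", ifelse(phie > pt, "alert", "no-alert"))
  as.character(out)
}

#' Apply the consecutive-alert rule to an alert stream
#'
#' Processes epochs chronologically. Until `n` grid epochs have elapsed
#' the last-`n` window does not yet exist and the system is deferred — no
#' decision can be issued before `n` x 20 min of monitoring (100 min at
#' the default `n = 5`). From the `n`-th epoch on, the window of the last
#' `n` grid slots is examined: more than `floor(n/2)` missing slots defers
#' the decision; otherwise, if every observed slot alerts (and at least
#' one is observed) intervention is recommended, else not. Deferral never
#' resets a run — the test is simply re-applied at the next epoch.
#'
#' @param alert_flags Character vector from [alert_stream()], chronological
#'   order.
#' @param policy A [decision_policy()].
#' @param epoch_index Optional integer vector of epoch indices aligned with
#'   `alert_flags`; defaults to `(length - 1):0` (record start to
#'   delivery).
#' @return Object of class `subject_decision`: `recommended` (logical),
#'   `first_recommendation_epoch` (epoch index, or `NA` if never),
#'   `states` (per-epoch `"recommend"`/`"no-recommend"`/`"deferred"`,
#'   latched if the policy latches).
#' @export
recommend <- function(alert_flags, policy, epoch_index = NULL) {
  stopifnot(all(alert_flags %in% c("alert", "no-alert", "missing")))
  len <- length(alert_flags)
  if (is.null(epoch_index)) epoch_index <- seq.int(len - 1L, 0L)
  states <- character(len)
  first_epoch <- NA_integer_
  for (t in seq_len(len)) {
    if (t < policy$n) {
      states[t] <- "deferred"  # the last-n window does not exist yet
      next
    }
    win <- alert_flags[(t - policy$n + 1L):t]
    n_missing <- sum(win == "missing")
    states[t] <- if (n_missing > policy$max_missing) {
      "deferred"
    } else if (all(win[win != "missing"] == "alert") && n_missing < policy$n) {
      "recommend"
    } else {
      "no-recommend"
    }
    if (is.na(first_epoch) && states[t] == "recommend") {
      first_epoch <- epoch_index[t]
    }
  }
  if (policy$latch && !is.na(first_epoch)) {
    states[epoch_index <= first_epoch] <- "recommend"
  }
  structure(list(recommended = !is.na(first_epoch),
                 first_recommendation_epoch = first_epoch,
                 states = states,
                 epoch_index = epoch_index),
            class = "subject_decision")
}

# Subject score for the consecutive-alert rule at run length n: the
# largest threshold below which the subject would be recommended, i.e.
# max over admissible full windows (window entirely inside the record,
# <= floor(n/2) missing slots, >= 1 observed) of the minimum observed
# probability in the window. -Inf if no window is admissible. recommend()
# issues a recommendation at threshold pt iff score > pt, which makes
# threshold sweeps a ranking problem.
subject_score <- function(phie, n) {
  len <- length(phie)
  if (len < n) return(-Inf)
  best <- -Inf
  max_missing <- n %/% 2L
  for (t in n:len) {
    win <- phie[(t - n + 1L):t]
    n_missing <- sum(is.na(win))
    if (n_missing <= max_missing && n_missing < n) {
      best <- max(best, min(win, na.rm = TRUE))
    }
  }
  best
}

#' ROC curve of the recommendation system for one run length
#'
#' Sweeps the alert threshold `pt` over a grid and, for each value,
#' computes the subject-level true and false positive rates of the
#' end-of-record recommendation (TPR over pathological subjects — acidosis
#' or HIE; FPR over healthy). The sweep uses the exact reduction that a
#' subject is recommended at threshold `pt` iff its window score (max over
#' admissible `n`-windows of the minimum observed probability) exceeds
#' `pt`. AUC is the trapezoidal area over the `(FPR, TPR)` points
#' augmented with `(0, 0)` and `(1, 1)`.
#'
#' @param phie_by_subject Named list: per subject, the chronological
#'   probability stream (`NA` = missing epoch).
#' @param groups Named character vector of group labels per subject.
#' @param n Run length.
#' @param thresholds Threshold grid; default all distinct observed
#'   probabilities plus 0 and 1.
#' @return List with `roc` (`data.frame(pt, fpr, tpr)`, decreasing `pt`),
#'   `auc`, `n`, and the per-subject `scores`.
#' @export
roc_for_n <- function(phie_by_subject, groups, n, thresholds = NULL) {
  groups <- groups[names(phie_by_subject)]
  if (anyNA(groups)) stop("groups must cover every subject in phie_by_subject")
  pathological <- groups != "healthy"
  if (!any(pathological) || all(pathological)) {
    stop("both a healthy and a pathological group are required")
  }
  scores <- vapply(phie_by_subject, subject_score, numeric(1), n = n)

  if (is.null(thresholds)) {
    vals <- unlist(phie_by_subject, use.names = FALSE)
    thresholds <- sort(unique(c(0, 1, vals[is.finite(vals)])))
  } else {
    thresholds <- sort(unique(thresholds))
  }
  s_path <- sort(scores[pathological])
  s_health <- sort(scores[!pathological])
  # number of scores strictly greater than each threshold
  tpr <- (length(s_path) - findInterval(thresholds, s_path)) / length(s_path)
  fpr <- (length(s_health) - findInterval(thresholds, s_health)) / length(s_health)
  roc <- data.frame(pt = rev(thresholds), fpr = rev(fpr), tpr = rev(tpr))
  # rows are in decreasing pt, i.e. non-decreasing fpr
  fx <- c(0, roc$fpr, 1)
  fy <- c(0, roc$tpr, 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  list(roc = roc, auc = auc, n = n, scores = scores)
}

#' Select the run length maximizing AUC
#'
#' @param auc_by_n Named numeric vector of AUCs, names the run lengths.
#' @return The run length with the highest AUC; ties broken toward the
#'   smallest `n` (earlier decisions).
#' @export
select_n <- function(auc_by_n) {
  if (length(auc_by_n) == 0) stop("auc_by_n is empty")
  ns <- as.integer(names(auc_by_n) %||% seq_along(auc_by_n))
  ord <- order(ns)
  ns <- ns[ord]
  auc <- auc_by_n[ord]
  ns[which.max(auc)]
}

#' Select the alert threshold under an FPR constraint
#'
#' Chooses the smallest (most sensitive) threshold whose training FPR does
#' not exceed `target_fpr` — the calibration anchoring the system's false
#' positive rate to the healthy-group Caesarean rate. If no grid threshold
#' satisfies the constraint, returns `pt = 1` with a warning (no epoch can
#' then alert, since alerts require `phie > pt`).
#'
#' @param roc The `roc` data.frame from [roc_for_n()] (columns `pt`,
#'   `fpr`, `tpr`).
#' @param target_fpr Maximum admissible FPR, in `[0, 1]`.
#' @return List with `pt`, its training `fpr`, and `target_fpr`.
#' @export
select_pt <- function(roc, target_fpr) {
  stopifnot(target_fpr >= 0, target_fpr <= 1)
  ok <- roc$fpr <= target_fpr
  if (!any(ok)) {
    warning("no threshold satisfies FPR <= ", target_fpr, "; returning pt = 1")
    return(list(pt = 1, fpr = 0, target_fpr = target_fpr))
  }
  i <- which(ok)[which.min(roc$pt[ok])]
  list(pt = roc$pt[i], fpr = roc$fpr[i], target_fpr = target_fpr)
}
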