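#' Construct a labor record
#'
#' A labor record holds one subject's full set of event-interval annotations
#' on the fetal heart rate (FHR) and uterine pressure (UP) channels, the
#' uninterpretable (noisy) segments, and outcome metadata. All times are in
#' seconds before delivery (delivery = 0), so intervals run from a larger
#' `start` down to a smaller `end` and chronological order is decreasing
#' `start`. Intervals are half-open at the delivery side: `[start, end)`
#' covers `end < t <= start`, so adjacent events may share a boundary.
#'
#' FHR events are labeled `BAS` (baseline), `ACC` (acceleration) or `DEC`
#' (deceleration); UP events are `CON` (contraction) or `RIN` (resting
#' interval). FHR events need not tile the record: unlabeled gaps are
#' permitted and distinct from uninterpretable segments.
#'
#' @param subject_id Character scalar identifier.
#' @param group One of `"healthy"`, `"acidosis"`, `"HIE"`.
#' @param duration Record length in seconds (at most 43,200 s = 12 h).
#' @param caesarean Logical: was a Caesarean delivery observed?
#' @param events `data.frame` with columns `channel` (`"FHR"`/`"UP"`),
#'   `label`, `start`, `end`. May be empty.
#' @param invalid_intervals `data.frame` with columns `start`, `end`
#'   marking uninterpretable segments. May be empty.
#' @return An object of class `labor_record`.
#' @seealso [validate_record()], [read_records()], [simulate_record()]
#' @export
labor_record <- function(subject_id, group, duration, caesarean,
                         events = NULL, invalid_intervals = NULL) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(channel = character(0), label = character(0),
                         start = numeric(0), end = numeric(0))
  }
  events <- events[order(events$channel, -events$start), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(invalid_intervals) || nrow(invalid_intervals) == 0) {
    invalid_intervals <- data.frame(start = numeric(0), end = numeric(0))
  }
  invalid_intervals <- invalid_intervals[order(-invalid_intervals$start), ,
                                         drop = FALSE]
  rownames(invalid_intervals) <- NULL
  structure(
    list(subject_id = as.character(subject_id),
         group = as.character(group),
         duration = as.numeric(duration),
         caesarean = as.logical(caesarean),
         events = events,
         invalid_intervals = invalid_intervals),
    class = "labor_record"
  )
}

#' @export
print.labor_record <- function(x, ...) {
  cat(sprintf("<labor_record %s: %s, %.0f s, caesarean=%s, %d FHR / %d UP events, %d invalid segments>\n",
              x$subject_id, x$group, x$duration, x$caesarean,
              sum(x$events$channel == "FHR"), sum(x$events$channel == "UP"),
              nrow(x$invalid_intervals)))
  invisible(x)
}

#' Validate a labor record's invariants
#'
#' Checks every structural invariant of a [labor_record()] and reports the
#' violations found. Validation never throws: it returns a character vector
#' (empty when the record is well formed), each element naming the violated
#' invariant and the offending interval.
#'
#' Checked invariants: group and channel/label vocabulary; `start > end >= 0`
#' for every interval; all intervals inside `[0, duration]` with
#' `duration <= 43200`; per-channel events non-overlapping; uninterpretable
#' segments not overlapping any FHR event.
#'
#' @param record A `labor_record`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_record <- function(record) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  ivname <- function(ch, lab, s, e) sprintf("%s/%s [%g, %g)", ch, lab, s, e)

  if (!record$group %in% GROUPS) {
    note(sprintf("group: '%s' not one of %s", record$group,
                 paste(GROUPS, collapse = "/")))
  }
  if (!is.finite(record$duration) || record$duration <= 0) {
    note(sprintf("duration: %g is not a positive finite length", record$duration))
  } else if (record$duration > MAX_DURATION) {
    note(sprintf("duration: %g exceeds the %d s cap", record$duration, MAX_DURATION))
  }

  ev <- record$events
  for (i in seq_len(nrow(ev))) {
    ch <- ev$channel[i]; lab <- ev$label[i]
    s <- ev$start[i]; e <- ev$end[i]
    ok_vocab <- (ch == "FHR" && lab %in% FHR_LABELS) ||
      (ch == "UP" && lab %in% UP_LABELS)
    if (!ok_vocab) {
      note(sprintf("label/channel mismatch: %s", ivname(ch, lab, s, e)))
    }
    if (!(s > e && e >= 0)) {
      note(sprintf("interval order: %s must satisfy start > end >= 0",
                   ivname(ch, lab, s, e)))
    }
    if (s > record$duration) {
      note(sprintf("bounds: %s extends beyond record duration %g",
                   ivname(ch, lab, s, e), record$duration))
    }
  }

  # per-channel overlap: with events sorted by decreasing start, an event
  # must end no earlier (in before-delivery time, no lower bound violated)
  # than the next one starts
  for (ch in c("FHR", "UP")) {
    sub <- ev[ev$channel == ch, , drop = FALSE]
    if (nrow(sub) > 1) {
      sub <- sub[order(-sub$start), , drop = FALSE]
      for (i in 1:(nrow(sub) - 1)) {
        if (sub$end[i] < sub$start[i + 1]) {
          note(sprintf("overlap on %s: %s overlaps %s", ch,
                       ivname(ch, sub$label[i], sub$start[i], sub$end[i]),
                       ivname(ch, sub$label[i + 1], sub$start[i + 1], sub$end[i + 1])))
        }
      }
    }
  }

  inv <- record$invalid_intervals
  for (i in seq_len(nrow(inv))) {
    s <- inv$start[i]; e <- inv$end[i]
    if (!(s > e && e >= 0)) {
      note(sprintf("invalid segment order: [%g, %g) must satisfy start > end >= 0", s, e))
    }
    if (s > record$duration) {
      note(sprintf("bounds: invalid segment [%g, %g) beyond duration %g",
                   s, e, record$duration))
    }
  }
  fhr <- ev[ev$channel == "FHR", , drop = FALSE]
  if (nrow(inv) > 0 && nrow(fhr) > 0) {
    for (i in seq_len(nrow(inv))) {
      ol <- interval_overlap(inv$start[i], inv$end[i], fhr$start, fhr$end)
      for (j in which(ol > 0)) {
        note(sprintf("invalid segment [%g, %g) overlaps FHR event %s",
                     inv$start[i], inv$end[i],
                     ivname("FHR", fhr$label[j], fhr$start[j], fhr$end[j])))
      }
    }
  }
  v
}

#' Read labor records from event and metadata files
#'
#' The events file is comma-delimited with header
#' `subject_id,channel,label,start_s,end_s`; `channel` is `FHR` or `UP` and
#' `label` the corresponding event vocabulary. Rows with channel `QC` and
#' label `INV` carry the record's uninterpretable segments (an extension of
#' the event vocabulary so that the full record round-trips through a single
#' file pair). The metadata file has header
#' `subject_id,group,duration_s,caesarean` with `group` in
#' `healthy`/`acidosis`/`HIE` and `caesarean` in `{0, 1}`. Times use seconds
#' before delivery with a `.` decimal separator.
#'
#' Every event row must reference a subject present in the metadata, and
#' each assembled record must pass [validate_record()]; otherwise reading
#' aborts with a message naming the offending line or violation.
#'
#' @param events_path,metadata_path Paths to the two files.
#' @return List of [labor_record()] objects, in metadata row order.
#' @export
read_records <- function(events_path, metadata_path) {
  ev <- utils::read.csv(events_path, colClasses = c(
    subject_id = "character", channel = "character", label = "character",
    start_s = "character", end_s = "character"))
  need <- c("subject_id", "channel", "label", "start_s", "end_s")
  if (!identical(names(ev), need)) {
    stop("events file columns must be ", paste(need, collapse = ","),
         " (got ", paste(names(ev), collapse = ","), ")")
  }
  start <- suppressWarnings(as.numeric(ev$start_s))
  end <- suppressWarnings(as.numeric(ev$end_s))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0) {
    stop("malformed event row at line ", bad[1] + 1L,
         " of ", events_path, ": non-numeric start/end")
  }
  ev$start <- start
  ev$end <- end

  md <- utils::read.csv(metadata_path, colClasses = c(
    subject_id = "character", group = "character",
    duration_s = "numeric", caesarean = "integer"))
  needm <- c("subject_id", "group", "duration_s", "caesarean")
  if (!identical(names(md), needm)) {
    stop("metadata file columns must be ", paste(needm, collapse = ","))
  }
  if (anyDuplicated(md$subject_id)) {
    stop("duplicate subject_id in metadata: ",
         md$subject_id[duplicated(md$subject_id)][1])
  }
  unknown <- setdiff(ev$subject_id, md$subject_id)
  if (length(unknown) > 0) {
    stop("event rows reference subject absent from metadata: ", unknown[1])
  }

  records <- lapply(seq_len(nrow(md)), function(i) {
    sub <- ev[ev$subject_id == md$subject_id[i], , drop = FALSE]
    is_inv <- sub$channel == "QC" & sub$label == "INV"
    rec <- labor_record(
      subject_id = md$subject_id[i],
      group = md$group[i],
      duration = md$duration_s[i],
      caesarean = md$caesarean[i] == 1L,
      events = sub[!is_inv, c("channel", "label", "start", "end")],
      invalid_intervals = sub[is_inv, c("start", "end")]
    )
    viol <- validate_record(rec)
    if (length(viol) > 0) {
      stop("invalid record ", rec$subject_id, ": ", viol[1])
    }
    rec
  })
  records
}

#' Write labor records to event and metadata files
#'
#' Inverse of [read_records()]: `read_records()` applied to the written
#' files reproduces the records field-for-field. Uninterpretable segments
#' are written as `QC,INV` rows (see [read_records()]).
#'
#' @param records List of `labor_record` objects.
#' @param events_path,metadata_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_records <- function(records, events_path, metadata_path) {
  ev_rows <- lapply(records, function(r) {
    ev <- r$events
    out <- data.frame(subject_id = rep(r$subject_id, nrow(ev)),
                      channel = ev$channel, label = ev$label,
                      start_s = ev$start, end_s = ev$end)
    inv <- r$invalid_intervals
    if (nrow(inv) > 0) {
      out <- rbind(out, data.frame(
        subject_id = r$subject_id, channel = "QC", label = "INV",
        start_s = inv$start, end_s = inv$end))
    }
    out
  })
  ev_all <- do.call(rbind, c(ev_rows, list(data.frame(
    subject_id = character(0), channel = character(0), label = character(0),
    start_s = numeric(0), end_s = numeric(0)))))
  utils::write.csv(ev_all, events_path, row.names = FALSE, quote = FALSE)

  md <- data.frame(
    subject_id = vapply(records, `[[`, character(1), "subject_id"),
    group = vapply(records, `[[`, character(1), "group"),
    duration_s = vapply(records, `[[`, numeric(1), "duration"),
    caesarean = as.integer(vapply(records, `[[`, logical(1), "caesarean")))
  utils::write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Cohort metadata table
#'
#' Collects per-subject metadata from a list of records into a data frame
#' (one row per subject: `subject_id`, `group`, `duration`, `caesarean`).
#'
#' @param records List of `labor_record` objects.
#' @return A `data.frame`.
#' @export
cohort_metadata <- function(records) {
  data.frame(
    subject_id = vapply(records, `[[`, character(1), "subject_id"),
    group = vapply(records, `[[`, character(1), "group"),
    duration = vapply(records, `[[`, numeric(1), "duration"),
    caesarean = vapply(records, `[[`, logical(1), "caesarean"))
}
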