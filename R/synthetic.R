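#' Semi-Markov channel parameters
#'
#' One channel of the labor-event generator: a state set, an embedded
#' transition matrix (zero diagonal, rows summing to 1 — self-transitions
#' are unobservable in an event stream), and a log-normal dwell
#' distribution per state (`meanlog` in log-seconds, `sdlog`).
#'
#' @param states Character vector of state labels.
#' @param trans Square transition matrix, `states` x `states`.
#' @param dwell_meanlog,dwell_sdlog Named numeric vectors over `states`.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(states, trans, dwell_meanlog, dwell_sdlog) {
  trans <- as.matrix(trans)
  dimnames(trans) <- list(states, states)
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-9),
            all(abs(diag(trans)) < 1e-12),
            all(dwell_sdlog >= 0))
  structure(list(states = states, trans = trans,
                 dwell_meanlog = dwell_meanlog[states],
                 dwell_sdlog = dwell_sdlog[states]),
            class = "channel_params")
}

#' Semi-Markov labor-event generator parameters for one group
#'
#' Describes how one outcome group's event sequences are generated: an FHR
#' channel over `BAS`/`ACC`/`DEC`, a UP channel over `CON`/`RIN`, a
#' deceleration drift that intensifies as delivery approaches, a Poisson
#' model of uninterpretable segments, and a record-duration range.
#'
#' The drift encodes the physiology that hypoxic stress expresses as more
#' frequent and longer decelerations toward delivery. At time-to-delivery
#' `t` the drift weight is
#' `w(t) = drift_floor + (1 - drift_floor) * max(0, 1 - t/drift_horizon)`,
#' rising linearly from `drift_floor` (at or beyond the horizon) to 1 at
#' delivery. The effective BAS->DEC transition probability becomes
#' `p + w(t) * dec_prob_drift` (other BAS-row entries rescaled to keep the
#' row a distribution) and the DEC dwell mean-log becomes
#' `meanlog + w(t) * dec_dwell_drift` (multiplicative on the seconds
#' scale). A positive `drift_floor` gives a group a constant elevation in
#' deceleration burden across the whole record, on top of the ramp.
#'
#' @param fhr,up [channel_params()] for the two channels.
#' @param dec_prob_drift Added BAS->DEC probability at full drift weight.
#' @param dec_dwell_drift Added DEC dwell `meanlog` at full drift weight.
#' @param drift_floor Drift weight far from delivery, in `[0, 1]`.
#' @param drift_horizon Seconds before delivery at which the ramp starts.
#' @param invalid_rate Uninterpretable-segment arrivals per hour.
#' @param invalid_mean Mean uninterpretable-segment duration, seconds.
#' @param duration_range Record duration drawn uniformly from this range
#'   (seconds), capped at 43,200.
#' @return Object of class `sm_params`.
#' @export
sm_params <- function(fhr = default_fhr_channel(),
                      up = default_up_channel(),
                      dec_prob_drift = 0,
                      dec_dwell_drift = 0,
                      drift_floor = 0,
                      drift_horizon = 21600,
                      invalid_rate = 1,
                      invalid_mean = 90,
                      duration_range = c(14400, 43200)) {
  stopifnot(drift_floor >= 0, drift_floor <= 1, drift_horizon > 0,
            invalid_rate >= 0, invalid_mean > 0,
            length(duration_range) == 2,
            duration_range[1] > 0, diff(duration_range) >= 0)
  duration_range <- pmin(duration_range, MAX_DURATION)
  # drift must keep the BAS row a sub-distribution at w = 1
  p_dec <- fhr$trans["BAS", "DEC"]
  stopifnot(p_dec + dec_prob_drift <= 1 + 1e-12, p_dec + dec_prob_drift >= 0)
  structure(list(fhr = fhr, up = up,
                 dec_prob_drift = dec_prob_drift,
                 dec_dwell_drift = dec_dwell_drift,
                 drift_floor = drift_floor,
                 drift_horizon = drift_horizon,
                 invalid_rate = invalid_rate,
                 invalid_mean = invalid_mean,
                 duration_range = duration_range),
            class = "sm_params")
}

#' @rdname sm_params
#' @export
default_fhr_channel <- function() {
  channel_params(
    states = FHR_LABELS,
    trans = rbind(BAS = c(BAS = 0, ACC = 0.5, DEC = 0.5),
                  ACC = c(BAS = 0.85, ACC = 0, DEC = 0.15),
                  DEC = c(BAS = 0.85, ACC = 0.15, DEC = 0)),
    dwell_meanlog = c(BAS = log(300), ACC = log(45), DEC = log(50)),
    dwell_sdlog = c(BAS = 0.5, ACC = 0.35, DEC = 0.4))
}

#' @rdname sm_params
#' @export
default_up_channel <- function() {
  channel_params(
    states = UP_LABELS,
    trans = rbind(CON = c(CON = 0, RIN = 1),
                  RIN = c(CON = 1, RIN = 0)),
    dwell_meanlog = c(CON = log(75), RIN = log(100)),
    dwell_sdlog = c(CON = 0.25, RIN = 0.45))
}

#' Default generator parameters per outcome group
#'
#' Healthy labor has a mild deceleration ramp toward delivery (labor is
#' stressful for every fetus); the acidosis and HIE groups add a constant
#' elevation (`drift_floor = 0.25`) and progressively stronger ramps in
#' both deceleration entry probability and deceleration duration, HIE being
#' the most severe.
#'
#' @param group `"healthy"`, `"acidosis"` or `"HIE"`.
#' @return An [sm_params()] object.
#' @export
default_group_params <- function(group) {
  group <- match.arg(group, GROUPS)
  switch(group,
    healthy = sm_params(dec_prob_drift = 0.10, dec_dwell_drift = log(1.25),
                        drift_floor = 0),
    acidosis = sm_params(dec_prob_drift = 0.30, dec_dwell_drift = log(2.0),
                         drift_floor = 0.25),
    HIE = sm_params(dec_prob_drift = 0.45, dec_dwell_drift = log(3.0),
                    drift_floor = 0.25))
}

# drift weight at time-to-delivery t
drift_weight <- function(t, params) {
  params$drift_floor +
    (1 - params$drift_floor) * pmax(0, 1 - t / params$drift_horizon)
}

# BAS transition row with DEC-entry drift applied; other entries rescaled
drifted_row <- function(row, extra_dec) {
  p_dec <- min(1, max(0, row["DEC"] + extra_dec))
  others <- setdiff(names(row), "DEC")
  base_other <- sum(row[others])
  if (base_other > 0) row[others] <- row[others] * (1 - p_dec) / base_other
  row["DEC"] <- p_dec
  row
}

#' Sample one dwell time
#'
#' Draws the duration spent in `state` from its log-normal dwell
#' distribution, with the group's deceleration-duration drift applied when
#' `state == "DEC"` (see [sm_params()]). Uses the current RNG stream.
#'
#' @param state State label on either channel.
#' @param time_to_delivery Seconds before delivery at which the dwell
#'   starts (drives the drift weight).
#' @param params An [sm_params()] object.
#' @return Positive duration in seconds.
#' @export
sample_dwell <- function(state, time_to_delivery, params) {
  ch <- dwell_channel(state, params)
  meanlog <- ch$dwell_meanlog[state]
  if (state == "DEC") {
    meanlog <- meanlog + drift_weight(time_to_delivery, params) * params$dec_dwell_drift
  }
  stats::rlnorm(1, meanlog = meanlog, sdlog = ch$dwell_sdlog[state])
}

dwell_channel <- function(state, params) {
  if (state %in% params$fhr$states) return(params$fhr)
  if (state %in% params$up$states) return(params$up)
  stop("unknown state: ", state)
}

#' Sample the next semi-Markov state
#'
#' Draws the successor of `current_state` from its (possibly drifted)
#' transition row; never returns `current_state` itself. For the FHR
#' channel the BAS row's DEC-entry probability is drifted by the group's
#' `dec_prob_drift` at the current drift weight.
#'
#' @param current_state State label.
#' @param channel `"FHR"` or `"UP"`.
#' @param time_to_delivery Seconds before delivery (drift weight input).
#' @param params An [sm_params()] object.
#' @return The next state label.
#' @export
next_state <- function(current_state, channel, time_to_delivery, params) {
  ch <- if (channel == "FHR") params$fhr else params$up
  if (!current_state %in% ch$states) {
    stop("unknown state '", current_state, "' on channel ", channel)
  }
  row <- ch$trans[current_state, ]
  if (channel == "FHR" && current_state == "BAS") {
    row <- drifted_row(row, drift_weight(time_to_delivery, params) * params$dec_prob_drift)
  }
  sample(ch$states, 1, prob = row)
}

# Generate one channel's event sequence chronologically, from the record
# start (t = duration) toward delivery (t = 0). The drift weight for each
# interval uses the interval's start instant. Inlines the sampling of
# sample_dwell()/next_state() for speed; semantics are identical (asserted
# by tests against the exported functions).
simulate_channel <- function(channel, duration, params, init_state) {
  ch <- if (channel == "FHR") params$fhr else params$up
  states <- ch$states
  meanlog <- ch$dwell_meanlog
  sdlog <- ch$dwell_sdlog
  trans <- ch$trans
  fl <- params$drift_floor
  hz <- params$drift_horizon
  is_fhr <- channel == "FHR"

  cap <- 64L
  starts <- ends <- numeric(cap)
  labels <- character(cap)
  state <- init_state
  pos <- duration
  i <- 0L
  repeat {
    w <- fl + (1 - fl) * max(0, 1 - pos / hz)
    ml <- meanlog[[state]]
    if (is_fhr && state == "DEC") ml <- ml + w * params$dec_dwell_drift
    d <- stats::rlnorm(1, meanlog = ml, sdlog = sdlog[[state]])
    e <- max(0, pos - d)
    i <- i + 1L
    if (i > cap) {
      cap <- cap * 2L
      length(starts) <- cap; length(ends) <- cap; length(labels) <- cap
    }
    starts[i] <- pos; ends[i] <- e; labels[i] <- state
    if (e <= 0) break
    row <- trans[state, ]
    if (is_fhr && state == "BAS") {
      we <- fl + (1 - fl) * max(0, 1 - e / hz)
      row <- drifted_row(row, we * params$dec_prob_drift)
    }
    state <- states[sample.int(length(states), 1L, prob = row)]
    pos <- e
  }
  data.frame(channel = rep(channel, i), label = labels[seq_len(i)],
             start = starts[seq_len(i)], end = ends[seq_len(i)])
}

# Split FHR events around uninterpretable segments; fragments shorter than
# min_fragment seconds are dropped.
punch_out_invalid <- function(fhr, invalid, min_fragment = 5) {
  if (nrow(invalid) == 0 || nrow(fhr) == 0) return(fhr)
  inv_s <- invalid$start
  inv_e <- invalid$end
  acc_s <- acc_e <- numeric(0)
  acc_lab <- character(0)
  for (i in seq_len(nrow(fhr))) {
    s <- fhr$start[i]; e <- fhr$end[i]
    hit <- which(pmin(s, inv_s) - pmax(e, inv_e) > 0)
    if (length(hit) == 0) {
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      acc_lab <- c(acc_lab, fhr$label[i])
      next
    }
    ord <- hit[order(-inv_s[hit])]
    seg_start <- s
    out_s <- out_e <- numeric(0)
    for (j in ord) {
      if (inv_s[j] < seg_start) {
        out_s <- c(out_s, seg_start)
        out_e <- c(out_e, max(inv_s[j], e))
      }
      seg_start <- min(seg_start, inv_e[j])
      if (seg_start <= e) break
    }
    if (seg_start > e) {
      out_s <- c(out_s, seg_start)
      out_e <- c(out_e, e)
    }
    keep <- (out_s - out_e) >= min_fragment
    acc_s <- c(acc_s, out_s[keep]); acc_e <- c(acc_e, out_e[keep])
    acc_lab <- c(acc_lab, rep(fhr$label[i], sum(keep)))
  }
  data.frame(channel = rep("FHR", length(acc_s)), label = acc_lab,
             start = acc_s, end = acc_e)
}

#' Simulate one labor record
#'
#' Generates FHR and UP event sequences chronologically (from the record
#' start toward delivery) by alternating [next_state()] and
#' [sample_dwell()] until the record duration is covered; the final event
#' on each channel is truncated at delivery. Uninterpretable segments
#' arrive as a Poisson process (rate `invalid_rate` per hour) with
#' exponential durations (mean `invalid_mean` s); FHR events overlapping
#' them are split at the segment boundaries and fragments shorter than 5 s
#' are dropped. The two channels are generated independently; both share
#' the group's drift clock.
#'
#' The result always satisfies [validate_record()].
#'
#' @param subject_id Identifier for the record.
#' @param group Outcome group label (annotates the record).
#' @param params An [sm_params()] object (typically the group's).
#' @param duration Record length in seconds; drawn uniformly from
#'   `params$duration_range` when `NULL`.
#' @param caesarean Logical outcome flag stored on the record.
#' @return A [labor_record()].
#' @export
simulate_record <- function(subject_id, group, params, duration = NULL,
                            caesarean = FALSE) {
  if (is.null(duration)) {
    duration <- stats::runif(1, params$duration_range[1], params$duration_range[2])
  }
  duration <- min(duration, MAX_DURATION)
  fhr <- simulate_channel("FHR", duration, params, init_state = "BAS")
  up_init <- sample(UP_LABELS, 1)
  up <- simulate_channel("UP", duration, params, init_state = up_init)

  n_inv <- stats::rpois(1, params$invalid_rate * duration / 3600)
  invalid <- data.frame(start = numeric(0), end = numeric(0))
  if (n_inv > 0) {
    st <- stats::runif(n_inv, 0, duration)
    du <- stats::rexp(n_inv, rate = 1 / params$invalid_mean)
    invalid <- merge_intervals(data.frame(start = st, end = pmax(0, st - du)))
  }
  fhr <- punch_out_invalid(fhr, invalid)
  labor_record(subject_id, group, duration, caesarean,
               events = rbind(fhr, up), invalid_intervals = invalid)
}

#' Cohort generator configuration
#'
#' @param size Number of subjects.
#' @param group_props Named proportions over the three groups (default:
#'   the 37,546 / 3,056 / 374 healthy/acidosis/HIE composition,
#'   normalized).
#' @param caesarean_prob Named per-group Caesarean probabilities (default
#'   0.389 / 0.376 / 0.549).
#' @param params Named list of [sm_params()] per group.
#' @param seed Integer root seed; every record gets its own derived
#'   substream so cohorts are reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(size,
                          group_props = c(healthy = 37546, acidosis = 3056,
                                          HIE = 374) / 40976,
                          caesarean_prob = c(healthy = 0.389,
                                             acidosis = 0.376, HIE = 0.549),
                          params = NULL, seed = 1L) {
  stopifnot(abs(sum(group_props) - 1) < 1e-9,
            all(caesarean_prob >= 0 & caesarean_prob <= 1))
  if (is.null(params)) {
    params <- stats::setNames(lapply(GROUPS, default_group_params), GROUPS)
  }
  structure(list(size = as.integer(size),
                 group_props = group_props[GROUPS],
                 caesarean_prob = caesarean_prob[GROUPS],
                 params = params, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort of labor records
#'
#' Group counts follow the configured proportions by largest-remainder
#' rounding; Caesarean flags are Bernoulli draws at the per-group rates;
#' each record is generated on its own seed substream derived from the
#' root seed, so the cohort is fully reproducible.
#'
#' @param config A [cohort_config()].
#' @return List of [labor_record()] objects.
#' @export
simulate_cohort <- function(config) {
  counts <- largest_remainder(config$group_props, config$size)
  groups <- rep(GROUPS, counts)
  set.seed(config$seed)
  caesarean <- stats::rbinom(config$size, 1,
                             config$caesarean_prob[groups]) == 1L
  rec_seeds <- sample.int(.Machine$integer.max - 1L, config$size)
  lapply(seq_len(config$size), function(i) {
    set.seed(rec_seeds[i])
    simulate_record(sprintf("S%05d", i), groups[i],
                    config$params[[groups[i]]], caesarean = caesarean[i])
  })
}
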