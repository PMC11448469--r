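#' Stratified subject-level train/test split
#'
#' Splits subjects into disjoint, exhaustive train and test sets,
#' stratified by group. Test counts per group follow largest-remainder
#' apportionment of `test_fraction`, and every group contributes at least
#' one test subject.
#'
#' @param x List of [labor_record()] objects, or a metadata `data.frame`
#'   with `subject_id` and `group` columns.
#' @param test_fraction Fraction of subjects for testing, in `(0, 1)`.
#' @param seed Integer seed.
#' @return List with character vectors `train_ids` and `test_ids`.
#' @export
split_cohort <- function(x, test_fraction = 0.1, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  md <- if (is.data.frame(x)) x else cohort_metadata(x)
  md$group <- factor(md$group, levels = intersect(GROUPS, unique(md$group)))
  sizes <- table(md$group)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 subjects; got ",
         paste(names(sizes)[sizes < 2], collapse = ", "), " smaller")
  }
  total_test <- round(test_fraction * nrow(md))
  n_test <- largest_remainder(as.numeric(sizes), total_test)
  n_test <- pmax(n_test, 1L)
  set.seed(seed)
  test_ids <- unlist(lapply(seq_along(sizes), function(g) {
    ids <- md$subject_id[as.integer(md$group) == g]
    sample(ids, n_test[g])
  }), use.names = FALSE)
  list(train_ids = setdiff(md$subject_id, test_ids), test_ids = test_ids)
}

#' Pipeline configuration for one evaluation iteration
#'
#' @param trees Trees per forest (default 2,500).
#' @param n_range Run lengths searched (default 1..10).
#' @param test_fraction Test split fraction (default 0.1).
#' @param target_fpr FPR calibration target; `NULL` (default) uses the
#'   observed healthy-group Caesarean rate of the full cohort.
#' @param mtry,min_node_size Forest hyperparameters, see [forest_config()].
#' @param epoch_seconds,gap_tolerance,min_valid Featurization parameters,
#'   see [featurize_record()].
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(trees = 2500, n_range = 1:10, test_fraction = 0.1,
                        target_fpr = NULL, mtry = 3, min_node_size = 1,
                        epoch_seconds = 1200, gap_tolerance = 60,
                        min_valid = 0.8) {
  structure(list(trees = trees, n_range = n_range,
                 test_fraction = test_fraction, target_fpr = target_fpr,
                 mtry = mtry, min_node_size = min_node_size,
                 epoch_seconds = epoch_seconds,
                 gap_tolerance = gap_tolerance, min_valid = min_valid),
            class = "eval_config")
}

# Per-subject chronological probability streams on the delivery-anchored
# grid. features: rows for a set of subjects; phie: probabilities aligned
# with the VALID rows of `features` (NA allowed, e.g. no out-of-bag
# estimate). Invalid epochs become NA slots.
phie_series <- function(features, phie) {
  stopifnot(sum(features$valid) == length(phie))
  p_all <- rep(NA_real_, nrow(features))
  p_all[features$valid] <- phie
  split(p_all, features$subject_id)[unique(features$subject_id)]
  # rows are chronological within subject already (featurize order)
}

#' Run one train/test iteration of the full pipeline
#'
#' Executes, for one random split: subject-level stratified 90/10 split;
#' balanced-forest training on valid training epochs; out-of-bag epoch
#' probabilities; run-length selection by maximal subject-level AUC over
#' `n_range`; threshold selection under the FPR constraint — all from
#' training data only — then applies the frozen policy to the test set and
#' records per-group recommendation-rate curves.
#'
#' @param records Cohort as a list of [labor_record()] objects.
#' @param config An [eval_config()].
#' @param seed Integer seed for this iteration (split + forest).
#' @param features Optional precomputed [featurize_cohort()] table (saves
#'   recomputation across iterations).
#' @return Object of class `iteration_result`: `seed`, `n_hat`, `pt_hat`
#'   (with its training FPR), `auc_by_n`, `policy`, the training ROC at
#'   the selected run length (`roc_at_n_hat`), test-set `decisions`
#'   (`data.frame`), per-group `curves`, training-set out-of-bag table
#'   `oob` (`subject_id`, `group`, `epoch_index`, `phie`), and group
#'   sizes.
#' @export
run_iteration <- function(records, config = eval_config(), seed = 1L,
                          features = NULL) {
  if (is.null(features)) {
    features <- featurize_cohort(records,
                                 epoch_seconds = config$epoch_seconds,
                                 gap_tolerance = config$gap_tolerance,
                                 min_valid = config$min_valid)
  }
  md <- cohort_metadata(records)
  target_fpr <- config$target_fpr %||%
    mean(md$caesarean[md$group == "healthy"])

  seeds <- spawn_seeds(seed, 2)
  split <- split_cohort(md, config$test_fraction, seed = seeds[1])
  tr_feat <- features[features$subject_id %in% split$train_ids, , drop = FALSE]
  te_feat <- features[features$subject_id %in% split$test_ids, , drop = FALSE]

  model <- train_forest(tr_feat, forest_config(
    trees = config$trees, mtry = config$mtry,
    min_node_size = config$min_node_size, seed = seeds[2]))

  groups <- stats::setNames(md$group, md$subject_id)
  tr_series <- phie_series(tr_feat, model$oob)
  rocs <- lapply(config$n_range, function(n) {
    roc_for_n(tr_series, groups, n)
  })
  auc_by_n <- stats::setNames(vapply(rocs, `[[`, numeric(1), "auc"),
                              config$n_range)
  n_hat <- select_n(auc_by_n)
  roc_at_n_hat <- rocs[[match(n_hat, config$n_range)]]$roc
  sel <- select_pt(roc_at_n_hat, target_fpr)
  policy <- decision_policy(n_hat, sel$pt)

  te_valid <- te_feat[te_feat$valid, , drop = FALSE]
  te_p <- predict_p(model, te_valid)
  te_series <- phie_series(te_feat, te_p)
  decisions <- do.call(rbind, lapply(names(te_series), function(id) {
    dec <- recommend(alert_stream(te_series[[id]], policy$pt), policy)
    data.frame(subject_id = id, group = groups[[id]],
               recommended = dec$recommended,
               first_recommendation_epoch = dec$first_recommendation_epoch)
  }))

  epoch_range <- 0:(max(features$epoch_index))
  curves <- do.call(rbind, lapply(unique(decisions$group), function(g) {
    data.frame(group = g, epoch_index = epoch_range,
               rate = recommendation_curve(decisions, g, epoch_range))
  }))

  oob_tab <- cbind(model$train_ids, phie = model$oob)

  structure(list(seed = seed, n_hat = n_hat,
                 pt_hat = sel$pt, train_fpr = sel$fpr,
                 target_fpr = target_fpr,
                 auc_by_n = auc_by_n, policy = policy,
                 roc_at_n_hat = roc_at_n_hat,
                 decisions = decisions, curves = curves,
                 oob = oob_tab,
                 test_sizes = table(factor(
                   md$group[md$subject_id %in% split$test_ids], GROUPS))),
            class = "iteration_result")
}

#' Cumulative recommendation-rate curve for one group
#'
#' At epoch `k`, the fraction of the group's subjects recommended at or
#' before that time, i.e. whose first recommendation epoch is `>= k`
#' (epoch indices count backwards from delivery). The denominator is all
#' of the group's subjects, so the latched curve is non-decreasing toward
#' delivery.
#'
#' @param decisions `data.frame` with columns `subject_id`, `group`,
#'   `recommended`, `first_recommendation_epoch`.
#' @param group Group to tabulate.
#' @param epoch_range Integer vector of epoch indices.
#' @return Numeric vector of rates aligned with `epoch_range`.
#' @export
recommendation_curve <- function(decisions, group, epoch_range) {
  sub <- decisions[decisions$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no subjects in group '", group, "'")
  firsts <- sub$first_recommendation_epoch[sub$recommended]
  vapply(epoch_range, function(k) sum(firsts >= k) / nrow(sub), numeric(1))
}

#' Median with distribution-free confidence interval
#'
#' Order-statistic (binomial-rank) confidence interval for the median:
#' the interval `(x_(j), x_(k))` with `j` the `alpha/2` binomial(n, 1/2)
#' quantile and `k = n + 1 - j`, giving coverage at least `level`.
#'
#' @param values Numeric vector with at least 8 observations.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `median`, `lo`, `hi`.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("median_ci needs at least 8 values, got ", n)
  alpha <- 1 - level
  j <- stats::qbinom(alpha / 2, n, 0.5)
  if (stats::pbinom(j - 1, n, 0.5) > alpha / 2) j <- j - 1  # guard qbinom edge
  j <- max(1L, j)
  k <- n + 1L - j
  s <- sort(values)
  c(median = stats::median(s), lo = s[j], hi = s[k])
}

#' Compare iteration recommendation rates with the Caesarean rate
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the per-iteration
#' test-set recommendation rates against a fixed Caesarean rate (normal
#' approximation; exact `p = 1` when every rate equals the comparator).
#'
#' @param iteration_rates Numeric vector (>= 8) of per-iteration rates.
#' @param caesarean_rate The group's observed Caesarean rate.
#' @return The p-value.
#' @export
compare_to_caesarean <- function(iteration_rates, caesarean_rate) {
  if (length(iteration_rates) < 8) {
    stop("need at least 8 iteration rates, got ", length(iteration_rates))
  }
  if (all(iteration_rates == caesarean_rate)) return(1.0)
  suppressWarnings(
    stats::wilcox.test(iteration_rates, mu = caesarean_rate,
                       exact = FALSE)$p.value)
}

#' Median epoch-probability trajectories per group
#'
#' Pools valid epochs across subjects and reports, per group and epoch,
#' the median risk probability with its order-statistic 95% CI (CIs are
#' `NA` below 8 observations; empty cells are dropped).
#'
#' @param oob_tab `data.frame` with columns `subject_id`, `group`,
#'   `epoch_index`, `phie` (as stored on an [run_iteration()] result).
#' @param epoch_range Epoch indices to report; default all present.
#' @param min_count Minimum observations per group/epoch cell for a row to
#'   be emitted (default 1).
#' @return `data.frame(group, epoch_index, n, median, lo, hi)`.
#' @export
phie_trajectory <- function(oob_tab, epoch_range = NULL, min_count = 1) {
  tab <- oob_tab[!is.na(oob_tab$phie), , drop = FALSE]
  if (is.null(epoch_range)) epoch_range <- sort(unique(tab$epoch_index))
  out <- lapply(unique(tab$group), function(g) {
    sub <- tab[tab$group == g, , drop = FALSE]
    rows <- lapply(epoch_range, function(k) {
      v <- sub$phie[sub$epoch_index == k]
      if (length(v) < max(1, min_count)) return(NULL)
      ci <- if (length(v) >= 8) median_ci(v) else
        c(median = stats::median(v), lo = NA_real_, hi = NA_real_)
      data.frame(group = g, epoch_index = k, n = length(v),
                 median = ci[["median"]], lo = ci[["lo"]], hi = ci[["hi"]])
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(group = character(0), epoch_index = integer(0),
                      n = integer(0), median = numeric(0),
                      lo = numeric(0), hi = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Repeated random-split evaluation of the full pipeline
#'
#' Runs [run_iteration()] for `iterations` independent subject-level
#' splits (seeds derived from `seed`), featurizing the cohort once, and
#' summarizes: per-group, per-epoch median recommendation rates with 95%
#' CIs of the median; median AUC per run length; and Wilcoxon p-values
#' comparing each group's recommendation rate at selected epochs with its
#' observed Caesarean rate (computed on the full cohort).
#'
#' @param records Cohort as a list of [labor_record()] objects.
#' @param config An [eval_config()].
#' @param iterations Number of random splits (default 100).
#' @param seed Root seed.
#' @param compare_epochs Epoch indices at which rates are compared with
#'   the Caesarean rate (default `c(9, 2)`: the epochs ending 3 h and
#'   40 min before delivery).
#' @return Object of class `evaluation_summary` with fields `iterations`
#'   (list of [run_iteration()] results), `curve_summary`, `auc_summary`,
#'   `comparison`, and `caesarean_rates`.
#' @export
evaluate_cohort <- function(records, config = eval_config(),
                            iterations = 100, seed = 1L,
                            compare_epochs = c(9L, 2L)) {
  features <- featurize_cohort(records,
                               epoch_seconds = config$epoch_seconds,
                               gap_tolerance = config$gap_tolerance,
                               min_valid = config$min_valid)
  seeds <- spawn_seeds(seed, iterations)
  results <- lapply(seeds, function(s) {
    run_iteration(records, config, seed = s, features = features)
  })

  md <- cohort_metadata(records)
  caesarean_rates <- vapply(GROUPS, function(g) {
    mean(md$caesarean[md$group == g])
  }, numeric(1))

  curve_summary <- NULL
  comparison <- NULL
  if (iterations >= 8) {
    all_curves <- do.call(rbind, lapply(results, `[[`, "curves"))
    cells <- unique(all_curves[, c("group", "epoch_index")])
    curve_summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      v <- all_curves$rate[all_curves$group == cells$group[i] &
                             all_curves$epoch_index == cells$epoch_index[i]]
      ci <- median_ci(v)
      data.frame(group = cells$group[i], epoch_index = cells$epoch_index[i],
                 median = ci[["median"]], lo = ci[["lo"]], hi = ci[["hi"]])
    }))
    comparison <- do.call(rbind, lapply(GROUPS, function(g) {
      do.call(rbind, lapply(compare_epochs, function(k) {
        v <- all_curves$rate[all_curves$group == g &
                               all_curves$epoch_index == k]
        data.frame(group = g, epoch_index = k,
                   median_rate = stats::median(v),
                   caesarean_rate = caesarean_rates[[g]],
                   p_value = compare_to_caesarean(v, caesarean_rates[[g]]))
      }))
    }))
  }

  auc_mat <- do.call(rbind, lapply(results, `[[`, "auc_by_n"))
  auc_summary <- data.frame(
    n = config$n_range,
    median_auc = apply(auc_mat, 2, stats::median),
    lo = if (iterations >= 8) apply(auc_mat, 2, function(v) median_ci(v)[["lo"]]) else NA_real_,
    hi = if (iterations >= 8) apply(auc_mat, 2, function(v) median_ci(v)[["hi"]]) else NA_real_)

  structure(list(iterations = results,
                 curve_summary = curve_summary,
                 auc_summary = auc_summary,
                 comparison = comparison,
                 caesarean_rates = caesarean_rates),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  n_hats <- vapply(x$iterations, `[[`, integer(1), "n_hat")
  cat(sprintf("<evaluation_summary: %d iterations, median n_hat=%d>\n",
              length(x$iterations), as.integer(stats::median(n_hats))))
  if (!is.null(x$comparison)) {
    cat("Recommendation rate vs Caesarean rate:\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}
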