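test_that("split_cohort stratifies by group with largest-remainder counts", {
  md <- data.frame(
    subject_id = sprintf("S%03d", 1:100),
    group = rep(c("healthy", "acidosis", "HIE"), c(80, 15, 5)))
  sp <- split_cohort(md, 0.1, seed = 1)
  tg <- table(factor(md$group[md$subject_id %in% sp$test_ids],
                     c("healthy", "acidosis", "HIE")))
  expect_equal(as.vector(tg), c(8, 2, 1))

  sp2 <- split_cohort(md, 0.1, seed = 1)
  expect_identical(sp2, sp)

  for (s in 1:100) {
    spl <- split_cohort(md, 0.2, seed = s)
    expect_length(intersect(spl$train_ids, spl$test_ids), 0)
    expect_setequal(c(spl$train_ids, spl$test_ids), md$subject_id)
  }

  tiny <- data.frame(subject_id = c("A", "B", "C"),
                     group = c("healthy", "healthy", "HIE"))
  expect_error(split_cohort(tiny, 0.5, seed = 1), "at least 2")
})

test_that("median_ci reproduces the order-statistic interval", {
  expect_equal(median_ci(rep(0.5, 100)), c(median = 0.5, lo = 0.5, hi = 0.5))

  v <- 1:100
  ci <- median_ci(v)
  expect_equal(ci[["median"]], 50.5)
  # exact binomial enumeration: the largest lower rank j with
  # P(Bin(100, 1/2) < j) <= 2.5%, upper rank 100 + 1 - j
  j <- max(which(stats::pbinom(0:99, 100, 0.5) <= 0.025))
  k <- 100 + 1 - j
  expect_equal(ci[["lo"]], sort(v)[j])
  expect_equal(ci[["hi"]], sort(v)[k])
  # the interval's exact coverage is at least the nominal level
  expect_gte(stats::pbinom(k - 1, 100, 0.5) - stats::pbinom(j - 1, 100, 0.5),
             0.95)

  set.seed(30)
  for (i in 1:20) {
    x <- rnorm(sample(8:60, 1))
    ci <- median_ci(x)
    expect_lte(ci[["lo"]], ci[["median"]])
    expect_gte(ci[["hi"]], ci[["median"]])
  }
  expect_error(median_ci(1:5), "at least 8")
})

test_that("compare_to_caesarean behaves at its boundary cases", {
  expect_equal(compare_to_caesarean(rep(0.389, 50), 0.389), 1.0)
  expect_lt(compare_to_caesarean(runif(100, 0.45, 0.60), 0.389), 0.001)

  set.seed(31)
  ps <- replicate(20, compare_to_caesarean(0.389 + rnorm(60, 0, 0.05), 0.389))
  expect_gt(mean(ps), 0.05)  # symmetric about the comparator: mostly null
  expect_error(compare_to_caesarean(rep(0.5, 3), 0.389), "at least 8")
})

test_that("recommendation_curve equals a direct per-epoch recount", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    rec <- runif(n) < 0.6
    decisions <- data.frame(
      subject_id = sprintf("S%02d", 1:n),
      group = sample(c("healthy", "acidosis"), n, replace = TRUE),
      recommended = rec,
      first_recommendation_epoch = ifelse(rec, sample(0:20, n, replace = TRUE),
                                          NA_integer_))
    g <- sample(unique(decisions$group), 1)
    er <- 0:20
    expect_equal(recommendation_curve(decisions, g, er),
                 oracle_curve(decisions, g, er))
  }
  expect_error(recommendation_curve(
    data.frame(subject_id = "A", group = "healthy", recommended = FALSE,
               first_recommendation_epoch = NA_integer_),
    "HIE", 0:3), "no subjects")
})

test_that("phie_trajectory pools epochs and flags sparse cells", {
  tab <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:20), each = 3),
    group = rep(rep(c("healthy", "HIE"), each = 10), each = 3),
    epoch_index = rep(2:0, 20),
    phie = rep(0.5, 60))
  tr <- phie_trajectory(tab)
  expect_true(all(tr$median == 0.5))
  expect_true(all(tr$lo == 0.5 & tr$hi == 0.5))
  expect_equal(nrow(tr), 6)

  tr2 <- phie_trajectory(tab, min_count = 11)
  expect_equal(nrow(tr2), 0)
})

test_that("a single pipeline iteration is deterministic and leak-free", {
  cohort <- small_cohort()
  cfg <- eval_config(trees = 120)
  res <- run_iteration(cohort, cfg, seed = 77)
  res2 <- run_iteration(cohort, cfg, seed = 77)
  expect_equal(res, res2)

  # policy derives from training data only: recompute it from the stored
  # training OOB table and the frozen split
  md <- cohort_metadata(cohort)
  groups <- stats::setNames(md$group, md$subject_id)
  feats <- featurize_cohort(cohort)
  tr_feat <- feats[feats$subject_id %in% unique(res$oob$subject_id), ]
  p_all <- rep(NA_real_, nrow(tr_feat))
  p_all[tr_feat$valid] <- res$oob$phie
  series <- split(p_all, tr_feat$subject_id)[unique(tr_feat$subject_id)]
  aucs <- vapply(1:10, function(n) roc_for_n(series, groups, n)$auc, numeric(1))
  expect_equal(unname(res$auc_by_n), aucs)
  n_hat <- select_n(stats::setNames(aucs, 1:10))
  expect_identical(res$n_hat, n_hat)
  sel <- select_pt(roc_for_n(series, groups, n_hat)$roc, res$target_fpr)
  expect_equal(res$pt_hat, sel$pt)
  expect_lte(res$train_fpr, res$target_fpr)

  # no test subject appears in the training OOB table
  expect_length(intersect(unique(res$oob$subject_id),
                          unique(res$decisions$subject_id)), 0)

  # latched curves are non-decreasing toward delivery
  for (g in unique(res$curves$group)) {
    cg <- res$curves[res$curves$group == g, ]
    cg <- cg[order(-cg$epoch_index), ]
    expect_true(all(diff(cg$rate) >= 0))
  }
})

test_that("evaluate_cohort summarizes iterations with valid intervals", {
  cohort <- small_cohort()
  ev <- evaluate_cohort(cohort, eval_config(trees = 100), iterations = 8,
                        seed = 5)
  expect_length(ev$iterations, 8)
  cs <- ev$curve_summary
  expect_true(all(cs$lo <= cs$median & cs$median <= cs$hi))
  expect_true(all(cs$median >= 0 & cs$median <= 1))
  expect_equal(nrow(ev$auc_summary), 10)
  expect_true(all(ev$auc_summary$median_auc >= 0 &
                    ev$auc_summary$median_auc <= 1))
  expect_true(all(ev$comparison$p_value >= 0 & ev$comparison$p_value <= 1))
  expect_equal(unname(ev$caesarean_rates["healthy"]),
               mean(cohort_metadata(cohort)$caesarean[
                 cohort_metadata(cohort)$group == "healthy"]))
})
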