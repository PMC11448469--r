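test_that("alert_stream applies the strict threshold and propagates missing", {
  expect_identical(alert_stream(c(0.5, 0.5001, NA, 0.2), 0.5),
                   c("no-alert", "alert", "missing", "no-alert"))
  # pt = 1 never alerts; pt = 0 alerts whenever phie > 0
  expect_false(any(alert_stream(runif(50), 1) == "alert"))
  p <- runif(50, 0.01, 1)
  expect_true(all(alert_stream(p, 0) == "alert"))
  expect_error(alert_stream(c(0.5, 1.2), 0.5), "\\[0, 1\\]")
})

test_that("the consecutive-alert rule matches its worked examples", {
  pol5 <- decision_policy(5, 0.5)
  # five straight alerts: first recommendation exactly at the 5th epoch,
  # i.e. after 100 minutes of monitoring
  dec <- recommend(rep("alert", 5), pol5)
  expect_true(dec$recommended)
  expect_identical(dec$states[1:4], rep("deferred", 4))
  expect_identical(dec$states[5], "recommend")
  expect_identical(dec$first_recommendation_epoch, 0L)

  # one missing slot within budget still recommends
  dec2 <- recommend(c("alert", "alert", "missing", "alert", "alert"), pol5)
  expect_identical(dec2$states[5], "recommend")

  # three missing > floor(5/2): deferred
  dec3 <- recommend(c("alert", "missing", "missing", "missing", "alert"), pol5)
  expect_identical(dec3$states[5], "deferred")
  expect_false(dec3$recommended)

  # n = 1: a single alert recommends immediately
  dec4 <- recommend(c("no-alert", "alert"), decision_policy(1, 0.5))
  expect_identical(dec4$states, c("no-recommend", "recommend"))
  expect_identical(dec4$first_recommendation_epoch, 0L)
})

test_that("latching fixes the recommendation from the first alert run onward", {
  pol <- decision_policy(2, 0.5)
  flags <- c("alert", "alert", "no-alert", "no-alert", "alert")
  dec <- recommend(flags, pol)
  expect_identical(dec$first_recommendation_epoch, 3L)
  expect_identical(dec$states, c("deferred", rep("recommend", 4)))

  unlatched <- recommend(flags, decision_policy(2, 0.5, latch = FALSE))
  expect_identical(unlatched$states,
                   c("deferred", "recommend", "no-recommend", "no-recommend",
                     "no-recommend"))
})

test_that("roc_for_n at n = 1 equals the brute-force max-probability ranking", {
  set.seed(20)
  for (rep in 1:5) {
    n_subj <- 50
    series <- lapply(seq_len(n_subj), function(i) {
      p <- runif(sample(3:12, 1))
      p[runif(length(p)) < 0.2] <- NA
      p
    })
    names(series) <- sprintf("R%02d", seq_len(n_subj))
    groups <- stats::setNames(
      sample(c("healthy", "acidosis"), n_subj, replace = TRUE, prob = c(.7, .3)),
      names(series))
    if (length(unique(groups)) < 2) next
    res <- roc_for_n(series, groups, n = 1)
    expect_equal(res$auc,
                 oracle_auc_n1(series, groups, sort(res$roc$pt)),
                 tolerance = 1e-12)
  }
})

test_that("perfect separation and null distributions bracket the AUC", {
  series <- c(lapply(1:20, function(i) rep(1, 6)),
              lapply(1:20, function(i) rep(0, 6)))
  names(series) <- sprintf("S%02d", 1:40)
  groups <- stats::setNames(rep(c("HIE", "healthy"), each = 20), names(series))
  expect_equal(roc_for_n(series, groups, n = 3)$auc, 1.0)

  aucs <- vapply(21:23, function(s) {
    set.seed(s)
    series2 <- lapply(1:400, function(i) runif(10))
    names(series2) <- sprintf("T%03d", 1:400)
    groups2 <- stats::setNames(rep(c("healthy", "acidosis"), 200),
                               names(series2))
    roc_for_n(series2, groups2, n = 3)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
  set.seed(21)
  series2 <- lapply(1:400, function(i) runif(10))
  names(series2) <- sprintf("T%03d", 1:400)
  groups2 <- stats::setNames(rep(c("healthy", "acidosis"), 200), names(series2))

  expect_error(roc_for_n(series2, stats::setNames(rep("healthy", 400),
                                                  names(series2)), 1),
               "both a healthy and a pathological")
})

test_that("ROC sweep agrees with direct recommend() evaluation at every threshold", {
  set.seed(22)
  series <- lapply(1:60, function(i) {
    p <- runif(sample(6:15, 1))
    p[runif(length(p)) < 0.25] <- NA
    p
  })
  names(series) <- sprintf("U%02d", 1:60)
  groups <- stats::setNames(rep(c("healthy", "HIE"), 30), names(series))
  for (n in c(2, 5)) {
    res <- roc_for_n(series, groups, n = n)
    for (pt in sample(res$roc$pt, 12)) {
      rec <- vapply(series, function(p) {
        recommend(alert_stream(p, pt), decision_policy(n, pt))$recommended
      }, logical(1))
      row <- res$roc[res$roc$pt == pt, ]
      expect_equal(row$tpr, mean(rec[groups != "healthy"]))
      expect_equal(row$fpr, mean(rec[groups == "healthy"]))
    }
  }
})

test_that("ROC curves are monotone and the policy monotonicities hold", {
  set.seed(23)
  series <- lapply(1:80, function(i) runif(12))
  names(series) <- sprintf("V%02d", 1:80)
  groups <- stats::setNames(rep(c("healthy", "acidosis"), 40), names(series))
  res <- roc_for_n(series, groups, n = 4)
  # rows in decreasing pt: tpr and fpr non-decreasing
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_gte(res$auc, 0)
  expect_lte(res$auc, 1)

  # raising pt never creates a recommendation; raising n never adds subjects
  p <- series[[1]]
  for (n in c(1, 3, 6)) {
    rec_low <- recommend(alert_stream(p, 0.3), decision_policy(n, 0.3))$recommended
    rec_high <- recommend(alert_stream(p, 0.7), decision_policy(n, 0.7))$recommended
    expect_true(rec_low >= rec_high)
  }
  for (pt in c(0.2, 0.5)) {
    recs <- vapply(1:10, function(n) {
      recommend(alert_stream(p, pt), decision_policy(n, pt))$recommended
    }, logical(1))
    expect_true(all(diff(as.integer(recs)) <= 0))
  }
})

test_that("select_n maximizes AUC with ties broken toward earlier decisions", {
  expect_identical(select_n(stats::setNames(c(.6, .7, .8, .85, .9, .87, .8, .7, .6, .5), 1:10)), 5L)
  expect_identical(select_n(stats::setNames(rep(.8, 10), 1:10)), 1L)
  expect_identical(select_n(stats::setNames(0.9, 7)), 7L)
  expect_error(select_n(numeric(0)), "empty")
})

test_that("select_pt picks the most sensitive threshold within the FPR budget", {
  roc <- data.frame(pt = c(0.9, 0.7, 0.5, 0.3, 0.1),
                    fpr = c(0.05, 0.15, 0.30, 0.45, 0.80),
                    tpr = c(0.2, 0.5, 0.7, 0.85, 0.95))
  sel <- select_pt(roc, 0.389)
  expect_equal(sel$pt, 0.5)
  expect_equal(sel$fpr, 0.30)
  # tightness: the next smaller grid threshold violates the budget
  expect_gt(roc$fpr[roc$pt == 0.3], 0.389)

  expect_equal(select_pt(roc, 1.0)$pt, 0.1)
  expect_warning(sel0 <- select_pt(roc[roc$fpr > 0, ], 0), "pt = 1")
  expect_equal(sel0$pt, 1)
})
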