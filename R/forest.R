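#' Balanced bootstrap indices
#'
#' Draws, with replacement, `m` items from each class where `m` is the
#' minority class size — the per-tree sampling scheme of the balanced
#' forest (the majority class is subsampled so every tree sees an equal
#' number of observations from both classes).
#'
#' @param labels Logical or two-level factor vector.
#' @return Integer vector of `2m` in-bag indices.
#' @export
balanced_bootstrap <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(droplevels(f)) < 2) {
    stop("balanced_bootstrap needs both classes present")
  }
  idx_by_class <- split(seq_along(f), droplevels(f))
  m <- min(lengths(idx_by_class))
  unlist(lapply(idx_by_class, function(ix) {
    ix[sample.int(length(ix), m, replace = TRUE)]
  }), use.names = FALSE)
}

#' Forest training configuration
#'
#' @param trees Number of trees (default 2,500).
#' @param mtry Features tried per split (default `floor(sqrt(11))` = 3).
#' @param min_node_size Minimum terminal node size (default 1:
#'   fully grown trees).
#' @param seed Integer seed making training deterministic.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(trees = 2500, mtry = 3, min_node_size = 1,
                          seed = 1L) {
  structure(list(trees = as.integer(trees), mtry = as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train the class-balanced epoch risk forest
#'
#' Fits a random forest discriminating healthy from pathological epochs
#' (pathological = acidosis or HIE). Each tree is grown on its own
#' balanced bootstrap: `m` draws with replacement from each class, `m`
#' being the minority (pathological) epoch count, so every tree sees
#' equal class counts regardless of cohort imbalance. Only rows with
#' `valid = TRUE` enter training. Out-of-bag epoch probabilities on the
#' training set are computed at fit time (see [oob_probabilities()]) and
#' stored on the model.
#'
#' The forest is fit with \pkg{ranger} (per-class sampling fractions with
#' replacement, in-bag counts retained); probabilities are vote fractions
#' over trees, not leaf-probability averages.
#'
#' @param feature_table Output of [featurize_cohort()] (invalid rows are
#'   dropped internally).
#' @param config A [forest_config()].
#' @return Object of class `risk_model`: the fitted forest, per-tree
#'   in-bag counts, the training row identity
#'   (`subject_id`/`epoch_index`/`group`), and `oob` — the out-of-bag
#'   pathological vote fraction per training row (`NA` where no tree
#'   excluded the row).
#' @export
train_forest <- function(feature_table, config = forest_config()) {
  tab <- feature_table[feature_table$valid, , drop = FALSE]
  y <- factor(ifelse(tab$group == "healthy", "healthy", "pathological"),
              levels = c("healthy", "pathological"))
  if (any(table(y) < 2)) {
    stop("need at least 2 valid epochs in each class, got ",
         paste(table(y), collapse = "/"))
  }
  x <- tab[, FEATURE_NAMES, drop = FALSE]
  m <- min(table(y))
  n <- nrow(tab)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$trees,
    mtry = config$mtry,
    min.node.size = config$min_node_size,
    replace = TRUE,
    sample.fraction = c(m / n, m / n),
    keep.inbag = TRUE,
    seed = config$seed,
    num.threads = 1,
    verbose = FALSE)

  model <- structure(
    list(forest = fit,
         config = config,
         feature_names = FEATURE_NAMES,
         train_ids = tab[, c("subject_id", "group", "epoch_index")],
         n_train = n),
    class = "risk_model")
  model$oob <- oob_probabilities(model, feature_table)
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %d trees, %d training epochs (%d pathological), mtry=%d>\n",
              x$config$trees, x$n_train,
              sum(x$train_ids$group != "healthy"), x$config$mtry))
  invisible(x)
}

# Per-tree pathological votes for a feature matrix: n x trees matrix of
# 0/1 (1 = pathological vote).
tree_votes <- function(model, x) {
  pr <- stats::predict(model$forest, data = x, predict.all = TRUE,
                       num.threads = 1)
  # ranger returns factor-level indices; level 2 = "pathological"
  pr$predictions == 2
}

#' Out-of-bag epoch probabilities
#'
#' For each training epoch, the fraction of trees whose balanced bootstrap
#' excluded it that vote pathological. Epochs present in every tree's bag
#' have no out-of-bag estimate and are reported `NA` (they propagate to
#' the decision rule as missing epochs, they are never imputed).
#'
#' @param model A [train_forest()] model.
#' @param feature_table The exact feature table the model was trained on
#'   (checked against the stored row identity).
#' @return Numeric vector of out-of-bag pathological vote fractions, one
#'   per `valid` row of the training table.
#' @export
oob_probabilities <- function(model, feature_table) {
  tab <- feature_table[feature_table$valid, , drop = FALSE]
  if (nrow(tab) != model$n_train ||
      !identical(as.character(tab$subject_id), as.character(model$train_ids$subject_id)) ||
      !identical(as.integer(tab$epoch_index), as.integer(model$train_ids$epoch_index))) {
    stop("feature_table does not match the model's training table")
  }
  votes <- tree_votes(model, tab[, model$feature_names, drop = FALSE])
  inbag <- do.call(cbind, model$forest$inbag.counts)
  oob <- inbag == 0
  n_oob <- rowSums(oob)
  p <- rowSums(votes & oob) / n_oob
  p[n_oob == 0] <- NA_real_
  p
}

#' Predict epoch risk probabilities
#'
#' The probability that an epoch is pathological: the fraction of all
#' trees voting pathological. Rows must be valid epochs carrying all 11
#' features; invalid rows are refused.
#'
#' @param model A [train_forest()] model.
#' @param feature_rows Feature `data.frame` rows (as produced by
#'   [featurize_record()]).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_p <- function(model, feature_rows) {
  if (!all(model$feature_names %in% names(feature_rows))) {
    stop("feature_rows must carry all 11 feature columns")
  }
  if ("valid" %in% names(feature_rows) && !all(feature_rows$valid)) {
    stop("feature_rows contains invalid (flagged) epochs; filter them first")
  }
  x <- feature_rows[, model$feature_names, drop = FALSE]
  if (anyNA(x)) stop("feature_rows contains missing feature values")
  rowMeans(tree_votes(model, x))
}
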