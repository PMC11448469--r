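# Shared fixtures. The heavyweight synthetic cohorts and their pipeline
# runs are built lazily and cached, so the expensive work happens once per
# test session regardless of how many test blocks use it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A tiny clean record: 1 h, alternating BAS/DEC on FHR, CON/RIN on UP.
toy_record <- function(subject_id = "T1", group = "healthy",
                       duration = 3600, caesarean = FALSE) {
  fhr_bounds <- seq(duration, 0, by = -300)
  up_bounds <- seq(duration, 0, by = -90)
  labor_record(
    subject_id, group, duration, caesarean,
    events = rbind(
      data.frame(channel = "FHR",
                 label = rep(c("BAS", "DEC"), length.out = length(fhr_bounds) - 1),
                 start = fhr_bounds[-length(fhr_bounds)],
                 end = fhr_bounds[-1]),
      data.frame(channel = "UP",
                 label = rep(c("CON", "RIN"), length.out = length(up_bounds) - 1),
                 start = up_bounds[-length(up_bounds)],
                 end = up_bounds[-1])))
}

# Linearly separable toy feature table: pathological epochs spend the
# whole epoch decelerating (with the matching transition counts and more
# intense contractions), healthy epochs none of it.
separable_features <- function(n_healthy = 60, n_path = 30, seed = 1) {
  set.seed(seed)
  n <- n_healthy + n_path
  grp <- c(rep("healthy", n_healthy), rep("acidosis", n_path))
  path <- grp != "healthy"
  data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    group = grp, epoch_index = 0L, valid = TRUE, valid_fraction = 1,
    t_bas_acc = ifelse(path, 0, 2), t_acc_bas = ifelse(path, 0, 2),
    t_bas_dec = ifelse(path, 5, 0), t_dec_bas = ifelse(path, 5, 0),
    t_acc_dec = 0, t_dec_acc = 0,
    d_bas = ifelse(path, 0, 1200),
    d_acc = 0,
    d_dec = ifelse(path, 1200, 0),
    d_con = ifelse(path, 800, 500),
    d_rin = ifelse(path, 400, 700))
}

# Small drifted cohort for fast integration tests.
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(cohort_config(250, seed = 4182)))
}

# Study-scale drifted cohort (group dynamics at their defaults) plus its
# feature table and ten pipeline iterations at 300 trees.
accept_cohort <- function() {
  cached("accept_cohort", simulate_cohort(cohort_config(2000, seed = 20117)))
}

accept_features <- function() {
  cached("accept_features", featurize_cohort(accept_cohort()))
}

accept_iterations <- function() {
  cached("accept_iterations", {
    feats <- accept_features()
    seeds <- 101:110
    lapply(seeds, function(s) {
      run_iteration(accept_cohort(), eval_config(trees = 300), seed = s,
                    features = feats)
    })
  })
}

# Null cohort: all three groups generated from the healthy dynamics, so
# group labels carry no signal.
null_cohort <- function() {
  cached("null_cohort", {
    pars <- list(healthy = default_group_params("healthy"),
                 acidosis = default_group_params("healthy"),
                 HIE = default_group_params("healthy"))
    simulate_cohort(cohort_config(1200, params = pars, seed = 934))
  })
}

null_iterations <- function() {
  cached("null_iterations", {
    feats <- featurize_cohort(null_cohort())
    lapply(c(201, 202), function(s) {
      run_iteration(null_cohort(), eval_config(trees = 300), seed = s,
                    features = feats)
    })
  })
}
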