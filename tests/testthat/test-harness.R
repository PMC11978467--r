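make_signal_data <- function(n_patients = 60, lesions_each = 2, d = 2,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_patients * lesions_each
    patients <- rep(sprintf("P%03d", seq_len(n_patients)),
                    each = lesions_each)
    y <- runif(n) < 0.4
    x <- tibble::tibble(
      s1 = rnorm(n) + d * y,
      s2 = rnorm(n) + 0.5 * d * y,
      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    list(x = x, y = y, patients = patients)
  })
}

test_that("bootstrap splits are reproducible, disjoint and patient-coherent", {
  patients <- rep(sprintf("P%02d", 1:20), times = rep(c(1, 2, 3), length.out = 20))
  s1 <- bootstrap_split(patients, seed = 5)
  s2 <- bootstrap_split(patients, seed = 5)
  expect_identical(s1, s2)
  expect_length(intersect(unique(s1$train_rows), s1$test_rows), 0)
  expect_setequal(c(unique(s1$train_rows), s1$test_rows),
                  seq_along(patients))
  # every patient is fully on one side
  split_side <- tapply(seq_along(patients) %in% s1$test_rows, patients,
                       function(v) length(unique(v)))
  expect_true(all(split_side == 1))
  expect_false(identical(s1$test_rows,
                         bootstrap_split(patients, seed = 6)$test_rows))
})

test_that("the mean out-of-bag fraction approaches the bootstrap limit", {
  # (1 - 1/P)^P -> e^-1; at P = 100 the exact expectation is 36.6%
  patients <- sprintf("P%03d", 1:100)
  fr <- vapply(1:200, function(i) {
    bootstrap_split(patients, seed = i)$test_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 100 * (1 - 1 / 100)^100), 1.5)
})

test_that("the correlation filter applies the greedy keep-first rule", {
  withr::with_seed(11, {
    z <- rnorm(500)
    x <- tibble::tibble(
      a = z,
      b = z + rnorm(500, 0, 0.1),     # r ~ 0.995 with a: dropped
      c = rnorm(500),                  # independent: kept
      d = rep(1, 500))                 # zero variance: dropped
    kept <- correlation_filter(x, cutoff = 0.8)
    expect_equal(kept, c(1, 3))
    # three mutually ~0.9-correlated columns collapse to the first
    w <- rnorm(2000)
    trio <- tibble::tibble(
      p = sqrt(0.9) * w + sqrt(0.1) * rnorm(2000),
      q = sqrt(0.9) * w + sqrt(0.1) * rnorm(2000),
      r = sqrt(0.9) * w + sqrt(0.1) * rnorm(2000))
    expect_equal(correlation_filter(trio, cutoff = 0.8), 1)
    # independent columns all survive
    ind <- tibble::as_tibble(matrix(rnorm(1000 * 5), 1000, 5),
                             .name_repair = "minimal")
    expect_length(correlation_filter(ind, cutoff = 0.8), 5)
  })
})

test_that("hyperparameter search stays in bounds and finds separable data", {
  withr::with_seed(13, {
    n <- 40
    y <- rep(c(TRUE, FALSE), n / 2)
    x <- tibble::tibble(a = ifelse(y, 2, -2) + rnorm(n, 0, 0.1),
                        b = rnorm(n))
    tuned <- tune_hyperparameters(x, y, budget = 6, folds = 5, seed = 2)
    expect_gte(tuned$n_trees, 10)
    expect_lte(tuned$n_trees, 1000)
    expect_gte(tuned$max_depth, 1)
    expect_lte(tuned$max_depth, n)
    expect_equal(tuned$cv_auc, 1)
    expect_equal(nrow(tuned$history), 6)
    # budget 1: the single evaluated point is returned
    t1 <- tune_hyperparameters(x, y, budget = 1, seed = 3)
    expect_equal(nrow(t1$history), 1)
    expect_equal(t1$n_trees, t1$history$n_trees[1])
    expect_error(tune_hyperparameters(x, rep(TRUE, n)))
  })
})

test_that("forest fits are deterministic and expose importance", {
  dat <- make_signal_data(seed = 21)
  hp <- list(n_trees = 100, max_depth = NULL)
  f1 <- fit_forest(dat$x, dat$y, hp, seed = 7)
  f2 <- fit_forest(dat$x, dat$y, hp, seed = 7)
  p1 <- predict_forest(f1, dat$x)
  expect_identical(p1, predict_forest(f2, dat$x))
  expect_length(f1$importance, ncol(dat$x))
  # memorisation: training AUC is (near) perfect on strong signal
  expect_gt(roc_auc(p1, dat$y), 0.99)
  xx <- dat$x; xx$s1[1] <- NA
  expect_error(fit_forest(xx, dat$y, hp))
})

test_that("no training artifact depends on the test rows", {
  dat <- make_signal_data(seed = 31)
  split <- bootstrap_split(dat$patients, seed = 4)
  res1 <- evaluate_split(dat$x, dat$y, split, tune_budget = 3, seed = 9)
  # permute the test rows' features: filter, hyperparameters, threshold and
  # importances must be bit-identical
  x2 <- as.data.frame(dat$x)
  perm <- withr::with_seed(1, sample(split$test_rows))
  x2[split$test_rows, ] <- x2[perm, ]
  res2 <- evaluate_split(x2, dat$y, split, tune_budget = 3, seed = 9)
  expect_identical(res1$kept, res2$kept)
  expect_identical(res1$hyperparams, res2$hyperparams)
  expect_identical(res1$metrics$threshold, res2$metrics$threshold)
  expect_identical(res1$importance, res2$importance)
})

test_that("experiments aggregate means with well-ordered CIs, reproducibly", {
  dat <- make_signal_data(seed = 41)
  ex1 <- run_experiment(dat$x, dat$y, dat$patients, n_iterations = 6,
                        seed = 3, tune_budget = 0, n_trees = 60)
  ex2 <- run_experiment(dat$x, dat$y, dat$patients, n_iterations = 6,
                        seed = 3, tune_budget = 0, n_trees = 60)
  expect_identical(ex1$summary, ex2$summary)
  expect_true(all(ex1$summary$ci_low <= ex1$summary$mean &
                    ex1$summary$mean <= ex1$summary$ci_high))
  expect_equal(nrow(ex1$iterations), 6)
  expect_true(all(ex1$iterations$auc >= 0 & ex1$iterations$auc <= 1))
  expect_error(run_experiment(dat$x, rep(TRUE, length(dat$y)),
                              dat$patients, n_iterations = 2))
  # tidiers
  td <- tidy(ex1)
  expect_identical(td$metric, c("auc", "auprc", "sensitivity", "specificity"))
  gl <- glance(ex1)
  expect_equal(gl$n_iterations, 6)
  expect_true(gl$mean_test_fraction > 10 & gl$mean_test_fraction < 70)
})

test_that("importance aggregation follows zero/min-max/mean/renormalise", {
  # single iteration, nothing filtered: plain min-max
  expect_equal(aggregate_importance(matrix(c(2, 4, 6), 1)), c(0, 0.5, 1))
  # a feature filtered in every iteration scores zero
  m <- rbind(c(NA, 1, 3), c(NA, 2, 8))
  agg <- aggregate_importance(m)
  expect_equal(agg[1], 0)
  expect_equal(agg[3], 1)
  # hand computation: rows normalise to (0,0,1) and (0,0,1)... general case
  m2 <- rbind(c(2, 4, 6), c(3, NA, 9))
  # row 1 -> (0, .5, 1); row 2 -> (0, 0, 1); mean (0, .25, 1); range already
  # [0,1] so renormalisation is identity
  expect_equal(aggregate_importance(m2), c(0, 0.25, 1))
  # anti-symmetric iterations average to a constant: renormalised to zeros
  expect_equal(aggregate_importance(rbind(c(0, 1), c(1, 0))), c(0, 0))
})

test_that("pooled subgroup metrics behave like the whole-set pooling", {
  dat <- make_signal_data(n_patients = 40, seed = 51)
  ex <- run_experiment(dat$x, dat$y, dat$patients, n_iterations = 8,
                       seed = 5, tune_budget = 0, n_trees = 60)
  whole <- subgroup_pooled_metrics(ex, rep("all", length(dat$y)))
  expect_equal(nrow(whole), 1)
  tp <- ex$test_probs
  expect_equal(whole$auc, roc_auc(tp$prob, tp$label))
  expect_equal(whole$baseline_auprc, mean(tp$label))
  # a single-class group reports NA, not an error
  grp <- ifelse(dat$y, "mixed", "mixed")
  grp[which(!dat$y)[1:2]] <- "pure"  # a tiny all-negative group
  sub <- subgroup_pooled_metrics(ex, grp)
  pure_row <- sub[sub$group == "pure", ]
  if (nrow(pure_row) == 1 && pure_row$baseline_auprc == 0) {
    expect_true(is.na(pure_row$auc))
  }
})
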