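# Bootstrap out-of-bag evaluation harness: patient-level resampling,
# correlation-based feature filtering on the training rows only, Bayesian
# hyperparameter search, random-forest fitting, test metrics at a
# training-chosen operating point, and importance aggregation.

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 1e6) * 2039 + i * 7919) %% 2147483629L + 1L
}

#' Draw one bootstrap-with-resampling train/test split
#'
#' Units (patients by default, so all of a patient's lesions travel together)
#' are sampled with replacement as many times as there are units; the
#' training multiset is the lesions of the sampled units with multiplicity
#' and the test set is the lesions of the never-sampled (out-of-bag) units.
#'
#' @param patients Character/factor vector, one unit id per lesion row.
#' @param seed Integer seed.
#' @param unit `"patient"` (default) or `"lesion"` (each row its own unit).
#'
#' @return A list of class `bootstrap_split` with `train_rows` (row indices
#'   with multiplicity), `test_rows` (out-of-bag row indices) and
#'   `test_fraction` (percent of lesions out of bag).
#' @export
bootstrap_split <- function(patients, seed, unit = c("patient", "lesion")) {
  unit <- match.arg(unit)
  ids <- if (unit == "patient") as.character(patients) else
    as.character(seq_along(patients))
  uniq <- unique(ids)
  stopifnot(length(uniq) >= 2)
  withr::local_seed(seed)
  drawn <- sample(uniq, length(uniq), replace = TRUE)
  row_of <- split(seq_along(ids), factor(ids, levels = uniq))
  train_rows <- unlist(row_of[drawn], use.names = FALSE)
  oob <- setdiff(uniq, drawn)
  test_rows <- sort(unlist(row_of[oob], use.names = FALSE))
  structure(list(train_rows = train_rows, test_rows = test_rows,
                 test_fraction = 100 * length(test_rows) / length(ids)),
            class = "bootstrap_split")
}

#' Greedy correlation-based feature filter
#'
#' Scans features in their fixed column order and keeps a feature iff its
#' absolute Pearson correlation with every already-kept feature is at most
#' `cutoff` (computed on the supplied training rows only). Zero-variance
#' features are dropped first, their correlation being undefined.
#'
#' @param train_features Data frame or matrix of numeric features (training
#'   rows only).
#' @param cutoff Absolute correlation cutoff (default 0.8).
#' @return Integer vector of retained column indices.
#' @export
correlation_filter <- function(train_features, cutoff = 0.8) {
  x <- as.matrix(train_features)
  stopifnot(nrow(x) >= 2)
  variances <- apply(x, 2, var)
  candidates <- which(variances > 0)
  if (length(candidates) == 0) return(integer(0))
  cm <- abs(suppressWarnings(cor(x[, candidates, drop = FALSE])))
  kept_local <- integer(0)
  for (k in seq_along(candidates)) {
    if (all(cm[k, kept_local] <= cutoff)) {
      kept_local <- c(kept_local, k)
    }
  }
  unname(candidates[kept_local])
}

cv_auc <- function(x, y, n_trees, max_depth, folds, seed) {
  withr::local_seed(seed)
  n <- length(y)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  probs <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- fit_forest(x[tr, , drop = FALSE], y[tr],
                      list(n_trees = n_trees, max_depth = max_depth),
                      seed = seed + f)
    probs[!tr] <- predict_forest(fit, x[!tr, , drop = FALSE])
  }
  if (length(unique(y)) < 2) return(NA_real_)
  roc_auc(probs, y)
}

#' Bayesian search for random-forest hyperparameters
#'
#' Maximises an inner cross-validated AUC on the training data over the
#' number of trees (10--1000, log scale) and the maximum tree depth (1 to
#' the training-set size). After a Latin-hypercube initial design, a
#' Gaussian-process surrogate (RBF kernel) proposes each next point by
#' expected improvement over a random candidate pool; if the surrogate is
#' numerically singular the point falls back to random search. Test rows are
#' never seen.
#'
#' @param x Training feature matrix/data frame (filtered columns).
#' @param y Logical training outcomes (both classes present).
#' @param n_trees_range,max_depth_range Search bounds; the depth upper bound
#'   is capped at `nrow(x)`.
#' @param budget Total number of evaluated points (default 25).
#' @param folds Inner CV folds (default 5).
#' @param seed Integer seed.
#'
#' @return A list with `n_trees`, `max_depth`, `cv_auc` and the evaluation
#'   `history` tibble.
#' @export
tune_hyperparameters <- function(x, y, n_trees_range = c(10, 1000),
                                 max_depth_range = c(1, nrow(x)),
                                 budget = 25, folds = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  stopifnot(budget >= 1)
  depth_max <- min(max_depth_range[2], nrow(x))
  folds <- min(folds, min(table(y)))
  folds <- max(folds, 2)

  to_params <- function(u) {
    # u in [0,1]^2 -> (trees on log scale, depth linear)
    n_trees <- round(exp(log(n_trees_range[1]) +
                           u[1] * log(n_trees_range[2] / n_trees_range[1])))
    depth <- max(1, round(max_depth_range[1] +
                            u[2] * (depth_max - max_depth_range[1])))
    list(n_trees = as.integer(n_trees), max_depth = as.integer(depth))
  }

  withr::local_seed(derive_seed(seed, 17L))
  n_init <- min(budget, max(4, budget %/% 3))
  u_hist <- lhs::randomLHS(n_init, 2)
  if (budget == 1) u_hist <- matrix(runif(2), 1)
  scores <- rep(NA_real_, 0)
  for (r in seq_len(nrow(u_hist))) {
    pr <- to_params(u_hist[r, ])
    scores[r] <- cv_auc(x, y, pr$n_trees, pr$max_depth, folds,
                        derive_seed(seed, 100L + r))
  }
  while (nrow(u_hist) < budget) {
    r <- nrow(u_hist) + 1
    cand <- matrix(runif(2 * 128), ncol = 2)
    u_next <- gp_propose(u_hist, scores, cand)
    pr <- to_params(u_next)
    u_hist <- rbind(u_hist, u_next)
    scores[r] <- cv_auc(x, y, pr$n_trees, pr$max_depth, folds,
                        derive_seed(seed, 100L + r))
  }
  ok <- which(!is.na(scores))
  if (length(ok) == 0) {
    best_u <- c(0.5, 1)  # default: mid-size forest, unrestricted depth
  } else {
    best_u <- u_hist[ok[which.max(scores[ok])], ]
  }
  best <- to_params(best_u)
  hist_tbl <- tibble::tibble(
    n_trees = vapply(seq_len(nrow(u_hist)),
                     function(r) to_params(u_hist[r, ])$n_trees, integer(1)),
    max_depth = vapply(seq_len(nrow(u_hist)),
                       function(r) to_params(u_hist[r, ])$max_depth,
                       integer(1)),
    cv_auc = scores)
  list(n_trees = best$n_trees, max_depth = best$max_depth,
       cv_auc = if (length(ok)) max(scores[ok]) else NA_real_,
       history = hist_tbl)
}

# GP-EI proposal; falls back to a random candidate if the kernel matrix is
# numerically singular or there is nothing to learn from yet
gp_propose <- function(u_hist, scores, cand) {
  ok <- !is.na(scores)
  if (sum(ok) < 3 || sd(scores[ok]) == 0) {
    return(cand[sample.int(nrow(cand), 1), ])
  }
  X <- u_hist[ok, , drop = FALSE]
  y <- scale(scores[ok])[, 1]
  ell <- 0.3
  k <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    exp(-pmax(d2, 0) / (2 * ell^2))
  }
  K <- k(X, X) + diag(1e-4 + 1e-2, nrow(X))
  Kinv <- tryCatch(solve(K), error = function(e) NULL)
  if (is.null(Kinv)) return(cand[sample.int(nrow(cand), 1), ])
  Ks <- k(cand, X)
  mu <- as.vector(Ks %*% Kinv %*% y)
  var_c <- pmax(1 - rowSums((Ks %*% Kinv) * Ks), 1e-10)
  sd_c <- sqrt(var_c)
  best <- max(y)
  z <- (mu - best) / sd_c
  ei <- sd_c * (z * pnorm(z) + dnorm(z))
  cand[which.max(ei), ]
}

#' Fit a random decision forest
#'
#' A probability forest honouring the tuned tree count and depth cap,
#' deterministic under its seed.
#'
#' @param x Feature matrix/data frame.
#' @param y Logical outcomes.
#' @param hyperparams List with `n_trees` and `max_depth` (`NULL`/`Inf` depth
#'   means unrestricted).
#' @param seed Integer seed.
#' @return A fitted model (class `srs_forest`) usable with
#'   [predict_forest()]; permutation importances in `$importance`.
#' @export
fit_forest <- function(x, y, hyperparams, seed = 1L) {
  x <- as.data.frame(x)
  if (any(!is.finite(as.matrix(x)))) {
    stop("non-finite feature values", call. = FALSE)
  }
  y <- factor(as.logical(y), levels = c(FALSE, TRUE))
  depth <- hyperparams$max_depth
  if (is.null(depth) || !is.finite(depth)) depth <- 0  # unrestricted
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = hyperparams$n_trees,
    max.depth = depth,
    probability = TRUE,
    importance = "permutation",
    seed = seed,
    num.threads = 1
  )
  structure(list(fit = fit, importance = fit$variable.importance,
                 features = colnames(x)),
            class = "srs_forest")
}

#' Predict progression probabilities from a fitted forest
#' @param model A [fit_forest()] result.
#' @param x New feature rows (same columns).
#' @return Numeric vector of failure-class probabilities.
#' @export
predict_forest <- function(model, x) {
  stopifnot(inherits(model, "srs_forest"))
  p <- predict(model$fit, data = as.data.frame(x),
               num.threads = 1)$predictions
  p[, "TRUE"]
}

#' Evaluate one bootstrap split end to end
#'
#' Filters features, optionally tunes hyperparameters, fits the forest and
#' chooses the operating point -- all strictly on the training multiset --
#' then scores the out-of-bag test lesions. This is the unit of work that
#' [run_experiment()] repeats.
#'
#' @param features Numeric feature data frame (one row per lesion).
#' @param labels Logical outcomes (TRUE = treatment failure).
#' @param split A [bootstrap_split()].
#' @param correlation_cutoff Filter cutoff (default 0.8).
#' @param tune_budget Evaluations for [tune_hyperparameters()]; 0 skips
#'   tuning and uses `n_trees`/`max_depth` as given.
#' @param tune_folds Inner CV folds when tuning.
#' @param n_trees,max_depth Hyperparameters used when not tuning.
#' @param seed Integer seed for tuning and fitting.
#'
#' @return A list with `metrics` (one-row tibble: auc, auprc, sensitivity,
#'   specificity, threshold, test_fraction), `importance` (full-length raw
#'   vector, `NA` at filtered features), `kept` (filtered-in column indices),
#'   `hyperparams`, and `test_probs` (tibble row/prob/label).
#' @export
evaluate_split <- function(features, labels, split,
                           correlation_cutoff = 0.8,
                           tune_budget = 0, tune_folds = 5,
                           n_trees = 300, max_depth = NULL, seed = 1L) {
  stopifnot(inherits(split, "bootstrap_split"))
  x_all <- as.matrix(features)
  y <- as.logical(labels)
  tr <- split$train_rows
  te <- split$test_rows
  if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
    stop("degenerate split: a class is missing", call. = FALSE)
  }
  kept <- correlation_filter(x_all[tr, , drop = FALSE], correlation_cutoff)
  x_tr <- x_all[tr, kept, drop = FALSE]
  x_te <- x_all[te, kept, drop = FALSE]

  hp <- if (tune_budget > 0) {
    tuned <- tune_hyperparameters(x_tr, y[tr], budget = tune_budget,
                                  folds = tune_folds, seed = seed)
    list(n_trees = tuned$n_trees, max_depth = tuned$max_depth)
  } else {
    list(n_trees = n_trees, max_depth = max_depth)
  }
  model <- fit_forest(x_tr, y[tr], hp, seed = seed)
  train_probs <- predict_forest(model, x_tr)
  threshold <- training_operating_point(train_probs, y[tr])
  test_probs <- predict_forest(model, x_te)
  ss <- sens_spec_at(test_probs, y[te], threshold)

  imp <- rep(NA_real_, ncol(x_all))
  imp[kept] <- unname(model$importance)
  list(
    metrics = tibble::tibble(
      auc = roc_auc(test_probs, y[te]),
      auprc = au_prc(test_probs, y[te]),
      sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]],
      threshold = threshold,
      test_fraction = split$test_fraction),
    importance = imp,
    kept = kept,
    hyperparams = hp,
    test_probs = tibble::tibble(row = te, prob = test_probs, label = y[te])
  )
}

#' Aggregate per-iteration feature importances
#'
#' Per iteration: filtered-out features (NA) get importance 0 and the
#' surviving features are min-max normalised to \[0, 1\]; the per-iteration
#' vectors are then averaged and the average min-max normalised again. A
#' constant aggregate (nothing to rank) renormalises to all zeros.
#'
#' @param importance_matrix Iterations x features matrix of raw importances
#'   with `NA` at filtered features.
#' @return Numeric vector of length `ncol(importance_matrix)` in \[0, 1\].
#' @export
aggregate_importance <- function(importance_matrix) {
  m <- as.matrix(importance_matrix)
  stopifnot(nrow(m) >= 1)
  norm_row <- function(r) {
    out <- rep(0, length(r))
    ok <- !is.na(r)
    if (any(ok)) {
      rng <- range(r[ok])
      out[ok] <- if (rng[2] > rng[1]) (r[ok] - rng[1]) / (rng[2] - rng[1])
      else 0
    }
    out
  }
  avg <- colMeans(t(apply(m, 1, norm_row)))
  rng <- range(avg)
  if (rng[2] > rng[1]) (avg - rng[1]) / (rng[2] - rng[1]) else rep(0, length(avg))
}

#' Run a full bootstrap experiment
#'
#' Repeats [evaluate_split()] over `n_iterations` bootstrap splits and
#' aggregates: mean and normal-approximation 95% CI of each test metric
#' across iterations, the mean out-of-bag test fraction, the aggregated
#' importance vector, and the pooled per-lesion test probabilities. Splits in
#' which a class is missing from the training or test partition are redrawn
#' with a fresh derived seed (and counted in `n_redrawn`).
#'
#' @inheritParams evaluate_split
#' @param patients Unit ids per lesion row (see [bootstrap_split()]).
#' @param n_iterations Number of bootstrap iterations (default 250).
#' @param seed Master seed; per-iteration seeds are derived from it so any
#'   iteration can be replayed independently.
#' @param unit Bootstrap unit, `"patient"` or `"lesion"`.
#' @param max_redraws Redraw attempts per iteration before giving up.
#'
#' @details The default `tune_budget = 25` re-tunes hyperparameters in every
#'   iteration and dominates the runtime; set `tune_budget = 0` with explicit
#'   `n_trees`/`max_depth` for quick, fixed-configuration experiments.
#'
#' @return An object of class `bm_experiment`: list with `summary` (tibble of
#'   metric, mean, ci_low, ci_high), `iterations` (per-iteration metrics),
#'   `aggregated_importance`, `importance_matrix`, `test_probs` (pooled),
#'   `mean_test_fraction`, `n_redrawn`, `feature_names`.
#' @export
run_experiment <- function(features, labels, patients,
                           n_iterations = 250, seed = 1L,
                           unit = c("patient", "lesion"),
                           correlation_cutoff = 0.8,
                           tune_budget = 25, tune_folds = 5,
                           n_trees = 300, max_depth = NULL,
                           max_redraws = 25) {
  unit <- match.arg(unit)
  y <- as.logical(labels)
  stopifnot(nrow(features) == length(y), length(patients) == length(y))
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; experiment is degenerate",
         call. = FALSE)
  }
  iters <- vector("list", n_iterations)
  imp <- matrix(NA_real_, n_iterations, ncol(features))
  probs_list <- vector("list", n_iterations)
  n_redrawn <- 0L
  for (i in seq_len(n_iterations)) {
    res <- NULL
    for (attempt in 0:max_redraws) {
      it_seed <- derive_seed(seed, i * 1000L + attempt)
      split <- bootstrap_split(patients, it_seed, unit)
      res <- tryCatch(
        evaluate_split(features, y, split,
                       correlation_cutoff = correlation_cutoff,
                       tune_budget = tune_budget, tune_folds = tune_folds,
                       n_trees = n_trees, max_depth = max_depth,
                       seed = it_seed),
        error = function(e) {
          if (grepl("degenerate split", conditionMessage(e))) NULL else stop(e)
        })
      if (!is.null(res)) {
        if (attempt > 0) n_redrawn <- n_redrawn + 1L
        break
      }
    }
    if (is.null(res)) {
      stop("could not draw a non-degenerate split after ", max_redraws,
           " attempts", call. = FALSE)
    }
    iters[[i]] <- dplyr::mutate(res$metrics, iteration = i,
                                iteration_seed = it_seed,
                                n_trees = res$hyperparams$n_trees,
                                max_depth = res$hyperparams$max_depth %||% NA)
    imp[i, ] <- res$importance
    probs_list[[i]] <- dplyr::mutate(res$test_probs, iteration = i)
  }
  iterations <- dplyr::bind_rows(iters)
  metric_cols <- c("auc", "auprc", "sensitivity", "specificity")
  summary <- purrr::map_dfr(metric_cols, function(mc) {
    v <- iterations[[mc]]
    se <- sd(v) / sqrt(length(v))
    tibble::tibble(metric = mc, mean = mean(v),
                   ci_low = mean(v) - 1.96 * se,
                   ci_high = mean(v) + 1.96 * se)
  })
  structure(list(
    summary = summary,
    iterations = iterations,
    aggregated_importance = aggregate_importance(imp),
    importance_matrix = imp,
    test_probs = dplyr::bind_rows(probs_list),
    mean_test_fraction = mean(iterations$test_fraction),
    n_redrawn = n_redrawn,
    feature_names = colnames(features),
    n_iterations = n_iterations,
    seed = seed
  ), class = "bm_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bm_experiment <- function(x, ...) {
  cat("<bm_experiment> ", x$n_iterations, " iterations, mean test fraction ",
      sprintf("%.1f%%", x$mean_test_fraction), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Pooled subgroup metrics over all bootstrap iterations
#'
#' Gathers every test-set probability over all iterations, groups the pooled
#' set by a per-lesion key (e.g. primary cancer site) and computes AUC,
#' AU-PRC, baseline AU-PRC, sensitivity and specificity per group (the
#' pooled threshold is the median of the per-iteration operating points).
#' A group whose pooled set contains a single class reports `NA` metrics.
#'
#' @param experiment A [run_experiment()] result.
#' @param group Vector of group keys, one per lesion row of the original
#'   feature table.
#' @return A tibble with one row per group.
#' @export
subgroup_pooled_metrics <- function(experiment, group) {
  stopifnot(inherits(experiment, "bm_experiment"))
  tp <- experiment$test_probs
  tp$group <- group[tp$row]
  threshold <- stats::median(experiment$iterations$threshold)
  tp |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      ok <- length(unique(d$label)) == 2
      ss <- if (ok) sens_spec_at(d$prob, d$label, threshold) else
        c(sensitivity = NA_real_, specificity = NA_real_)
      tibble::tibble(
        n_probs = nrow(d),
        auc = if (ok) roc_auc(d$prob, d$label) else NA_real_,
        auprc = if (ok) au_prc(d$prob, d$label) else NA_real_,
        baseline_auprc = baseline_auprc(d$label),
        sensitivity = ss[["sensitivity"]],
        specificity = ss[["specificity"]])
    }) |>
    dplyr::ungroup()
}
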