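# Benchmarking protocol: repeated 10-fold cross-validation under three
# blinding regimes, AUC/AUPR scoring, grid search and paired significance
# testing.
#
#   CVS1 blinds random entries of Y  -> prediction for new pairs,
#   CVS2 blinds whole drug rows      -> prediction for new drugs,
#   CVS3 blinds whole target columns -> prediction for new targets.

#' Build repeated cross-validation splits
#'
#' Partitions the evaluation units (matrix entries for `cvs1`, drug rows for
#' `cvs2`, target columns for `cvs3`) into `n_folds` folds of sizes
#' differing by at most one, independently for each of `n_repeats` repeats.
#' Repeat `k` is seeded with `seed + k - 1`, so the whole split is
#' deterministic given `seed`.
#'
#' @param ds a `dti_dataset`.
#' @param setting `"cvs1"`, `"cvs2"` or `"cvs3"`.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 5).
#' @param seed master seed.
#' @return an object of class `cv_split`: list of repeats, each a list of
#'   integer unit-index vectors (entry indices into `Y` for cvs1, row or
#'   column indices otherwise).
#' @export
make_cv_splits <- function(ds, setting = c("cvs1", "cvs2", "cvs3"),
                           n_folds = 10, n_repeats = 5, seed = 1L) {
  setting <- match.arg(setting)
  m <- nrow(ds$Y); n <- ncol(ds$Y)
  n_units <- switch(setting, cvs1 = m * n, cvs2 = m, cvs3 = n)
  if (n_folds > n_units) {
    stop_validation("cannot make %d folds from %d %s units", n_folds, n_units, setting)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  repeats <- lapply(seq_len(n_repeats), function(k) {
    set.seed(seed + k - 1L)
    perm <- sample.int(n_units)
    fold_of <- rep_len(seq_len(n_folds), n_units)
    unname(split(perm, fold_of))
  })
  structure(list(setting = setting, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 repeats = repeats),
            class = "cv_split")
}

#' Mask the test units of one fold out of the training data
#'
#' Returns a training dataset whose blinded entries are set to zero
#' (unknown), together with the test pairs and their true labels. Under
#' `cvs1` only the selected entries are blinded; under `cvs2`/`cvs3` every
#' entry of the selected rows/columns is blinded and the test set is all
#' pairs in those rows/columns.
#'
#' @param ds a `dti_dataset`.
#' @param split a `cv_split`.
#' @param rep,fold coordinates of the fold to hold out.
#' @return list with `train` (a `dti_dataset`), `test_pairs` (two-column
#'   integer matrix of drug/target indices) and `test_labels`.
#' @export
mask_training <- function(ds, split, rep, fold) {
  stopifnot(inherits(split, "cv_split"))
  if (rep < 1 || rep > split$n_repeats || fold < 1 || fold > split$n_folds) {
    stop_validation("fold coordinates out of range")
  }
  units <- split$repeats[[rep]][[fold]]
  Y <- ds$Y
  m <- nrow(Y)
  if (split$setting == "cvs1") {
    pairs <- arrayInd(units, dim(Y))
  } else if (split$setting == "cvs2") {
    pairs <- as.matrix(expand.grid(drug = units, target = seq_len(ncol(Y))))
  } else {
    pairs <- as.matrix(expand.grid(drug = seq_len(m), target = units))
  }
  colnames(pairs) <- c("drug", "target")
  labels <- Y[pairs]
  Y_train <- Y
  Y_train[pairs] <- 0
  train <- ds
  train$Y <- Y_train
  list(train = train, test_pairs = pairs, test_labels = labels)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_validation("scores and labels differ in length")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop_validation("AUC undefined: need at least one positive and one negative label")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average precision with step interpolation: sweeping the decision
#' threshold down the distinct score values, `sum_k (R_k - R_{k-1}) * P_k`
#' with precision `P_k` and recall `R_k` at each threshold. Step
#' interpolation avoids the over-optimism of trapezoidal interpolation on
#' PR curves.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_validation("scores and labels differ in length")
  np <- sum(labels == 1)
  if (np == 0) stop_validation("AUPR undefined: no positive labels")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # thresholds sit at the last element of each tie group of scores
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_group]; fp <- fp[last_of_group]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Cross-validate an NRLMF configuration
#'
#' For every repeat and fold: blind the fold, rebuild neighborhoods and
#' train on the masked data, score the held-out pairs with the cold-start
#' smoothed predictor, and compute AUC and AUPR. Folds whose test labels
#' are single-class are skipped with a warning and excluded from
#' aggregation.
#'
#' @param ds a `dti_dataset`.
#' @param hyper an [nrlmf_hyperparams()].
#' @param setting blinding regime, see [make_cv_splits()].
#' @param split optional precomputed `cv_split`; built from the remaining
#'   arguments when `NULL`.
#' @param n_folds,n_repeats,seed passed to [make_cv_splits()] when `split`
#'   is `NULL`.
#' @param aggregate `"per_fold"` (default) computes one AUC/AUPR per fold
#'   and averages across all folds and repeats; `"pooled"` concatenates the
#'   scores of all folds within a repeat and computes one value per repeat.
#' @return an object of class `nrlmf_cv`: `fold_metrics` tibble (`repeat_`,
#'   `fold`, `auc`, `aupr`), `summary` tibble (mean and sd per metric),
#'   the hyperparameters and the split.
#' @export
cross_validate <- function(ds, hyper = nrlmf_hyperparams(),
                           setting = c("cvs1", "cvs2", "cvs3"),
                           split = NULL, n_folds = 10, n_repeats = 5,
                           seed = 1L,
                           aggregate = c("per_fold", "pooled")) {
  setting <- match.arg(setting)
  aggregate <- match.arg(aggregate)
  if (is.null(split)) {
    split <- make_cv_splits(ds, setting, n_folds, n_repeats, seed)
  }
  rows <- list()
  pooled <- list()
  for (k in seq_len(split$n_repeats)) {
    rep_scores <- numeric(0); rep_labels <- numeric(0)
    for (f in seq_len(split$n_folds)) {
      fold_data <- mask_training(ds, split, k, f)
      model <- nrlmf(fold_data$train, hyper)
      P <- predict(model)
      sc <- P[fold_data$test_pairs]
      lb <- fold_data$test_labels
      rep_scores <- c(rep_scores, sc); rep_labels <- c(rep_labels, lb)
      if (length(unique(lb)) < 2) {
        warning(sprintf("repeat %d fold %d has single-class test labels; skipped", k, f))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = k, fold = f, auc = auc_score(sc, lb), aupr = aupr_score(sc, lb))
    }
    pooled[[k]] <- tibble::tibble(
      repeat_ = k, fold = NA_integer_,
      auc = if (length(unique(rep_labels)) < 2) NA_real_ else auc_score(rep_scores, rep_labels),
      aupr = if (sum(rep_labels) == 0) NA_real_ else aupr_score(rep_scores, rep_labels))
  }
  fold_metrics <- if (aggregate == "per_fold") {
    dplyr::bind_rows(rows)
  } else {
    dplyr::bind_rows(pooled)
  }
  summary <- tibble::tibble(
    metric = c("auc", "aupr"),
    mean = c(mean(fold_metrics$auc, na.rm = TRUE), mean(fold_metrics$aupr, na.rm = TRUE)),
    sd = c(stats::sd(fold_metrics$auc, na.rm = TRUE), stats::sd(fold_metrics$aupr, na.rm = TRUE)))
  structure(list(setting = setting, aggregate = aggregate,
                 fold_metrics = fold_metrics, summary = summary,
                 hyper = hyper, split = split),
            class = "nrlmf_cv")
}

#' @export
print.nrlmf_cv <- function(x, ...) {
  cat(sprintf("<nrlmf_cv> %s, %d repeats x %d folds (%s aggregation)\n",
              toupper(x$setting), x$split$n_repeats, x$split$n_folds, x$aggregate))
  with(x$summary, cat(sprintf("  %s: %.3f +/- %.3f\n", metric, mean, sd), sep = ""))
  invisible(x)
}

#' @rdname cross_validate
#' @param x an `nrlmf_cv` object.
#' @param ... unused.
#' @method tidy nrlmf_cv
#' @export
tidy.nrlmf_cv <- function(x, ...) x$fold_metrics

#' @rdname cross_validate
#' @method glance nrlmf_cv
#' @export
glance.nrlmf_cv <- function(x, ...) {
  tibble::tibble(
    setting = x$setting,
    auc_mean = x$summary$mean[x$summary$metric == "auc"],
    auc_sd = x$summary$sd[x$summary$metric == "auc"],
    aupr_mean = x$summary$mean[x$summary$metric == "aupr"],
    aupr_sd = x$summary$sd[x$summary$metric == "aupr"],
    n_folds = x$split$n_folds, n_repeats = x$split$n_repeats)
}

#' Grid search over hyperparameter combinations
#'
#' Evaluates [cross_validate()] at every point of the Cartesian product of
#' the supplied value vectors and returns the point maximizing the mean of
#' the chosen metric, together with the full results table. A `lambda`
#' entry sets `lambda_d` and `lambda_t` jointly (the usual tying). The
#' selection reuses one shared split, so fold pairing is preserved across
#' grid points.
#'
#' @param ds a `dti_dataset`.
#' @param grid named list of value vectors over [nrlmf_hyperparams()]
#'   fields (plus optional `lambda`); see [default_grid()].
#' @param setting blinding regime.
#' @param metric `"auc"` or `"aupr"`.
#' @param base hyperparameters for fields not in the grid.
#' @param n_folds,n_repeats,seed CV protocol.
#' @return list with `best` (an `nrlmf_hyperparams`), `best_row` and
#'   `results` (one tibble row per grid point with mean/sd of both metrics).
#' @export
grid_search_nrlmf <- function(ds, grid, setting = c("cvs1", "cvs2", "cvs3"),
                              metric = c("auc", "aupr"),
                              base = nrlmf_hyperparams(),
                              n_folds = 10, n_repeats = 5, seed = 1L) {
  setting <- match.arg(setting)
  metric <- match.arg(metric)
  if (length(grid) == 0) stop_validation("grid must be nonempty")
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  split <- make_cv_splits(ds, setting, n_folds, n_repeats, seed)
  eval_point <- function(row) {
    hp <- unclass(base)
    for (nm in names(row)) {
      if (nm == "lambda") {
        hp$lambda_d <- row[[nm]]; hp$lambda_t <- row[[nm]]
      } else {
        hp[[nm]] <- row[[nm]]
      }
    }
    hp <- do.call(nrlmf_hyperparams, hp)
    cv <- cross_validate(ds, hp, setting, split = split)
    g <- glance(cv)
    tibble::tibble(!!!row, auc_mean = g$auc_mean, auc_sd = g$auc_sd,
                   aupr_mean = g$aupr_mean, aupr_sd = g$aupr_sd)
  }
  results <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    eval_point(as.list(points[i, , drop = FALSE]))
  })
  score <- results[[paste0(metric, "_mean")]]
  best_i <- which.max(score)
  best_row <- results[best_i, ]
  hp <- unclass(base)
  for (nm in names(grid)) {
    if (nm == "lambda") {
      hp$lambda_d <- best_row[[nm]]; hp$lambda_t <- best_row[[nm]]
    } else {
      hp[[nm]] <- best_row[[nm]]
    }
  }
  list(best = do.call(nrlmf_hyperparams, hp), best_row = best_row, results = results)
}

#' Paired significance test between two cross-validation runs
#'
#' Two-sided paired t-test on per-fold metric differences. Folds are paired
#' across methods under a shared split, which is why the paired form is
#' appropriate. When the differences have zero variance the t statistic is
#' undefined; the p-value is then defined as 1 for identical means and 0
#' otherwise.
#'
#' @param res_a,res_b equal-length numeric vectors of per-fold metric
#'   values (or `nrlmf_cv` objects, from which the chosen metric column is
#'   taken).
#' @param metric metric column used when passing `nrlmf_cv` objects.
#' @return the p-value.
#' @export
compare_significance <- function(res_a, res_b, metric = c("auc", "aupr")) {
  metric <- match.arg(metric)
  if (inherits(res_a, "nrlmf_cv")) res_a <- res_a$fold_metrics[[metric]]
  if (inherits(res_b, "nrlmf_cv")) res_b <- res_b$fold_metrics[[metric]]
  if (length(res_a) != length(res_b)) {
    stop_validation("per-fold lists must have equal length (%d vs %d)",
                    length(res_a), length(res_b))
  }
  if (length(res_a) < 2) stop_validation("need at least two paired folds")
  d <- res_a - res_b
  if (stats::sd(d) == 0) {
    return(if (mean(d) == 0) 1 else 0)
  }
  stats::t.test(res_a, res_b, paired = TRUE)$p.value
}

#' Rank unknown pairs by predicted interaction probability
#'
#' Trains on the full dataset, predicts every pair with `y = 0` via the
#' smoothed predictor, and returns the top of the ranking — the candidate
#' novel interactions. Ties are broken lexicographically by
#' (drug id, target id).
#'
#' @param ds a `dti_dataset`.
#' @param hyper hyperparameters (conventionally those selected under the
#'   pair-blinded regime).
#' @param top_n number of pairs to return (default 30); if it exceeds the
#'   number of unknown pairs, all are returned with a warning.
#' @param model optional pre-fitted `nrlmf` on `ds`, to avoid retraining.
#' @return tibble with columns `rank`, `drug_id`, `target_id`,
#'   `probability`, in non-increasing probability order; no training
#'   positive appears.
#' @export
rank_novel_interactions <- function(ds, hyper = nrlmf_hyperparams(), top_n = 30,
                                    model = NULL) {
  if (is.null(model)) model <- nrlmf(ds, hyper)
  P <- predict(model)
  unknown <- which(ds$Y == 0)
  if (length(unknown) == 0) stop_validation("no unknown pairs to rank")
  if (top_n > length(unknown)) {
    warning(sprintf("top_n = %d exceeds the %d unknown pairs; returning all",
                    top_n, length(unknown)))
    top_n <- length(unknown)
  }
  ij <- arrayInd(unknown, dim(ds$Y))
  res <- tibble::tibble(
    drug_id = ds$drug_ids[ij[, 1]],
    target_id = ds$target_ids[ij[, 2]],
    probability = P[unknown])
  res <- dplyr::arrange(res, dplyr::desc(.data$probability),
                        .data$drug_id, .data$target_id)
  res <- dplyr::slice_head(res, n = top_n)
  dplyr::mutate(res, rank = dplyr::row_number(), .before = 1)
}
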