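#' Sensitivity, specificity and accuracy from confusion counts
#'
#' The positive class is the disease group of the task (group 1).
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' accuracy = (TP + TN) / (TP + FP + TN + FN). A metric whose denominator
#' is zero is undefined and reported as `NA`.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' confusion_metrics(tp = 46, fp = 2, tn = 78, fn = 1)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  c(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (total > 0) (tp + tn) / total else NA_real_
  )
}

#' Repeated stratified cross-validation of a linear-kernel SVM
#'
#' Evaluates how well the autoantibody profiles separate two serum groups:
#' a soft-margin linear-kernel support vector machine (cost `C`, via
#' \pkg{e1071}/libsvm) is assessed by stratified `folds`-fold
#' cross-validation, repeated `repetitions` times with re-drawn folds.
#' Quantile normalization is fitted on the training folds only and applied
#' to the held-out fold, so no test information leaks into the reference
#' distribution. Per repetition the fold confusion counts are pooled into
#' one sensitivity/specificity/accuracy triple; the report carries all
#' repetition values, their medians and 95% percentile intervals, and
#' per-serum probability-like decision scores (logistic calibration of the
#' SVM decision values, fitted on the training folds) averaged across
#' repetitions.
#'
#' The *first* level of `groups` is the positive (disease) class.
#'
#' @param x Numeric matrix, sera as rows, antigens as columns
#'   (unnormalized; normalization happens per fold).
#' @param groups Factor (or coercible) with two levels, length `nrow(x)`.
#' @param folds Number of cross-validation folds; reduced with a warning
#'   if a class has fewer sera than folds.
#' @param repetitions Number of times the fold split is re-drawn.
#' @param cost Soft-margin cost C of the SVM.
#' @param seed Integer seed; repetition-level seeds are derived from it so
#'   the full report is reproducible.
#' @param normalize `"fold"` (quantile normalization fitted per training
#'   fold; default), `"global"` (one normalization of the full matrix
#'   up front) or `"none"`.
#' @param calibrate Compute per-serum probability scores (default `TRUE`;
#'   disable to speed up permutation runs).
#' @return Object of class `classification_report`: list with `metrics`
#'   (per-repetition data frame of pooled confusion counts and metric
#'   values), `median`, `ci` (2.5/97.5 percentiles per metric), `scores`
#'   (per-serum mean calibrated score with the 0.5 threshold), `positive`,
#'   and the evaluation parameters.
#' @examples
#' sim <- simulate_profiles(sim_config(n_antigens = 40, n_subgrid_rows = 2,
#'   n_subgrid_cols = 2, spots_per_subgrid = 20, n_group1 = 10,
#'   n_group2 = 10, effect_size = 60, noise_sd = 5))
#' cv <- cross_validate(sim$profiles, sim$groups, folds = 5,
#'                      repetitions = 2, seed = 7)
#' cv$median
#' @export
cross_validate <- function(x, groups, folds = 10L, repetitions = 10L,
                           cost = 1, seed = 1L,
                           normalize = c("fold", "global", "none"),
                           calibrate = TRUE) {
  normalize <- match.arg(normalize)
  groups <- check_two_groups(x, groups)
  positive <- levels(groups)[1]
  min_class <- min(table(groups))
  if (min_class < 2L) stop("each serum group needs >= 2 sera", call. = FALSE)
  if (min_class < folds) {
    warning("reducing folds from ", folds, " to ", min_class,
            " (smallest class size)", call. = FALSE)
    folds <- min_class
  }
  if (normalize == "global") x <- quantile_normalize(x)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)

  n <- nrow(x)
  metrics <- data.frame(repetition = seq_len(repetitions), tp = 0L, fp = 0L,
                        tn = 0L, fn = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, accuracy = NA_real_)
  score_mat <- matrix(NA_real_, n, repetitions)

  order_key <- if (!is.null(rownames(x))) rownames(x) else seq_len(n)

  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    fold_id <- stratified_folds(groups, folds, order_key)
    counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      fit <- fit_svm_fold(x, groups, tr, te, cost, normalize, calibrate)
      truth_pos <- groups[te] == positive
      pred_pos <- fit$pred == positive
      counts["tp"] <- counts["tp"] + sum(pred_pos & truth_pos)
      counts["fp"] <- counts["fp"] + sum(pred_pos & !truth_pos)
      counts["tn"] <- counts["tn"] + sum(!pred_pos & !truth_pos)
      counts["fn"] <- counts["fn"] + sum(!pred_pos & truth_pos)
      if (calibrate) score_mat[te, r] <- fit$score
    }
    metrics[r, c("tp", "fp", "tn", "fn")] <- as.list(counts)
    metrics[r, c("sensitivity", "specificity", "accuracy")] <-
      as.list(confusion_metrics(counts["tp"], counts["fp"], counts["tn"],
                                counts["fn"]))
  }

  med <- vapply(metrics[c("sensitivity", "specificity", "accuracy")],
                stats::median, 0, na.rm = TRUE)
  ci <- vapply(metrics[c("sensitivity", "specificity", "accuracy")],
               stats::quantile, numeric(2), probs = c(0.025, 0.975),
               na.rm = TRUE)
  rownames(ci) <- c("lower", "upper")

  scores <- if (calibrate) {
    data.frame(
      serum_id = if (!is.null(rownames(x))) rownames(x) else seq_len(n),
      group = groups,
      score = rowMeans(score_mat)
    )
  } else NULL

  structure(list(metrics = metrics, median = med, ci = ci, scores = scores,
                 threshold = 0.5, positive = positive, folds = folds,
                 repetitions = repetitions, cost = cost, seed = seed,
                 normalize = normalize),
            class = "classification_report")
}

# Stratified fold assignment: class proportions preserved per fold.
# Sera are enumerated in order of 'order_key' (serum id) before the random
# shuffle, so the serum-to-fold map does not depend on row order.
stratified_folds <- function(groups, folds, order_key = seq_along(groups)) {
  fold_id <- integer(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    idx <- idx[order(order_key[idx])]
    idx <- sample(idx)
    fold_id[idx] <- rep_len(sample.int(folds), length(idx))
  }
  fold_id
}

# Train on rows tr, predict rows te; normalization fitted on tr only.
fit_svm_fold <- function(x, groups, tr, te, cost, normalize, calibrate) {
  if (normalize == "fold") {
    ref <- qn_reference(x[tr, , drop = FALSE])
    xtr <- qn_apply(x[tr, , drop = FALSE], ref)
    xte <- qn_apply(x[te, , drop = FALSE], ref)
  } else {
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
  }
  fit <- e1071::svm(xtr, groups[tr], kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, xte)
  score <- NULL
  if (calibrate) {
    dv_tr <- attr(stats::predict(fit, xtr, decision.values = TRUE),
                  "decision.values")[, 1]
    dv_te <- attr(stats::predict(fit, xte, decision.values = TRUE),
                  "decision.values")[, 1]
    y <- as.integer(groups[tr] == levels(groups)[1])
    cal <- tryCatch(
      suppressWarnings(stats::glm(y ~ dv, family = stats::binomial(),
                                  data = data.frame(y = y, dv = dv_tr))),
      error = function(e) NULL
    )
    score <- if (is.null(cal)) {
      # fallback when the logistic fit fails outright: orient the raw
      # decision values toward the positive class
      s <- sign(stats::cor(dv_tr, y))
      stats::plogis(s * dv_te)
    } else {
      as.numeric(stats::predict(cal, newdata = data.frame(dv = dv_te),
                                type = "response"))
    }
  }
  list(pred = pred, score = score)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Linear SVM (C = %g), %d-fold CV x %d repetitions, positive class '%s'\n",
              x$cost, x$folds, x$repetitions, x$positive))
  for (m in names(x$median)) {
    cat(sprintf("  median %-11s %.3f  (95%% CI %.3f-%.3f)\n", m,
                x$median[m], x$ci["lower", m], x$ci["upper", m]))
  }
  invisible(x)
}

#' Stratified label-permutation test of the classifier
#'
#' Guards against overfitting: class labels are randomly permuted
#' (preserving the class sizes) and the full cross-validated SVM
#' evaluation is repeated on each permuted labeling, yielding a chance
#' distribution of accuracy. With balanced classes its center is about
#' 50%; with unbalanced classes it sits at the class-prior chance level
#' `p^2 + (1-p)^2`. The true-label repetition accuracies are compared
#' against the permutation accuracies with a one-sided Wilcoxon rank-sum
#' test.
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations.
#' @param observed Optional precomputed [cross_validate()] report for the
#'   true labels (with matching parameters); computed internally if
#'   missing.
#' @return Object of class `permutation_test`: list with `accuracies`
#'   (one pooled CV accuracy per permutation), their `median` and `mean`,
#'   the one-sided rank-sum `p_value`, and the `observed` report.
#' @examples
#' sim <- simulate_profiles(sim_config(n_antigens = 40, n_subgrid_rows = 2,
#'   n_subgrid_cols = 2, spots_per_subgrid = 20, n_group1 = 8, n_group2 = 8,
#'   effect_size = 0))
#' pt <- permutation_test(sim$profiles, sim$groups, n_permutations = 5,
#'                        folds = 4, seed = 3)
#' pt$median
#' @export
permutation_test <- function(x, groups, n_permutations = 100L, folds = 10L,
                             cost = 1, seed = 1L,
                             normalize = c("fold", "global", "none"),
                             observed = NULL) {
  normalize <- match.arg(normalize)
  groups <- check_two_groups(x, groups)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_permutations + 1L)

  if (is.null(observed)) {
    observed <- cross_validate(x, groups, folds = folds, repetitions = 10L,
                               cost = cost, seed = seeds[1L],
                               normalize = normalize, calibrate = FALSE)
  }

  acc <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    set.seed(seeds[p + 1L])
    perm <- sample(groups)  # preserves class sizes (stratified)
    cv <- cross_validate(x, perm, folds = folds, repetitions = 1L,
                         cost = cost,
                         seed = seeds[p + 1L], normalize = normalize,
                         calibrate = FALSE)
    acc[p] <- cv$metrics$accuracy[1L]
  }

  pval <- suppressWarnings(
    stats::wilcox.test(observed$metrics$accuracy, acc,
                       alternative = "greater", exact = FALSE)$p.value
  )
  structure(list(accuracies = acc, median = stats::median(acc),
                 mean = mean(acc), p_value = pval, observed = observed,
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Stratified permutation test: %d permutations\n",
              x$n_permutations))
  cat(sprintf("  permuted accuracy: median %.3f, mean %.3f\n",
              x$median, x$mean))
  cat(sprintf("  observed median accuracy: %.3f\n",
              x$observed$median["accuracy"]))
  cat(sprintf("  one-sided rank-sum p-value: %.3g\n", x$p_value))
  invisible(x)
}

#' Per-serum decision scores of a cross-validated classifier
#'
#' Extracts the per-serum probability-like scores (mean calibrated SVM
#' score across repetitions; the estimated probability of belonging to
#' the positive class) together with the 0.5 classification threshold,
#' ready for a per-serum probability plot.
#'
#' @param report A `classification_report` from [cross_validate()] run
#'   with `calibrate = TRUE`.
#' @return Data frame `serum_id`, `group`, `score`, `predicted`, with the
#'   threshold as attribute `threshold`.
#' @export
decision_scores <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  if (is.null(report$scores)) {
    stop("report was produced with calibrate = FALSE; no scores available",
         call. = FALSE)
  }
  out <- report$scores
  lev <- levels(out$group)
  out$predicted <- factor(
    ifelse(out$score >= report$threshold, report$positive,
           setdiff(lev, report$positive)),
    levels = lev
  )
  attr(out, "threshold") <- report$threshold
  out
}
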