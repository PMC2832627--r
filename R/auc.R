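#' Per-antigen ROC AUC by threshold sweep
#'
#' Scores how well one antigen's intensities separate two serum groups.
#' Every observed intensity serves as a candidate threshold; at each
#' threshold sensitivity and specificity are computed with group 2 treated
#' as the positive class, and the area under the resulting ROC curve is
#' obtained by the trapezoidal rule (ties between a value and the
#' threshold therefore count one half). Orientation convention: AUC > 0.5
#' means group 2 tends to higher intensities; AUC < 0.5 means group 1
#' does. Equivalently, the AUC is the probability that a random group-2
#' serum exceeds a random group-1 serum, ties counted half, so
#' `antigen_auc(g1, g2) == 1 - antigen_auc(g2, g1)`.
#'
#' @param group1,group2 Numeric vectors of (normalized) intensities of the
#'   antigen in the two serum groups; both non-empty.
#' @return AUC in [0, 1]. 0.5 means the two intensity distributions cannot
#'   be distinguished; 0 or 1 means perfect separation.
#' @examples
#' antigen_auc(c(1, 3), c(2, 4))  # 0.75
#' @export
antigen_auc <- function(group1, group2) {
  if (length(group1) == 0L || length(group2) == 0L) {
    stop("both serum groups must be non-empty", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(c(group1, group2))))
  # group 2 positive: sensitivity = P(g2 > t), 1 - specificity = P(g1 > t)
  sens <- vapply(thr, function(t) mean(group2 > t), 0)
  fpr <- vapply(thr, function(t) mean(group1 > t), 0)
  # thresholds ascend, so (fpr, sens) descends from (1, 1) to (0, 0)
  n <- length(thr)
  sum((fpr[-n] - fpr[-1L]) * (sens[-n] + sens[-1L]) / 2)
}

#' Informativeness rule for antigen AUCs
#'
#' An antigen is considered informative for a serum-group comparison when
#' its AUC deviates strongly from chance: strictly below 0.3 or strictly
#' above 0.7.
#'
#' @param auc Numeric vector of AUC values in [0, 1].
#' @return Logical vector.
#' @examples
#' flag_informative(c(0.29, 0.3, 0.5, 0.7, 0.71))
#' @export
flag_informative <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  auc < 0.3 | auc > 0.7
}

#' AUC table for all antigens of a profile matrix
#'
#' Computes [antigen_auc()] for every antigen (column) of a normalized
#' profile matrix and applies the informativeness rule.
#'
#' @param x Numeric matrix, sera as rows, antigens as columns (typically
#'   the output of [quantile_normalize()]).
#' @param groups Factor with two levels; the first level is group 1.
#' @return Data frame with `antigen_id`, `auc`, `informative`.
#' @export
auc_table <- function(x, groups) {
  groups <- check_two_groups(x, groups)
  g1 <- groups == levels(groups)[1]
  auc <- vapply(seq_len(ncol(x)),
                function(j) antigen_auc(x[g1, j], x[!g1, j]), 0)
  data.frame(
    antigen_id = if (!is.null(colnames(x))) colnames(x) else seq_len(ncol(x)),
    auc = auc,
    informative = flag_informative(auc)
  )
}

check_two_groups <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(x)) {
    stop("length of 'groups' (", length(groups),
         ") must match the number of sera (", nrow(x), ")", call. = FALSE)
  }
  if (nlevels(groups) != 2L) {
    stop("exactly two serum groups are required, got ", nlevels(groups),
         call. = FALSE)
  }
  groups
}
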