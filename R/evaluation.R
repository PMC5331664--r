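# Evaluation machinery: ROC/AUC fold-recognition analysis, Pearson
# correlation against external scores, and nearest-group classification
# experiments, plus the uninformative RANDOM distance baseline.

.pair_data <- function(distances, groups) {
  ids <- rownames(distances)
  if (is.null(ids)) stop("distance matrix must have id dimnames",
                         call. = FALSE)
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop("unlabeled sequence id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- groups[ids]
  ut <- upper.tri(distances)
  idx <- which(ut, arr.ind = TRUE)
  list(score = distances[ut], g1 = lab[idx[, 1L]], g2 = lab[idx[, 2L]])
}

# Midrank (Mann-Whitney) AUC for "smaller score = positive".
.auc_rank <- function(score, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  r <- rank(-score) # larger rank = smaller distance
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC analysis of group recognition from a distance matrix
#'
#' Sweeps a threshold over all pairwise distances; pairs at or below the
#' threshold are called positive. In `"pooled"` mode a pair is truly
#' positive when both members share a group, whichever group that is; in
#' `"per-group"` mode only pairs within the named `group` are positive and
#' every other pair is negative. The AUC is computed by the midrank
#' Mann-Whitney statistic, which equals the trapezoidal area under the
#' stepwise ROC curve.
#'
#' @param distances Symmetric distance matrix with id dimnames (smaller =
#'   more similar).
#' @param groups Named character vector, id to group label.
#' @param mode `"pooled"` or `"per-group"`.
#' @param group Group label, required in `"per-group"` mode.
#' @return Object of class `seqkernel_roc`: list with `thresholds`,
#'   `tpr`, `fpr` (curve including the (0,0) and (1,1) endpoints), `auc`,
#'   `mode`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(distances, groups,
                         mode = c("pooled", "per-group"), group = NULL) {
  mode <- match.arg(mode)
  pd <- .pair_data(distances, groups)
  if (length(unique(groups[rownames(distances)])) < 2L) {
    stop("need at least 2 groups for a ROC analysis", call. = FALSE)
  }
  if (mode == "pooled") {
    positive <- pd$g1 == pd$g2
    mode_label <- "pooled"
  } else {
    if (is.null(group)) stop("per-group mode needs a group label",
                             call. = FALSE)
    if (sum(groups[rownames(distances)] == group) < 2L) {
      stop("group '", group, "' has fewer than 2 members", call. = FALSE)
    }
    positive <- pd$g1 == group & pd$g2 == group
    mode_label <- paste0("per-group:", group)
  }
  if (!any(positive) || all(positive)) {
    stop("ROC analysis needs both positive and negative pairs",
         call. = FALSE)
  }
  auc <- .auc_rank(pd$score, positive)
  thr <- sort(unique(pd$score))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(positive & pd$score <= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(!positive & pd$score <= t) / n_neg,
                numeric(1))
  structure(list(thresholds = c(-Inf, thr), tpr = c(0, tpr),
                 fpr = c(0, fpr), auc = auc, mode = mode_label,
                 n_pos = n_pos, n_neg = n_neg),
            class = "seqkernel_roc")
}

#' @export
print.seqkernel_roc <- function(x, ...) {
  cat("ROC analysis (", x$mode, "): AUC = ", format(x$auc, digits = 4),
      " over ", x$n_pos, " positive / ", x$n_neg, " negative pairs\n",
      sep = "")
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc `seqkernel_roc` object.
#' @return Scalar area; equals the rank-statistic AUC up to round-off.
#' @export
roc_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                         utils::tail(roc$tpr, -1)) / 2)
}

#' Pearson correlation between two score sets
#'
#' Standard Pearson product-moment correlation, used to compare kernel
#' similarities against externally computed reference scores (for example
#' structural alignment SAS values).
#'
#' @param xs,ys Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("lengths differ", call. = FALSE)
  if (length(xs) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(xs, ys, method = "pearson")
}

#' Nearest-group classification experiments
#'
#' Repeated stratified half-split experiments: in each repeat the members
#' of every group are split at random into training and test halves (odd
#' sizes put the extra member in training). Each test sequence is assigned
#' the group whose training members have the smallest mean distance to it;
#' ties go to the lexicographically smallest group label. Results are
#' gathered per repeat into a confusion matrix `C(i,j)` (test sequences of
#' group i assigned to group j) and summarised by the classifier
#' efficiency, the trace of the confusion matrix over the sum of all its
#' elements.
#'
#' @param distances Symmetric distance matrix with id dimnames.
#' @param groups Named character vector, id to group label; every group
#'   must have at least 2 members.
#' @param n_repeats Number of random splits.
#' @param seed Optional integer seed fixing the splits.
#' @return Object of class `seqkernel_classify`: list with `confusion`
#'   (list of per-repeat matrices), `efficiencies`, `mean_efficiency`,
#'   `labels`, `n_repeats`.
#' @export
classify_experiment <- function(distances, groups, n_repeats = 1000L,
                                seed = NULL) {
  ids <- rownames(distances)
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop("unlabeled sequence id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- groups[ids]
  labels <- sort(unique(lab))
  sizes <- table(lab)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 members to split; group '",
         names(sizes)[which(sizes < 2L)[1L]], "' has ",
         min(sizes), call. = FALSE)
  }
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  by_group <- split(seq_along(ids), lab)
  confusion <- vector("list", n_repeats)
  eff <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    test_idx <- unlist(lapply(by_group, function(members) {
      n_test <- length(members) %/% 2L # extra member stays in training
      sample(members, n_test)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_along(ids), test_idx)
    train_by_group <- split(train_idx, lab[train_idx])[labels]
    cm <- matrix(0L, length(labels), length(labels),
                 dimnames = list(labels, labels))
    for (t in test_idx) {
      means <- vapply(train_by_group,
                      function(tr) mean(distances[t, tr]), numeric(1))
      assigned <- labels[which.min(means)] # which.min: first = smallest label
      cm[lab[t], assigned] <- cm[lab[t], assigned] + 1L
    }
    confusion[[r]] <- cm
    eff[r] <- sum(diag(cm)) / sum(cm)
  }
  structure(list(confusion = confusion, efficiencies = eff,
                 mean_efficiency = mean(eff), labels = labels,
                 n_repeats = n_repeats),
            class = "seqkernel_classify")
}

#' @export
print.seqkernel_classify <- function(x, ...) {
  cat("classification experiment: ", x$n_repeats, " repeat(s), ",
      length(x$labels), " group(s), mean efficiency ",
      format(x$mean_efficiency, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Uninformative random distance baseline
#'
#' Assigns an independent uniform(0, 1) value to every pair of ids — the
#' null reference against which informative distances are compared.
#'
#' @param ids Character vector of at least 2 unique ids.
#' @param seed Optional integer seed.
#' @return Symmetric matrix, zero diagonal, attribute `type = "distance"`.
#' @export
random_distance <- function(ids, seed = NULL) {
  if (length(ids) < 2L || anyDuplicated(ids)) {
    stop("need at least 2 unique ids", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- stats::runif(n * (n - 1L) / 2L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  attr(m, "type") <- "distance"
  m
}
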