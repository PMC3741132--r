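# Validation protocols and accuracy bookkeeping.
#
# Every protocol returns a protocol_report with the accounting used in the
# study's report tables: per-class accuracy (Control %, Alzheimer %),
# their arithmetic mean (A. Mean), the overall weighted mean
# (W. Mean = 1 - errors / records evaluated), and the raw error count.

#' Build a protocol report from held-out predictions
#'
#' @param predicted,truth Character label vectors of equal length.
#' @param meta Named list of protocol metadata (protocol name, K or split
#'   fraction, seed).
#' @return A `protocol_report` with fields `control`, `alzheimer` (per-class
#'   % accuracy), `a_mean`, `w_mean` (%), `error` (count), `n`,
#'   `predicted`, `truth`, `meta`.
#' @export
protocol_report <- function(predicted, truth, meta = list()) {
  predicted <- check_labels(predicted); truth <- check_labels(truth)
  if (length(predicted) != length(truth))
    ocm_stop("predicted and truth must have equal length")
  n <- length(truth)
  err <- sum(predicted != truth)
  acc_class <- vapply(group_levels(), function(g) {
    idx <- truth == g
    if (!any(idx)) return(NA_real_)
    100 * mean(predicted[idx] == truth[idx])
  }, numeric(1))
  structure(list(control = acc_class[["control"]],
                 alzheimer = acc_class[["AD"]],
                 a_mean = mean(acc_class),
                 w_mean = 100 * (1 - err / n),
                 error = err, n = n,
                 predicted = predicted, truth = truth, meta = meta),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("protocol: %s | Control %s  Alzheimer %s  A.Mean %s  W.Mean %s  Error %d/%d\n",
              x$meta$protocol %||% "?", fmt_pct(x$control), fmt_pct(x$alzheimer),
              fmt_pct(x$a_mean), fmt_pct(x$w_mean), x$error, x$n))
  invisible(x)
}

# Stratified fold ids: within each class, records are shuffled and dealt
# into K folds as evenly as possible.
stratified_folds <- function(labels, K) {
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < K)
      ocm_stop("class '%s' has %d records, fewer than K = %d: cannot stratify",
               g, length(idx), K)
    folds[sample(idx)] <- rep_len(seq_len(K), length(idx))
  }
  folds
}

#' K-fold cross-validation protocol (stratified)
#'
#' Folds are stratified by class; each record is predicted exactly once
#' while held out, and the report pools all held-out predictions.
#'
#' @param x Input matrix.
#' @param labels Class labels per record.
#' @param learner Function `(train_x, train_y, test_x) -> labels`.
#' @param K Number of folds (default 10, the protocol used in the study).
#' @param seed Integer seed for the fold assignment.
#' @return A [protocol_report()].
#' @export
kfold_protocol <- function(x, labels, learner, K = 10, seed = 1) {
  x <- as.matrix(x); labels <- check_labels(labels)
  if (K < 2) ocm_stop("K must be >= 2")
  if (K > nrow(x)) ocm_stop("K exceeds the number of records")
  folds <- with_seed(seed, stratified_folds(labels, K))
  predicted <- character(nrow(x))
  for (f in seq_len(K)) {
    test <- folds == f
    predicted[test] <- learner(x[!test, , drop = FALSE], labels[!test],
                               x[test, , drop = FALSE])
  }
  rep <- protocol_report(predicted, labels,
                         meta = list(protocol = "kfold", K = K, seed = seed))
  rep$folds <- folds
  rep
}

#' Random-split (training and testing) protocol
#'
#' One stratified random split: the learner trains on the training
#' fraction and the report covers the held-out fraction only.
#'
#' @inheritParams kfold_protocol
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.5, giving the study's 40/40 split of 80 records).
#' @return A [protocol_report()].
#' @export
random_split_protocol <- function(x, labels, learner, train_fraction = 0.5,
                                  seed = 1) {
  x <- as.matrix(x); labels <- check_labels(labels)
  if (train_fraction <= 0 || train_fraction >= 1)
    ocm_stop("train_fraction must be in (0, 1)")
  train <- with_seed(seed, {
    tr <- logical(nrow(x))
    for (g in unique(labels)) {
      idx <- which(labels == g)
      n_tr <- round(train_fraction * length(idx))
      if (n_tr < 1 || n_tr >= length(idx))
        ocm_stop("degenerate split for class '%s'", g)
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
  if (length(unique(labels[train])) < 2 || length(unique(labels[!train])) < 2)
    ocm_stop("both classes must be present in both halves")
  predicted <- learner(x[train, , drop = FALSE], labels[train],
                       x[!train, , drop = FALSE])
  rep <- protocol_report(predicted, labels[!train],
                         meta = list(protocol = "split",
                                     train_fraction = train_fraction, seed = seed))
  rep$train <- train
  rep
}

#' Two-subset (cross-testing) protocol
#'
#' Train on subset A / test on B and train on B / test on A; the error is
#' the summation of the errors of both testing phases and per-class
#' accuracies are pooled over both.  This is the protocol applied to the
#' two statistically equivalent subsets produced by the evolutionary
#' selector.
#'
#' @inheritParams kfold_protocol
#' @param assignment Logical vector per record: `TRUE` = subset A,
#'   `FALSE` = subset B.  Both parts must be non-empty.
#' @return A [protocol_report()].
#' @export
two_subset_protocol <- function(x, labels, learner, assignment) {
  x <- as.matrix(x); labels <- check_labels(labels)
  assignment <- as.logical(assignment)
  if (length(assignment) != nrow(x))
    ocm_stop("assignment length must equal the number of records")
  if (!any(assignment) || all(assignment))
    ocm_stop("both subsets must be non-empty")
  a <- assignment; b <- !assignment
  pred_b <- learner(x[a, , drop = FALSE], labels[a], x[b, , drop = FALSE])
  pred_a <- learner(x[b, , drop = FALSE], labels[b], x[a, , drop = FALSE])
  predicted <- character(nrow(x))
  predicted[b] <- pred_b; predicted[a] <- pred_a
  rep <- protocol_report(predicted, labels,
                         meta = list(protocol = "two_subset",
                                     n_A = sum(a), n_B = sum(b)))
  rep$assignment <- assignment
  rep
}

#' Distributional divergence between two record subsets
#'
#' For each variable, the absolute difference between subset means — for
#' indicator columns this is the absolute frequency difference.  The
#' summary `max_divergence` (attribute) scores how far the bipartition is
#' from the "statistically equivalent subsets" ideal; 0 means identical
#' per-variable means.
#'
#' @param x Input matrix (columns in \[0, 1\] for a comparable scale).
#' @param partition Logical vector: `TRUE` = subset A.
#' @return Data frame `variable`, `mean_A`, `mean_B`, `divergence`, with
#'   attribute `max_divergence`.
#' @export
distribution_equivalence <- function(x, partition) {
  x <- as.matrix(x)
  partition <- as.logical(partition)
  if (length(partition) != nrow(x))
    ocm_stop("partition length must equal the number of records")
  if (!any(partition) || all(partition))
    ocm_stop("both parts must be non-empty")
  m_a <- colMeans(x[partition, , drop = FALSE])
  m_b <- colMeans(x[!partition, , drop = FALSE])
  out <- data.frame(variable = colnames(x) %||% paste0("V", seq_len(ncol(x))),
                    mean_A = m_a, mean_B = m_b,
                    divergence = abs(m_a - m_b), row.names = NULL)
  attr(out, "max_divergence") <- max(out$divergence)
  out
}
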