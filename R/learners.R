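# Native KNN classifier and the pluggable-classifier adapter contract.
#
# A learner, for protocol purposes, is any function
#   function(train_x, train_y, test_x) -> character vector of labels
# The native Euclidean KNN is the package's own (it is also the fitness
# engine of the evolutionary selector); other algorithms plug in through
# classifier_spec() adapters.  The proprietary neural networks of the
# original battery are deliberately not reimplemented: the adapter slot
# keeps the battery shape without claiming their internals.

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' K-nearest-neighbour classification (Euclidean metric)
#'
#' Each test record is assigned the majority class of its `k` nearest
#' training records.  Deterministic tie rules (the field leaves both
#' unspecified): equal distances are broken by lower training-record
#' index; an even class vote predicts the lower-ordered label
#' (`control` < `AD`).
#'
#' @param train_x Numeric matrix of training records.
#' @param train_y Class labels for `train_x` (`"control"`/`"AD"`).
#' @param test_x Numeric matrix with the same columns as `train_x`.
#' @param k Neighbourhood size, `1 <= k <= nrow(train_x)`.
#' @return Character vector of predicted labels, one per test record.
#' @export
knn_fit_predict <- function(train_x, train_y, test_x, k = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0) ocm_stop("training set is empty")
  if (k < 1 || k > nrow(train_x))
    ocm_stop("k must be between 1 and the training size (%d)", nrow(train_x))
  if (ncol(train_x) != ncol(test_x) ||
      !identical(colnames(train_x), colnames(test_x)))
    ocm_stop("train and test must share the same column set and order")
  train_y <- check_labels(train_y)
  if (length(train_y) != nrow(train_x))
    ocm_stop("train_y length does not match training rows")
  d2 <- cross_dist2(test_x, train_x)
  knn_from_dist2(d2, train_y, k)
}

# Core vote given a (test x train) squared-distance matrix; shared with the
# evolutionary selector's fast path.
knn_from_dist2 <- function(d2, train_y, k) {
  n_test <- nrow(d2)
  out <- character(n_test)
  if (k == 1) {
    idx <- max.col(-d2, ties.method = "first")  # first minimum = lowest index
    return(train_y[idx])
  }
  for (i in seq_len(n_test)) {
    ord <- order(d2[i, ], seq_along(train_y))[seq_len(k)]
    votes <- table(factor(train_y[ord], levels = group_levels()))
    out[i] <- if (votes["AD"] > votes["control"]) "AD" else "control"
  }
  out
}

#' Declare a classifier for the battery
#'
#' @param nickname Short unique name used in report tables (e.g. `"IBk"`).
#' @param fit_predict Function `(train_x, train_y, test_x) -> labels`.
#' @param params Named list of constructor parameters (recorded in
#'   reports).
#' @param source `"native"` for package-owned learners, `"adapter"` for
#'   wrapped external implementations.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(nickname, fit_predict, params = list(),
                            source = c("native", "adapter")) {
  stopifnot(is.character(nickname), length(nickname) == 1,
            is.function(fit_predict))
  structure(list(nickname = nickname, fit_predict = fit_predict,
                 params = params, source = match.arg(source)),
            class = "classifier_spec")
}

#' Built-in classifier specs
#'
#' `knn_classifier()` is the native Euclidean KNN (the instance-based
#' learner nicknamed IBk in data-mining suites; default `k = 1`).
#' `logistic_classifier()` wraps `stats::glm` binomial regression.
#' `majority_classifier()` always predicts the majority training class —
#' the chance-level baseline.
#'
#' @param k Neighbourhood size for KNN.
#' @return A `classifier_spec`.
#' @export
knn_classifier <- function(k = 1) {
  classifier_spec(if (k == 1) "IBk" else sprintf("IBk_k%d", k),
                  function(train_x, train_y, test_x)
                    knn_fit_predict(train_x, train_y, test_x, k = k),
                  params = list(k = k), source = "native")
}

#' @rdname knn_classifier
#' @export
logistic_classifier <- function() {
  classifier_spec("Logistic", function(train_x, train_y, test_x) {
    df <- as.data.frame(train_x); names(df) <- paste0("V", seq_len(ncol(train_x)))
    df$.y <- as.integer(train_y == "AD")
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    newdf <- as.data.frame(test_x); names(newdf) <- paste0("V", seq_len(ncol(test_x)))
    p <- suppressWarnings(stats::predict(fit, newdata = newdf, type = "response"))
    ifelse(p > 0.5, "AD", "control")
  }, source = "adapter")
}

#' @rdname knn_classifier
#' @export
majority_classifier <- function() {
  classifier_spec("Majority", function(train_x, train_y, test_x) {
    tab <- table(factor(train_y, levels = group_levels()))
    maj <- group_levels()[which.max(tab)]  # ties -> control (lower order)
    rep(maj, nrow(as.matrix(test_x)))
  }, source = "native")
}

#' Run a battery of classifiers under one validation protocol
#'
#' Each spec is evaluated with `protocol`; a crashing adapter is recorded
#' as a failed row (all-NA accuracies) with a warning, and the run
#' continues.  Rows are sorted by descending weighted-mean accuracy, the
#' ordering used in the study's report tables.
#'
#' @param specs List of [classifier_spec()] objects with unique nicknames.
#' @param protocol One of `"kfold"`, `"split"`, `"two_subset"`.
#' @param x Design matrix (or plain matrix) of inputs.
#' @param labels Class labels per record.
#' @param ... Protocol arguments (`K`, `train_fraction`, `assignment`,
#'   `seed`).
#' @return A `battery_result`: data frame (one row per learner, columns
#'   `nickname, control, alzheimer, a_mean, w_mean, error`) with the full
#'   `protocol_report`s in attribute `reports`.
#' @export
run_battery <- function(specs, protocol = c("kfold", "split", "two_subset"),
                        x, labels, ...) {
  protocol <- match.arg(protocol)
  nick <- vapply(specs, function(s) s$nickname, character(1))
  if (anyDuplicated(nick)) ocm_stop("classifier nicknames must be unique in a battery")
  reports <- vector("list", length(specs))
  names(reports) <- nick
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    rep_i <- tryCatch({
      switch(protocol,
             kfold = kfold_protocol(x, labels, specs[[i]]$fit_predict, ...),
             split = random_split_protocol(x, labels, specs[[i]]$fit_predict, ...),
             two_subset = two_subset_protocol(x, labels, specs[[i]]$fit_predict, ...))
    }, error = function(e) {
      warning(sprintf("learner '%s' failed: %s", nick[i], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    reports[[i]] <- rep_i
    rows[[i]] <- if (is.null(rep_i)) {
      data.frame(nickname = nick[i], control = NA_real_, alzheimer = NA_real_,
                 a_mean = NA_real_, w_mean = NA_real_, error = NA_integer_,
                 status = "failed")
    } else {
      data.frame(nickname = nick[i], control = rep_i$control,
                 alzheimer = rep_i$alzheimer, a_mean = rep_i$a_mean,
                 w_mean = rep_i$w_mean, error = rep_i$error, status = "ok")
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$w_mean, tab$nickname, na.last = TRUE), ]
  rownames(tab) <- NULL
  structure(tab, reports = reports, protocol = protocol,
            class = c("battery_result", "data.frame"))
}
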