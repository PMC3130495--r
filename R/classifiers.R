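#' Loss pattern: the identity set of misclassified records
#'
#' With a small panel and very regular error behaviour, classifiers are
#' compared by *which* records they miss, not by scalar accuracy.  A loss
#' pattern records the missed ids and stars the false positives (truly
#' negative records predicted positive).
#'
#' @param missed Character vector of misclassified record ids.
#' @param labels Named logical vector of true labels covering `missed`.
#' @return Object of class `loss_pattern` with fields `missed` (sorted),
#'   `false_positives` and `n_errors`.
#' @export
loss_pattern <- function(missed, labels) {
  missed <- sort(unique(as.character(missed)))
  if (!all(missed %in% names(labels)))
    stop("missed ids absent from labels")
  structure(list(missed = missed,
                 false_positives = missed[!labels[missed]],
                 n_errors = length(missed)),
            class = "loss_pattern")
}

#' @export
print.loss_pattern <- function(x, ...) {
  cat("<loss_pattern> ", x$n_errors, " missed: ",
      format_loss_pattern(x), "\n", sep = "")
  invisible(x)
}

#' Format a loss pattern the way result tables print them
#'
#' Comma-separated missed ids with false positives starred, e.g.
#' `"2, 5*, 20"`.
#' @param x A `loss_pattern`.
#' @return Single string (`"-"` for an empty pattern).
#' @export
format_loss_pattern <- function(x) {
  if (!x$n_errors) return("-")
  star <- ifelse(x$missed %in% x$false_positives, "*", "")
  paste0(x$missed, star, collapse = ", ")
}

# canonical key for grouping identical patterns; the "k" prefix keeps the
# key non-empty for a perfect (empty) pattern, which plain "" indexing
# would silently drop
loss_key <- function(x) paste(c("k", x$missed), collapse = "|")

#' Build a crossvalidation plan
#'
#' Leave-one-out (`L1O`) folds are the singletons in id order.  Leave-six-out
#' (`L6O`) folds are a seeded random partition into folds of `fold_size`
#' (the last fold may be smaller); the hold-out grouping in the original
#' study was ad hoc, so a recorded random partition is used here.
#'
#' @param ids Record ids.
#' @param scheme `"L1O"` or `"L6O"`.
#' @param seed Integer seed for the L6O partition.
#' @param fold_size Fold size for L6O.
#' @return Object of class `cv_plan` with `scheme`, `folds` (list of id
#'   vectors partitioning `ids`) and `seed`.
#' @export
cv_plan <- function(ids, scheme = c("L1O", "L6O"), seed = 1L,
                    fold_size = 6L) {
  scheme <- match.arg(scheme)
  if (scheme == "L1O") {
    folds <- as.list(ids)
  } else {
    ord <- with_local_seed(seed, sample(ids))
    folds <- split(ord, ceiling(seq_along(ord) / fold_size))
    names(folds) <- NULL
  }
  structure(list(scheme = scheme, folds = folds, seed = seed),
            class = "cv_plan")
}

# run `expr` under `seed` without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Classify one record by its k nearest neighbours
#'
#' Majority vote among the `k` training records closest to the query; the
#' query itself (and anything not in `train_ids`) is excluded from the
#' neighbour set.  Distance ties are broken by the smaller record id, so the
#' result is deterministic; vote ties cannot occur for odd `k` with binary
#' labels.
#'
#' @param dist Distance matrix with id dimnames.
#' @param labels Named logical vector of training labels.
#' @param query_id Id of the record to classify.
#' @param k Odd positive integer, at most the training-set size.
#' @param train_ids Ids eligible as neighbours (default: all but the query).
#' @return Logical predicted label.
#' @export
knn_classify <- function(dist, labels, query_id, k = 3L,
                         train_ids = setdiff(rownames(dist), query_id)) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  train_ids <- setdiff(train_ids, query_id)
  if (k > length(train_ids)) stop("k exceeds the training-set size")
  d <- dist[query_id, train_ids]
  ord <- order(d, train_ids)
  nb <- train_ids[ord][seq_len(k)]
  mean(labels[nb]) > 0.5
}

#' Crossvalidate a classifier, collecting its loss pattern
#'
#' For each fold of the plan the classifier is given the complement as
#' training ids and asked to predict the fold; misclassified ids are
#' collected into a [loss_pattern()].  Distance computation never involves
#' labels, so precomputed distance matrices may be reused across folds with
#' held-out rows masked from the neighbour/reference sets.
#'
#' @param predict_fun `function(train_ids, test_ids)` returning a named
#'   logical vector of predictions for `test_ids`.
#' @param ids All record ids.
#' @param labels Named logical truth.
#' @param plan A [cv_plan()] over `ids`.
#' @return A `loss_pattern`.
#' @export
crossvalidate <- function(predict_fun, ids, labels, plan) {
  if (!setequal(unlist(plan$folds), ids))
    stop("cv plan does not partition the record ids")
  missed <- character()
  for (fold in plan$folds) {
    train <- setdiff(ids, fold)
    pred <- predict_fun(train, fold)
    wrong <- fold[pred[fold] != labels[fold]]
    missed <- c(missed, wrong)
  }
  loss_pattern(missed, labels)
}

#' Crossvalidated kNN on a precomputed distance matrix
#'
#' @inheritParams knn_classify
#' @param plan A [cv_plan()].
#' @return A `loss_pattern`.
#' @export
knn_crossvalidate <- function(dist, labels, plan, k = 3L) {
  ids <- rownames(dist)
  crossvalidate(function(train, test) {
    p <- vapply(test, function(q)
      knn_classify(dist, labels, q, k = k, train_ids = train), NA)
    names(p) <- test
    p
  }, ids, labels, plan)
}

#' Rank the elastic distance functions by kNN crossvalidation error
#'
#' Evaluates every (metric, k, scheme) cell of the grid with the full
#' distance sum over all loops and indices, and orders the table by error
#' count (ascending), then metric name, k and scheme, giving a deterministic
#' ranking of the candidate distance functions.
#'
#' @param sets Encoded records (list of `index_series_set`).
#' @param labels Named logical truth.
#' @param metrics Character subset of DTW/LCSS/MVM.
#' @param ks Odd k values.
#' @param schemes CV schemes to include.
#' @param seed Seed for the L6O partition.
#' @return Data frame with columns metric, k, scheme, n_errors, missed.
#' @export
rank_distance_functions <- function(sets, labels,
                                    metrics = c("DTW", "LCSS", "MVM"),
                                    ks = c(1L, 3L, 5L),
                                    schemes = c("L1O", "L6O"),
                                    seed = 1L) {
  ids <- vapply(sets, attr, "", "id")
  rows <- list()
  for (metric in metrics) {
    D <- distance_matrix(sets, distance_spec(metric))
    for (k in ks) {
      for (scheme in schemes) {
        plan <- cv_plan(ids, scheme, seed = seed)
        lp <- knn_crossvalidate(D, labels, plan, k = k)
        rows[[length(rows) + 1L]] <-
          data.frame(metric = metric, k = k, scheme = scheme,
                     n_errors = lp$n_errors,
                     missed = format_loss_pattern(lp),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$n_errors, out$metric, out$k, out$scheme), , drop = FALSE]
}

# ------------------------------------------------------------------ SVM ----

#' RBF bandwidth from the median-pairwise-distance heuristic
#'
#' `gamma = 1 / (2 * median^2)` of the pairwise Euclidean distances between
#' training feature vectors (zero distances are ignored; a degenerate all-
#' equal feature set falls back to `gamma = 1`).
#'
#' @param features Numeric feature matrix (rows = records).
#' @return Scalar gamma for [e1071::svm()].
#' @export
rbf_gamma_heuristic <- function(features) {
  d <- as.numeric(stats::dist(features))
  d <- d[d > 0]
  if (!length(d)) return(1)
  1 / (2 * stats::median(d)^2)
}

#' Train a dissimilarity-space SVM
#'
#' Each record is represented by the vector of its elastic distances to the
#' records of a *reference panel* (always the training set: held-out records
#' never contribute reference columns).  A soft-margin SVM with an RBF kernel
#' is trained on these feature vectors; the bandwidth comes from
#' [rbf_gamma_heuristic()] unless given.
#'
#' @param dist Distance matrix covering training (and later query) ids.
#' @param labels Named logical training labels.
#' @param train_ids Training record ids (also the reference panel).
#' @param cost Soft-margin constant.
#' @param gamma RBF bandwidth; `NULL` = heuristic.
#' @return Object of class `dissim_svm` wrapping the fitted [e1071::svm()].
#' @export
svm_train <- function(dist, labels, train_ids = rownames(dist),
                      cost = 1, gamma = NULL) {
  y <- labels[train_ids]
  if (length(unique(y)) < 2L) stop("training set has a single class")
  X <- dist[train_ids, train_ids, drop = FALSE]
  if (is.null(gamma)) gamma <- rbf_gamma_heuristic(X)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(FALSE, TRUE)),
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, reference = train_ids, gamma = gamma,
                 cost = cost),
            class = "dissim_svm")
}

#' Predict with a dissimilarity-space SVM
#'
#' @param object A `dissim_svm`.
#' @param dist Distance matrix whose columns include the reference panel and
#'   whose rows include `ids`.
#' @param ids Query record ids.
#' @param ... Unused.
#' @return Named logical predictions.
#' @export
predict.dissim_svm <- function(object, dist, ids, ...) {
  X <- dist[ids, object$reference, drop = FALSE]
  p <- stats::predict(object$fit, X) == "TRUE"
  names(p) <- ids
  p
}

#' Crossvalidated dissimilarity-space SVM
#'
#' @inheritParams svm_train
#' @param plan A [cv_plan()].
#' @return A `loss_pattern`.
#' @export
svm_crossvalidate <- function(dist, labels, plan, cost = 1, gamma = NULL) {
  ids <- rownames(dist)
  crossvalidate(function(train, test) {
    fit <- svm_train(dist, labels, train_ids = train, cost = cost,
                     gamma = gamma)
    predict(fit, dist, test)
  }, ids, labels, plan)
}

#' Reference-point kernel from a squared distance (documented utility)
#'
#' The kernel identity `k_O(x, y) = (-d^2(x,y) + d^2(x,O) + d^2(y,O)) / 2`
#' turns a distance into an inner-product-like form around a reference
#' object `O`.  For non-metric elastic distances such as DTW the resulting
#' Gram matrix need not be positive semidefinite, which is why the package's
#' SVM route goes through distance feature vectors instead; this helper
#' exists to make that check concrete.
#'
#' @param dist Distance matrix.
#' @param ref_id Id of the reference record.
#' @param tol Eigenvalue tolerance for the PSD check.
#' @return List with the Gram `matrix`, its minimum eigenvalue `min_eigen`,
#'   and logical `psd`.
#' @export
reference_point_kernel <- function(dist, ref_id, tol = 1e-8) {
  ids <- rownames(dist)
  stopifnot(ref_id %in% ids)
  d2 <- dist^2
  K <- 0.5 * (-d2 + outer(d2[, ref_id], rep(1, length(ids))) +
                outer(rep(1, length(ids)), d2[, ref_id]))
  dimnames(K) <- dimnames(dist)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  list(matrix = K, min_eigen = min(ev), psd = min(ev) >= -tol)
}
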