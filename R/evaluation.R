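# The majority-vote evaluation protocol: fold roles, cluster-to-activity
# mapping with an 'other' fallback, accuracy / macro-F1, and fold-based
# cross validation in which clustering is performed once over all
# segments (transductively) while voting and scoring respect fold roles.

#' Fold roles for the two 64-fold protocols
#'
#' For a pivot fold `i` (0-based) out of `F` folds:
#' \describe{
#'   \item{E1V1T62}{evaluation = `{i}`, validation = `{i+1 mod F}`,
#'     training = the remaining folds (the plentiful-labels setting).}
#'   \item{T1V1E62}{training = `{i}`, validation = `{i+1 mod F}`,
#'     evaluation = the remaining folds (the scarce-labels setting).}
#' }
#' Adjacency wraps modulo `F` so every fold can serve as pivot; the
#' roles always partition all folds.
#'
#' @param scheme `"E1V1T62"` or `"T1V1E62"`.
#' @param pivot 0-based pivot fold index.
#' @param nFolds total number of folds F (the reference protocol uses 64).
#' @return list with integer vectors `train`, `validation`, `evaluation`
#'   of 0-based fold indices.
#' @export
foldRoles <- function(scheme = c("E1V1T62", "T1V1E62"), pivot, nFolds) {
  scheme <- match.arg(scheme)
  pivot <- as.integer(pivot); nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stopf("need at least 2 folds")
  if (pivot < 0L || pivot >= nFolds) stopf("pivot must lie in [0, F-1]")
  nxt <- (pivot + 1L) %% nFolds
  rest <- setdiff(seq_len(nFolds) - 1L, c(pivot, nxt))
  if (scheme == "E1V1T62")
    list(train = rest, validation = nxt, evaluation = pivot)
  else
    list(train = pivot, validation = nxt, evaluation = rest)
}

#' Majority-vote cluster-to-activity mapping
#'
#' For each cluster, the ground-truth labels of its members among the
#' voting (labeled) segments are collected and the most frequent label is
#' assigned to the cluster; ties are broken toward the alphabetically
#' first label. Clusters with no voting member receive no mapping (the
#' prediction step then falls back to the 'other' label). Segments
#' outside `voterIdx` — typically the evaluation fold — never influence
#' the vote.
#'
#' @param clusters integer cluster assignment per segment.
#' @param labels character label per segment (`NA` allowed outside
#'   `voterIdx`).
#' @param voterIdx indices (or logical mask) of segments allowed to vote;
#'   all must carry non-`NA` labels.
#' @return named character vector mapping cluster id (as character) to
#'   label; unmapped clusters are absent.
#' @export
majorityVoteMap <- function(clusters, labels, voterIdx = seq_along(clusters)) {
  if (is.logical(voterIdx)) voterIdx <- which(voterIdx)
  if (any(is.na(labels[voterIdx])))
    stopf("all voting segments must be labeled")
  cl <- clusters[voterIdx]
  lb <- labels[voterIdx]
  out <- vapply(split(lb, cl), function(v) {
    t <- table(v)
    names(t)[which.max(t)]  # table is alphabetical; which.max takes first on ties
  }, character(1))
  out
}

#' Predict activity labels from cluster assignments
#'
#' Mapped clusters predict their majority label; segments in unmapped
#' clusters receive the fallback label.
#'
#' @param clusters integer cluster assignment per segment.
#' @param map named character vector from [majorityVoteMap()].
#' @param fallback label for unmapped clusters (default `"other"`).
#' @return character vector of predicted labels with attribute
#'   `fallbackCount`.
#' @export
predictLabels <- function(clusters, map, fallback = "other") {
  pred <- unname(map[as.character(clusters)])
  nFallback <- sum(is.na(pred))
  pred[is.na(pred)] <- fallback
  attr(pred, "fallbackCount") <- nFallback
  pred
}

#' Accuracy and macro-averaged F1
#'
#' Accuracy is the rate of correct predictions. Macro-F1 averages
#' per-activity F1 scores, unweighted, over the set of activities present
#' in the truth; an activity with no true and no predicted positives
#' contributes F1 = 0, and precision/recall with empty denominators are
#' taken as 0.
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels (same length, non-empty).
#' @return list with `accuracy`, `macroF1` and a per-class data frame
#'   (`precision`, `recall`, `f1`).
#' @examples
#' scorePredictions(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
#' # accuracy 0.75, macro-F1 11/15
#' @export
scorePredictions <- function(predictions, truth) {
  if (!length(truth)) stopf("empty evaluation set")
  if (length(predictions) != length(truth))
    stopf("predictions and truth must have equal length")
  classes <- sort(unique(truth))
  perClass <- do.call(rbind, lapply(classes, function(cls) {
    tp <- sum(predictions == cls & truth == cls)
    fp <- sum(predictions == cls & truth != cls)
    fn <- sum(predictions != cls & truth == cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cls, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(predictions == truth),
       macroF1 = mean(perClass$f1),
       perClass = perClass)
}

#' Fold-based cross validation of the majority-vote protocol
#'
#' The clustering is obtained once over the entire corpus (transductive:
#' either a supplied fitted model or one fit here), and the same
#' assignment vector is then evaluated under every pivot fold: majority
#' voting uses only the pivot's training + validation segments, scoring
#' uses only its evaluation segments, and segments in clusters without a
#' voting member fall back to the `fallback` label. With `refit = TRUE`
#' the model is instead refit for every pivot (same hyperparameters,
#' seed offset by the pivot index).
#'
#' @param corpus a labeled [TokenCorpus-class] with fold indices.
#' @param scheme `"E1V1T62"` or `"T1V1E62"`.
#' @param model optional fitted [DmmModel-class] for this corpus; when
#'   `NULL` one is fit with the `K`, `alpha`, `beta`, `iterations`,
#'   `seed` arguments.
#' @param K,alpha,beta,iterations,seed passed to [dmmFit()] when no model
#'   is given.
#' @param fallback label assigned to unmapped clusters.
#' @param refit refit the clustering for every pivot instead of
#'   clustering once (not the reference protocol).
#' @return object of class `CrossValidationResult`: data frame `perPivot`
#'   (pivot, accuracy, macroF1, fallbackRate, nEval), `aggregate`
#'   (mean/sd of accuracy and macro-F1, mean fallback rate),
#'   `estimatedClusters`, and the shared `assignments`.
#' @export
crossValidate <- function(corpus, scheme = c("E1V1T62", "T1V1E62"),
                          model = NULL, K = 20L, alpha = 1, beta = 0.1,
                          iterations = 50L, seed = 1L,
                          fallback = "other", refit = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is(corpus, "TokenCorpus"))
  folds <- corpus@folds
  labels <- corpus@labels
  if (any(is.na(folds))) stopf("cross validation requires fold indices on every segment")
  if (any(is.na(labels))) stopf("cross validation requires labels on every segment")
  foldIds <- sort(unique(folds))
  nFolds <- length(foldIds)
  if (!identical(foldIds, seq_len(nFolds) - 1L))
    stopf("folds must be contiguous 0-based indices 0..F-1")
  if (is.null(model) && !refit)
    model <- dmmFit(corpus, K = K, alpha = alpha, beta = beta,
                    iterations = iterations, seed = seed)
  rows <- vector("list", nFolds)
  sharedZ <- if (!refit) assignments(model) else NULL
  for (pivot in foldIds) {
    z <- if (refit)
      assignments(dmmFit(corpus, K = K, alpha = alpha, beta = beta,
                         iterations = iterations, seed = seed + pivot))
    else sharedZ
    roles <- foldRoles(scheme, pivot, nFolds)
    voters <- folds %in% c(roles$train, roles$validation)
    evalIdx <- folds %in% roles$evaluation
    map <- majorityVoteMap(z, labels, voters)
    pred <- predictLabels(z[evalIdx], map, fallback)
    sc <- scorePredictions(pred, labels[evalIdx])
    rows[[pivot + 1L]] <- data.frame(
      pivot = pivot, accuracy = sc$accuracy, macroF1 = sc$macroF1,
      fallbackRate = attr(pred, "fallbackCount") / sum(evalIdx),
      nEval = sum(evalIdx))
  }
  perPivot <- do.call(rbind, rows)
  structure(list(
    scheme = scheme,
    perPivot = perPivot,
    aggregate = list(
      accuracyMean = mean(perPivot$accuracy),
      accuracySd = sd(perPivot$accuracy),
      macroF1Mean = mean(perPivot$macroF1),
      macroF1Sd = sd(perPivot$macroF1),
      fallbackRateMean = mean(perPivot$fallbackRate)),
    estimatedClusters = if (!refit) estimatedClusterCount(model) else NA_integer_,
    assignments = sharedZ),
    class = "CrossValidationResult")
}

#' @export
print.CrossValidationResult <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("CrossValidationResult (%s, %d pivots)\n",
              x$scheme, nrow(x$perPivot)))
  cat(sprintf("  accuracy %.3f +/- %.3f; macro-F1 %.3f +/- %.3f; fallback rate %.3f\n",
              a$accuracyMean, a$accuracySd, a$macroF1Mean, a$macroF1Sd,
              a$fallbackRateMean))
  if (!is.na(x$estimatedClusters))
    cat(sprintf("  estimated clusters: %d\n", x$estimatedClusters))
  invisible(x)
}
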