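#' Multi-stream token corpus
#'
#' A `TokenCorpus` holds an ordered collection of audio segments, each
#' carrying one token sequence per stream. Tokens are stored as 1-based
#' integer identifiers into per-stream vocabularies; the word strings live
#' only in the `vocab` slot. Segments may carry an optional activity label
#' and an optional 0-based fold index (`NA` where absent). Per-stream
#' sequence lengths may differ across streams and across segments.
#'
#' @slot ids character vector of unique segment identifiers (length M).
#' @slot labels character vector, `NA_character_` for unlabeled segments.
#' @slot folds integer vector of 0-based fold indices, `NA` where absent.
#' @slot vocab named list, one character vector of word strings per
#'   stream; word strings are unique within a stream.
#' @slot tokens named list parallel to `vocab`; for each stream a list of
#'   length M whose elements are integer vectors of word identifiers in
#'   `[1, V_stream]`. Temporal order is preserved even though the model
#'   only uses counts.
#' @seealso [readCorpus()], [writeCorpus()], [generateCorpus()]
#' @export
setClass("TokenCorpus",
  representation(
    ids    = "character",
    labels = "character",
    folds  = "integer",
    vocab  = "list",
    tokens = "list"
  )
)

setValidity("TokenCorpus", function(object) {
  M <- length(object@ids)
  if (M < 1L) return("corpus must contain at least one segment")
  if (anyDuplicated(object@ids)) return("segment ids must be unique")
  if (length(object@labels) != M) return("labels must have one entry per segment")
  if (length(object@folds) != M) return("folds must have one entry per segment")
  sn <- names(object@vocab)
  if (is.null(sn) || anyDuplicated(sn) || any(sn == ""))
    return("vocab must be a named list with unique stream names")
  if (!identical(names(object@tokens), sn))
    return("tokens and vocab must name the same streams in the same order")
  for (s in sn) {
    if (anyDuplicated(object@vocab[[s]]))
      return(sprintf("duplicated word strings in stream '%s'", s))
    seqs <- object@tokens[[s]]
    if (length(seqs) != M)
      return(sprintf("stream '%s' must have one token sequence per segment", s))
    V <- length(object@vocab[[s]])
    for (m in seq_len(M)) {
      w <- seqs[[m]]
      if (length(w) && (!is.numeric(w) || any(w < 1L) || any(w > V)))
        return(sprintf("token id out of range [1, %d] in stream '%s', segment '%s'",
                       V, s, object@ids[m]))
    }
  }
  ok <- !is.na(object@folds)
  if (any(ok) && any(object@folds[ok] < 0L))
    return("fold indices must be non-negative (0-based)")
  TRUE
})

#' Construct a TokenCorpus from token strings
#'
#' @param ids character vector of unique segment identifiers.
#' @param tokens named list: for each stream, a list (one element per
#'   segment) of character vectors of token strings. All streams must
#'   cover the same segments in the same order.
#' @param labels optional character vector of activity labels (`NA` for
#'   unlabeled segments).
#' @param folds optional integer vector of 0-based fold indices.
#' @param vocab optional named list of per-stream word-string vectors
#'   (an explicit schema). When supplied, a token string absent from the
#'   schema is an error; when `NULL`, vocabularies are inferred as the
#'   union of observed tokens in first-seen order.
#' @return A [TokenCorpus-class] object.
#' @examples
#' tc <- TokenCorpus(
#'   ids = c("s1", "s2"),
#'   tokens = list(d0 = list(c("1_2", "1_2", "3_4"), c("3_4"))),
#'   labels = c("cooking", "eating")
#' )
#' nSegments(tc)
#' @export
TokenCorpus <- function(ids, tokens, labels = NULL, folds = NULL, vocab = NULL) {
  if (length(ids) < 1L) stopf("empty corpus")
  M <- length(ids)
  if (is.null(labels)) labels <- rep(NA_character_, M)
  if (is.null(folds)) folds <- rep(NA_integer_, M)
  labels <- as.character(labels)
  folds <- as.integer(folds)
  if (!is.list(tokens) || is.null(names(tokens)))
    stopf("tokens must be a named list of per-stream sequence lists")
  sn <- names(tokens)
  vocabOut <- vector("list", length(sn))
  names(vocabOut) <- sn
  idTokens <- vector("list", length(sn))
  names(idTokens) <- sn
  for (s in sn) {
    seqs <- tokens[[s]]
    if (length(seqs) != M)
      stopf("stream '%s' has %d sequences for %d segments", s, length(seqs), M)
    seqs <- lapply(seqs, as.character)
    if (is.null(vocab)) {
      voc <- unique(unlist(seqs, use.names = FALSE))
      if (is.null(voc)) voc <- character(0)
    } else {
      if (!s %in% names(vocab))
        stopf("explicit schema has no vocabulary for stream '%s'", s)
      voc <- as.character(vocab[[s]])
      observed <- unique(unlist(seqs, use.names = FALSE))
      bad <- setdiff(observed, voc)
      if (length(bad))
        stopf("schema violation: token '%s' in stream '%s' absent from the supplied schema",
              bad[1L], s)
    }
    idTokens[[s]] <- lapply(seqs, function(w) {
      if (!length(w)) return(integer(0))
      match(w, voc)
    })
    vocabOut[[s]] <- voc
  }
  new("TokenCorpus", ids = as.character(ids), labels = labels,
      folds = folds, vocab = vocabOut, tokens = idTokens)
}

#' Fitted multi-stream DMM model state
#'
#' Sufficient statistics and hyperparameters of a Dirichlet multinomial
#' mixture fit by collapsed Gibbs sampling. `tau` counts segments per
#' cluster; `omega` holds, per stream, the K x V table of token counts
#' accumulated by cluster. Both are exactly recomputable from
#' `assignments` plus the training corpus and are checked against that
#' recomputation at the end of every fit.
#'
#' @slot K integer, maximum number of clusters.
#' @slot alpha numeric length-K Dirichlet prior on cluster weights.
#' @slot beta named list, per stream a strictly positive K x V matrix of
#'   Dirichlet priors on word emissions (the second stream's entry plays
#'   the role usually written as a separate symbol in two-stream
#'   notation).
#' @slot tau numeric length-K cluster occupancy counts.
#' @slot omega named list of K x V token count matrices, one per stream.
#' @slot assignments integer length-M vector of 1-based cluster indices.
#' @slot vocab named list of per-stream word-string vectors (the model's
#'   vocabularies, frozen at fit time).
#' @slot seed integer seed the fit was started from (`NA` when resumed).
#' @slot iterationsRun integer, total Gibbs sweeps performed.
#' @slot logJointTrace numeric, collapsed log joint after each sweep.
#' @slot history integer matrix (sweeps x M) of per-sweep assignments,
#'   0 rows unless history recording was requested.
#' @slot rngState integer, the R RNG state at the end of the fit; used by
#'   [dmmFit()] to resume sampling as if uninterrupted.
#' @seealso [dmmFit()], [dmmAssign()], [saveModel()], [loadModel()]
#' @export
setClass("DmmModel",
  representation(
    K             = "integer",
    alpha         = "numeric",
    beta          = "list",
    tau           = "numeric",
    omega         = "list",
    assignments   = "integer",
    vocab         = "list",
    seed          = "integer",
    iterationsRun = "integer",
    logJointTrace = "numeric",
    history       = "matrix",
    rngState      = "integer"
  )
)

setValidity("DmmModel", function(object) {
  K <- object@K
  if (K < 1L) return("K must be >= 1")
  if (length(object@alpha) != K) return("alpha must have length K")
  if (any(object@alpha <= 0)) return("alpha must be strictly positive")
  if (length(object@tau) != K) return("tau must have length K")
  if (any(object@tau < 0)) return("tau must be non-negative")
  M <- length(object@assignments)
  if (!isTRUE(all.equal(sum(object@tau), M)))
    return("sum of tau must equal the number of segments")
  if (any(object@assignments < 1L) || any(object@assignments > K))
    return("assignments must lie in [1, K]")
  if (!isTRUE(all.equal(as.numeric(object@tau),
                        as.numeric(tabulate(object@assignments, nbins = K)))))
    return("tau disagrees with its recomputation from assignments")
  sn <- names(object@vocab)
  if (!identical(names(object@beta), sn) || !identical(names(object@omega), sn))
    return("beta, omega and vocab must name the same streams")
  for (s in sn) {
    V <- length(object@vocab[[s]])
    if (!identical(dim(object@beta[[s]]), c(K, V)))
      return(sprintf("beta[['%s']] must be K x V", s))
    if (any(object@beta[[s]] <= 0))
      return(sprintf("beta[['%s']] must be strictly positive", s))
    if (!identical(dim(object@omega[[s]]), c(K, V)))
      return(sprintf("omega[['%s']] must be K x V", s))
    if (any(object@omega[[s]] < 0))
      return(sprintf("omega[['%s']] must be non-negative", s))
  }
  TRUE
})
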