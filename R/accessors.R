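# Accessor generics and methods for the S4 containers.

#' @title Accessors for TokenCorpus and DmmModel
#' @description Small accessor functions exposing slots of the S4
#'   containers without reaching into them: segment count, identifiers,
#'   labels, folds, stream names, vocabularies, token sequences, cluster
#'   assignments and occupancy counts.
#' @param object a [TokenCorpus-class] or [DmmModel-class].
#' @param stream stream name; defaults to the first stream.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setMethod("nSegments", "TokenCorpus", function(object) length(object@ids))

#' @rdname accessors
#' @export
setGeneric("segmentIds", function(object) standardGeneric("segmentIds"))
#' @rdname accessors
#' @export
setMethod("segmentIds", "TokenCorpus", function(object) object@ids)

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setMethod("segmentLabels", "TokenCorpus", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("segmentFolds", function(object) standardGeneric("segmentFolds"))
#' @rdname accessors
#' @export
setMethod("segmentFolds", "TokenCorpus", function(object) object@folds)

#' @rdname accessors
#' @export
setGeneric("streamNames", function(object) standardGeneric("streamNames"))
#' @rdname accessors
#' @export
setMethod("streamNames", "TokenCorpus", function(object) names(object@vocab))
#' @rdname accessors
#' @export
setMethod("streamNames", "DmmModel", function(object) names(object@vocab))

#' @rdname accessors
#' @export
setGeneric("vocabulary", function(object, stream) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setMethod("vocabulary", "TokenCorpus", function(object, stream) {
  if (missing(stream)) stream <- names(object@vocab)[1L]
  object@vocab[[matchStream(object, stream)]]
})
#' @rdname accessors
#' @export
setMethod("vocabulary", "DmmModel", function(object, stream) {
  if (missing(stream)) stream <- names(object@vocab)[1L]
  object@vocab[[matchStream(object, stream)]]
})

#' @rdname accessors
#' @export
setGeneric("tokenSequences", function(object, stream) standardGeneric("tokenSequences"))
#' @rdname accessors
#' @export
setMethod("tokenSequences", "TokenCorpus", function(object, stream) {
  if (missing(stream)) stream <- names(object@vocab)[1L]
  object@tokens[[matchStream(object, stream)]]
})

#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setMethod("assignments", "DmmModel", function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setMethod("clusterSizes", "DmmModel", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("logJointTrace", function(object) standardGeneric("logJointTrace"))
#' @rdname accessors
#' @export
setMethod("logJointTrace", "DmmModel", function(object) object@logJointTrace)

matchStream <- function(object, stream) {
  sn <- names(object@vocab)
  if (is.numeric(stream)) stream <- sn[stream]
  if (!stream %in% sn)
    stopf("unknown stream '%s' (streams: %s)", stream, paste(sn, collapse = ", "))
  stream
}

setMethod("show", "TokenCorpus", function(object) {
  M <- length(object@ids)
  sn <- names(object@vocab)
  cat(sprintf("TokenCorpus: %d segments, %d stream(s)\n", M, length(sn)))
  for (s in sn) {
    ntok <- sum(lengths(object@tokens[[s]]))
    cat(sprintf("  stream '%s': V = %d, %d tokens\n",
                s, length(object@vocab[[s]]), ntok))
  }
  nlab <- sum(!is.na(object@labels))
  cat(sprintf("  labeled segments: %d; folds: %s\n", nlab,
              if (all(is.na(object@folds))) "none"
              else paste0(length(unique(object@folds[!is.na(object@folds)])), " distinct")))
})

setMethod("show", "DmmModel", function(object) {
  cat(sprintf("DmmModel: K = %d (%d non-empty), M = %d segments, %d stream(s)\n",
              object@K, sum(object@tau > 0), length(object@assignments),
              length(object@vocab)))
  cat(sprintf("  sweeps run: %d; final log joint: %s\n", object@iterationsRun,
              if (length(object@logJointTrace))
                format(tail(object@logJointTrace, 1L)) else "NA"))
})
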