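# Readers and writers for the plain-text exchange formats:
#   corpus  - JSON Lines, one object per segment
#   schema  - TSV (stream, token) listing per-stream vocabularies
#   model   - single JSON document with all DmmModel fields
# Integers are stored losslessly; fold and cluster indices are 0-based in
# files (the documented on-disk convention) and 1-based inside R.

#' Read a multi-stream token corpus from a JSON-Lines file
#'
#' Each line holds one segment object
#' `{"id": str, "label": str|null, "fold": int|null,
#'   "streams": {name: [token-string, ...]}}`.
#' Vocabularies are inferred as the union of observed tokens in first-seen
#' order unless an explicit schema is supplied, in which case a token
#' absent from the schema is an error.
#'
#' @param path path to a JSONL corpus file.
#' @param schema optional named list of per-stream word-string vectors, or
#'   the path of a schema TSV readable by [readSchema()].
#' @return A [TokenCorpus-class].
#' @seealso [writeCorpus()]
#' @export
readCorpus <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("corpus file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty corpus: '%s'", path)
  if (is.character(schema) && length(schema) == 1L) schema <- readSchema(schema)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stopf("parse error at line %d of '%s': %s",
                                i, path, conditionMessage(e)))
    if (is.null(rec$id) || is.null(rec$streams))
      stopf("parse error at line %d of '%s': segment record needs 'id' and 'streams'",
            i, path)
    recs[[i]] <- rec
  }
  streamNames <- unique(unlist(lapply(recs, function(r) names(r$streams))))
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  labels <- vapply(recs, function(r)
    if (is.null(r$label)) NA_character_ else as.character(r$label), character(1))
  folds <- vapply(recs, function(r)
    if (is.null(r$fold)) NA_integer_ else as.integer(r$fold), integer(1))
  tokens <- lapply(streamNames, function(s) {
    lapply(recs, function(r) {
      w <- r$streams[[s]]
      if (is.null(w)) character(0) else as.character(unlist(w, use.names = FALSE))
    })
  })
  names(tokens) <- streamNames
  TokenCorpus(ids = ids, tokens = tokens, labels = labels, folds = folds,
              vocab = schema)
}

#' Write a token corpus to a JSON-Lines file
#'
#' Produces a file readable by [readCorpus()]; the round trip reproduces
#' segments, labels, folds and token sequences exactly (empty sequences
#' included).
#'
#' @param corpus a [TokenCorpus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "TokenCorpus"))
  sn <- names(corpus@vocab)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stopf("cannot write '%s': %s", path,
                                            conditionMessage(e)))
  on.exit(close(con))
  for (m in seq_along(corpus@ids)) {
    streams <- lapply(sn, function(s) {
      w <- corpus@tokens[[s]][[m]]
      # keep [] (not {}) for empty sequences
      if (!length(w)) character(0) else corpus@vocab[[s]][w]
    })
    names(streams) <- sn
    rec <- list(
      id = corpus@ids[m],
      label = if (is.na(corpus@labels[m])) NULL else corpus@labels[m],
      fold = if (is.na(corpus@folds[m])) NULL else corpus@folds[m],
      streams = streams
    )
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read / write an explicit vocabulary schema
#'
#' Schema files are TSV with columns `stream` and `token`; row order fixes
#' the word-id order within each stream.
#'
#' @param path TSV path.
#' @return `readSchema()`: named list of per-stream character vectors.
#' @export
readSchema <- function(path) {
  if (!file.exists(path)) stopf("schema file '%s' does not exist", path)
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "", comment.char = "")
  if (!all(c("stream", "token") %in% names(df)))
    stopf("schema file must have columns 'stream' and 'token'")
  split(df$token, factor(df$stream, levels = unique(df$stream)))
}

#' @rdname readSchema
#' @param schema named list of per-stream word-string vectors.
#' @export
writeSchema <- function(schema, path) {
  df <- data.frame(
    stream = rep(names(schema), lengths(schema)),
    token = unlist(schema, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

MODEL_FORMAT <- "streamDMM-model-1"

#' Save / load a fitted DMM model
#'
#' The model file is a single JSON document carrying every
#' [DmmModel-class] field with integers stored losslessly; cluster
#' assignments are written 0-based (the on-disk convention) and restored
#' to the in-R 1-based form on load. `loadModel()` re-validates all count
#' invariants and fails with an integrity error on any mismatch, so a
#' corrupted file is never silently accepted. Saving and loading preserve
#' the sampler's RNG state, so a resumed fit ([dmmFit()] with `resume =`)
#' continues the exact seed stream of the saved run.
#'
#' @param model a [DmmModel-class].
#' @param path file path.
#' @return `saveModel()`: `path` invisibly; `loadModel()`: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "DmmModel"))
  validObject(model)
  doc <- list(
    format = MODEL_FORMAT,
    K = model@K,
    alpha = model@alpha,
    streams = names(model@vocab),
    vocab = model@vocab,
    beta = model@beta,
    tau = model@tau,
    omega = model@omega,
    assignments0 = model@assignments - 1L,
    seed = model@seed,
    iterationsRun = model@iterationsRun,
    logJointTrace = model@logJointTrace,
    history0 = if (nrow(model@history)) model@history - 1L
               else matrix(integer(0), 0, 0),
    rngState = model@rngState
  )
  writeLines(jsonlite::toJSON(doc, digits = NA, null = "null"), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stopf("model file '%s' does not exist", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, MODEL_FORMAT))
    stopf("integrity error: unrecognized model format '%s'", doc$format %||% "?")
  asMat <- function(x, K, V) {
    m <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = K, ncol = V)
         else matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
    m
  }
  K <- as.integer(doc$K)
  streams <- as.character(doc$streams)
  vocab <- lapply(streams, function(s) as.character(doc$vocab[[s]]))
  names(vocab) <- streams
  beta <- lapply(streams, function(s) asMat(doc$beta[[s]], K, length(vocab[[s]])))
  omega <- lapply(streams, function(s) asMat(doc$omega[[s]], K, length(vocab[[s]])))
  names(beta) <- streams
  names(omega) <- streams
  hist0 <- doc$history0
  history <- if (is.null(hist0) || !length(hist0)) emptyHistory()
             else matrix(as.integer(hist0), nrow = nrow(hist0)) + 1L
  model <- tryCatch(
    new("DmmModel",
        K = K,
        alpha = as.numeric(doc$alpha),
        beta = beta,
        tau = as.numeric(doc$tau),
        omega = omega,
        assignments = as.integer(doc$assignments0) + 1L,
        vocab = vocab,
        seed = as.integer(doc$seed),
        iterationsRun = as.integer(doc$iterationsRun),
        logJointTrace = as.numeric(doc$logJointTrace),
        history = history,
        rngState = as.integer(doc$rngState)),
    error = function(e) stopf("integrity error loading '%s': %s", path,
                              conditionMessage(e)))
  model
}

emptyHistory <- function() matrix(integer(0), nrow = 0, ncol = 0)
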