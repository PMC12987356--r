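# Acoustic-word construction from codec code matrices, and the two
# vocabulary filters: cumulative term-frequency-ratio (TFR) truncation and
# removal of noise words observed during 'absence'.

#' Read a code matrix for one audio segment
#'
#' Code matrices are TSV files with one row per audio frame and one
#' integer column per residual-vector-quantizer codebook level.
#'
#' @param path TSV path.
#' @return integer matrix (frames x codebook levels).
#' @export
readCodeMatrix <- function(path) {
  if (!file.exists(path)) stopf("code-matrix file '%s' does not exist", path)
  df <- read.table(path, header = FALSE, sep = "\t", colClasses = "integer")
  as.matrix(df)
}

#' Turn a code matrix into acoustic words
#'
#' An acoustic word for a frame is the concatenation of the frame's first
#' `prefixLength` residual-quantizer codes (coarsest stages first), joined
#' with an unambiguous separator. One word is produced per frame, so the
#' output length always equals the frame count, and distinct code prefixes
#' map to distinct words.
#'
#' @param codes integer matrix (frames x codebook levels).
#' @param prefixLength number of leading codebook levels to keep
#'   (default 2, the coarse approximation the method is built on).
#' @param sep join separator between code integers; must be non-empty so
#'   that e.g. codes (1, 23) and (12, 3) stay distinguishable.
#' @return character vector of acoustic words, one per frame.
#' @examples
#' codesToWords(rbind(c(17L, 503L, 88L), c(2L, 9L, 4L)))  # "17_503" "2_9"
#' @export
codesToWords <- function(codes, prefixLength = 2L, sep = "_") {
  codes <- as.matrix(codes)
  prefixLength <- as.integer(prefixLength)
  if (prefixLength < 1L) stopf("prefixLength must be >= 1")
  if (prefixLength > ncol(codes))
    stopf("prefixLength (%d) exceeds the number of codebook levels (%d)",
          prefixLength, ncol(codes))
  if (!nzchar(sep)) stopf("sep must be a non-empty string")
  if (nrow(codes) == 0L) return(character(0))
  cols <- lapply(seq_len(prefixLength), function(j) codes[, j])
  do.call(paste, c(cols, sep = sep))
}

#' Cumulative term-frequency-ratio (TFR) vocabulary filter
#'
#' Words are sorted by descending corpus count (ties broken
#' lexicographically) and retained rank by rank until the cumulative
#' frequency relative to the total first exceeds `r`; the word at which
#' the threshold is crossed is kept and all later words are discarded.
#' With `r=1` the cumulative ratio never exceeds the threshold and the
#' whole vocabulary is kept.
#'
#' @param wordCounts named numeric/integer vector of per-word corpus
#'   counts; at least one count must be positive.
#' @param r ratio in (0, 1].
#' @return list with elements `kept` (ordered character vector) and
#'   `report` (a `VocabularyFilterReport`: data frame with columns
#'   `token`, `count`, `cumulative`, `kept`, plus attributes `r` and
#'   `discarded`).
#' @examples
#' tfrFilter(c(a = 5, b = 3, c = 2), r = 0.6)$kept  # "a" "b"
#' @export
tfrFilter <- function(wordCounts, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stopf("r must lie in (0, 1]")
  if (!length(wordCounts) || all(wordCounts <= 0))
    stopf("tfrFilter needs at least one word with positive count")
  if (is.null(names(wordCounts))) stopf("wordCounts must be named")
  ord <- order(-as.numeric(wordCounts), names(wordCounts), method = "radix")
  counts <- as.numeric(wordCounts[ord])
  words <- names(wordCounts)[ord]
  cum <- cumsum(counts) / sum(counts)
  over <- which(cum > r)
  cut <- if (length(over)) over[1L] else length(words)
  keptMask <- seq_along(words) <= cut
  report <- data.frame(token = words, count = counts, cumulative = cum,
                       kept = as.integer(keptMask), stringsAsFactors = FALSE)
  attr(report, "r") <- r
  attr(report, "discarded") <- words[!keptMask]
  class(report) <- c("VocabularyFilterReport", "data.frame")
  list(kept = words[keptMask], report = report)
}

#' Remove words observed during noise ('absence') segments
#'
#' Every word type that occurs at least once in any of the given noise
#' segments is removed from its stream's vocabulary, and all its
#' occurrences are deleted from every segment — including segments of
#' other activities where the same word also appears. The noise segments
#' themselves are dropped from the returned corpus; other segments may
#' end up with zero-length streams but are kept.
#'
#' @param corpus a [TokenCorpus-class].
#' @param noiseSegmentIds character vector of segment ids treated as
#'   noise; must all exist in the corpus. An empty set returns the corpus
#'   unchanged.
#' @return list with `corpus` (filtered [TokenCorpus-class]) and
#'   `removed` (named list of removed word strings per stream).
#' @export
removeNoiseWords <- function(corpus, noiseSegmentIds) {
  stopifnot(is(corpus, "TokenCorpus"))
  noiseSegmentIds <- as.character(noiseSegmentIds)
  unknown <- setdiff(noiseSegmentIds, corpus@ids)
  if (length(unknown))
    stopf("unknown noise segment id '%s'", unknown[1L])
  if (!length(noiseSegmentIds))
    return(list(corpus = corpus, removed = lapply(corpus@vocab, function(v) character(0))))
  isNoise <- corpus@ids %in% noiseSegmentIds
  if (all(isNoise)) stopf("all segments are noise segments; nothing left to keep")
  removed <- lapply(names(corpus@vocab), function(s) {
    noiseIdsSeen <- unique(unlist(corpus@tokens[[s]][isNoise], use.names = FALSE))
    sort(corpus@vocab[[s]][noiseIdsSeen])
  })
  names(removed) <- names(corpus@vocab)
  keepSeg <- which(!isNoise)
  tokens <- lapply(names(corpus@vocab), function(s) {
    bad <- match(removed[[s]], corpus@vocab[[s]])
    lapply(corpus@tokens[[s]][keepSeg], function(w) {
      w <- w[!(w %in% bad)]
      corpus@vocab[[s]][w]
    })
  })
  names(tokens) <- names(corpus@vocab)
  vocab <- lapply(names(corpus@vocab), function(s)
    setdiff(corpus@vocab[[s]], removed[[s]]))
  names(vocab) <- names(corpus@vocab)
  out <- TokenCorpus(ids = corpus@ids[keepSeg], tokens = tokens,
                     labels = corpus@labels[keepSeg],
                     folds = corpus@folds[keepSeg], vocab = vocab)
  list(corpus = out, removed = removed)
}

# restrict a corpus to per-stream kept word lists (occurrences of other
# words are dropped; this silent dropping is the documented filter
# semantics, unlike schema violations at read time)
restrictVocabulary <- function(corpus, keptLists) {
  tokens <- lapply(names(corpus@vocab), function(s) {
    kept <- keptLists[[s]]
    keepId <- match(kept, corpus@vocab[[s]])
    lapply(corpus@tokens[[s]], function(w) {
      w <- w[w %in% keepId]
      corpus@vocab[[s]][w]
    })
  })
  names(tokens) <- names(corpus@vocab)
  TokenCorpus(ids = corpus@ids, tokens = tokens, labels = corpus@labels,
              folds = corpus@folds, vocab = keptLists)
}

#' Read a code-matrix manifest
#'
#' The manifest is a TSV with columns `id`, `stream`, `path` and optional
#' `label`, `fold`; one row per (segment, stream) code-matrix file.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest TSV path.
#' @return data frame with columns id, stream, path, label, fold.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest '%s' does not exist", path)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("id", "stream", "path")
  if (!all(need %in% names(df)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  if (!"label" %in% names(df)) df$label <- NA_character_
  if (!"fold" %in% names(df)) df$fold <- NA_integer_
  base <- dirname(path)
  abs <- file.path(base, df$path)
  df$path <- ifelse(file.exists(df$path), df$path, abs)
  df
}

#' Tokenize a corpus of code matrices with vocabulary filtering
#'
#' Composition of the full front end: code matrices are turned into
#' acoustic words per stream ([codesToWords()]), words seen in the noise
#' segments are removed ([removeNoiseWords()]), and each stream's
#' vocabulary is then truncated by the cumulative TFR rule
#' ([tfrFilter()]), independently per stream. Noise removal runs before
#' the TFR cut, so the frequency ranking is computed on the
#' absence-cleaned vocabulary.
#'
#' @param manifest a manifest data frame from [readManifest()] or a path
#'   to a manifest TSV.
#' @param prefixLength leading codebook levels per acoustic word
#'   (default 2).
#' @param r TFR threshold in (0, 1]; `r=1` keeps everything.
#' @param noiseSegmentIds segment ids treated as noise (may be empty).
#' @param sep word join separator, see [codesToWords()].
#' @return list with `corpus` (a [TokenCorpus-class]) and `reports`
#'   (per-stream `VocabularyFilterReport`s, each annotated with the
#'   stream's noise-removed words).
#' @export
tokenizeCorpus <- function(manifest, prefixLength = 2L, r = 0.6,
                           noiseSegmentIds = character(0), sep = "_") {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  ids <- unique(manifest$id)
  streams <- unique(manifest$stream)
  tokens <- lapply(streams, function(s) {
    sub <- manifest[manifest$stream == s, , drop = FALSE]
    lapply(ids, function(i) {
      row <- sub[sub$id == i, , drop = FALSE]
      if (nrow(row) == 0L) return(character(0))
      codesToWords(readCodeMatrix(row$path[1L]), prefixLength, sep)
    })
  })
  names(tokens) <- streams
  first <- manifest[match(ids, manifest$id), , drop = FALSE]
  corpus <- TokenCorpus(ids = ids, tokens = tokens,
                        labels = first$label, folds = first$fold)
  nr <- removeNoiseWords(corpus, noiseSegmentIds)
  corpus <- nr$corpus
  kept <- list()
  reports <- list()
  for (s in names(corpus@vocab)) {
    counts <- vocabularyCounts(corpus, s)
    if (!length(counts) || all(counts == 0)) {
      kept[[s]] <- character(0)
      reports[[s]] <- NULL
      next
    }
    f <- tfrFilter(counts, r)
    attr(f$report, "noiseWords") <- nr$removed[[s]]
    kept[[s]] <- f$kept
    reports[[s]] <- f$report
  }
  list(corpus = restrictVocabulary(corpus, kept), reports = reports)
}

#' Observed per-word corpus counts for one stream
#'
#' @param corpus a [TokenCorpus-class].
#' @param stream stream name (default: first stream).
#' @return named numeric vector of counts over the stream's vocabulary.
#' @export
vocabularyCounts <- function(corpus, stream) {
  if (missing(stream)) stream <- names(corpus@vocab)[1L]
  stream <- matchStream(corpus, stream)
  V <- length(corpus@vocab[[stream]])
  counts <- tabulate(unlist(corpus@tokens[[stream]], use.names = FALSE), nbins = V)
  setNames(as.numeric(counts), corpus@vocab[[stream]])
}

#' Write a vocabulary filter report as TSV
#'
#' Columns `token`, `count`, `kept` (0/1); noise-removed words, when
#' recorded on the report, are appended with `kept = 0` and count as
#' observed before removal is not retained (count `NA`).
#'
#' @param report a `VocabularyFilterReport` from [tfrFilter()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
writeVocabularyReport <- function(report, path) {
  df <- data.frame(token = report$token, count = report$count,
                   kept = report$kept, stringsAsFactors = FALSE)
  noise <- attr(report, "noiseWords")
  if (length(noise))
    df <- rbind(df, data.frame(token = noise, count = NA_real_, kept = 0L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
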