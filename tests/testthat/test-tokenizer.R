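# Acoustic-word construction and vocabulary filtering.

test_that("codesToWords joins the leading codes, one word per frame", {
  codes <- rbind(c(17L, 503L, 88L), c(1L, 23L, 4L), c(12L, 3L, 9L))
  expect_identical(codesToWords(codes, 2), c("17_503", "1_23", "12_3"))
  expect_identical(codesToWords(codes, 1), c("17", "1", "12"))
  expect_identical(codesToWords(codes, 3), c("17_503_88", "1_23_4", "12_3_9"))
  expect_error(codesToWords(codes, 4), "exceeds")
  # length contract: as many words as frames
  big <- matrix(sample(0:1023, 748 * 8, replace = TRUE), nrow = 748)
  expect_length(codesToWords(big, 2), 748)
})

test_that("distinct code prefixes always give distinct words", {
  # (1,23) vs (12,3) collide under plain concatenation, not under the join
  prefixes <- expand.grid(a = 0:30, b = 0:30)
  words <- codesToWords(as.matrix(prefixes), 2)
  expect_identical(anyDuplicated(words), 0L)
})

test_that("TFR filter keeps words through the first rank crossing r", {
  res <- tfrFilter(c(a = 5, b = 3, c = 2), r = 0.6)
  expect_identical(res$kept, c("a", "b"))
  expect_identical(attr(res$report, "discarded"), "c")
  expect_equal(res$report$cumulative, c(0.5, 0.8, 1.0))
  # r = 1 keeps everything
  expect_identical(tfrFilter(c(a = 5, b = 3, c = 2), r = 1)$kept,
                   c("a", "b", "c"))
  expect_error(tfrFilter(c(a = 1), r = 0), "\\(0, 1\\]")
  expect_error(tfrFilter(c(a = 1), r = 1.2), "\\(0, 1\\]")
})

test_that("TFR ties break lexicographically and kept sets are monotone in r", {
  counts <- c(z = 4, m = 4, a = 4, q = 2, b = 2)
  res <- tfrFilter(counts, r = 0.5)
  expect_identical(res$report$token[1:3], c("a", "m", "z"))
  set.seed(31)
  for (i in 1:20) {
    cts <- setNames(sample(1:6, 8, replace = TRUE),
                    paste0("w", sample(100:999, 8)))
    rs <- sort(runif(2, 0.05, 1))
    k1 <- tfrFilter(cts, rs[1])$kept
    k2 <- tfrFilter(cts, rs[2])$kept
    expect_true(all(k1 %in% k2))
    # identical reruns give identical results
    expect_identical(k1, tfrFilter(cts, rs[1])$kept)
  }
})

test_that("noise-word removal deletes noise vocabulary everywhere", {
  corpus <- TokenCorpus(
    ids = c("n1", "x1", "x2"),
    tokens = list(d0 = list(c("9_12", "7_7"), c("9_12", "5_5", "5_5"),
                            c("8_8"))),
    labels = c("absence", "cook", "eat"))
  res <- removeNoiseWords(corpus, "n1")
  expect_false("9_12" %in% vocabulary(res$corpus, "d0"))
  expect_false("7_7" %in% vocabulary(res$corpus, "d0"))
  # the shared word disappears from non-noise segments too
  expect_identical(segmentIds(res$corpus), c("x1", "x2"))
  expect_identical(vocabulary(res$corpus, "d0")[tokenSequences(res$corpus, "d0")[[1]]],
                   c("5_5", "5_5"))
  expect_identical(sort(res$removed$d0), c("7_7", "9_12"))
  # empty noise set is the identity
  res0 <- removeNoiseWords(corpus, character(0))
  expect_identical(res0$corpus@tokens, corpus@tokens)
  expect_error(removeNoiseWords(corpus, "ghost"), "unknown noise segment")
})

test_that("kept + discarded + noise partitions the original vocabulary", {
  syn <- generateCorpus(KTrue = 3, M = 30, streams = 2, V = 40, beta = 0.2,
                        segmentLength = 25, seed = 21)
  corpus <- syn$corpus
  noiseIds <- segmentIds(corpus)[1:3]
  before <- lapply(streamNames(corpus), function(s) sort(vocabulary(corpus, s)))
  nr <- removeNoiseWords(corpus, noiseIds)
  for (s in streamNames(corpus)) {
    counts <- vocabularyCounts(nr$corpus, s)
    counts <- counts[counts > 0]
    f <- tfrFilter(counts, 0.6)
    pieces <- c(f$kept, attr(f$report, "discarded"), nr$removed[[s]])
    expect_identical(anyDuplicated(pieces), 0L)
    unobserved <- setdiff(vocabulary(corpus, s), pieces)
    expect_identical(sort(c(pieces, unobserved)),
                     before[[match(s, streamNames(corpus))]])
  }
})

test_that("tokenizeCorpus runs the manifest pipeline deterministically", {
  td <- tempfile()
  dir.create(td)
  set.seed(5)
  ids <- c("sA", "sB", "sC")
  rows <- list()
  for (i in seq_along(ids)) {
    for (s in c("d0", "d30")) {
      codes <- matrix(sample(0:9, 8 * 8, replace = TRUE), nrow = 8)
      p <- file.path(td, paste0(ids[i], "_", s, ".tsv"))
      write.table(codes, p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        id = ids[i], stream = s, path = basename(p),
        label = c("cook", "absence", "eat")[i], fold = i - 1L)
    }
  }
  mf <- file.path(td, "manifest.tsv")
  write.table(do.call(rbind, rows), mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tk <- tokenizeCorpus(mf, prefixLength = 2, r = 1.0,
                       noiseSegmentIds = character(0))
  expect_identical(nSegments(tk$corpus), 3L)
  expect_identical(streamNames(tk$corpus), c("d0", "d30"))
  expect_identical(lengths(tokenSequences(tk$corpus, "d0")), rep(8L, 3))
  # r = 1 and no noise: no words lost
  expect_identical(sum(vocabularyCounts(tk$corpus, "d0")), 24)
  # rerun gives byte-identical corpus file
  f1 <- writeTempCorpus(tk$corpus)
  f2 <- writeTempCorpus(tokenizeCorpus(mf, prefixLength = 2, r = 1.0)$corpus)
  expect_identical(readLines(f1), readLines(f2))
  # noise removal drops the absence segment and its words
  tk2 <- tokenizeCorpus(mf, prefixLength = 2, r = 0.9,
                        noiseSegmentIds = "sB")
  expect_identical(nSegments(tk2$corpus), 2L)
  expect_false("sB" %in% segmentIds(tk2$corpus))
})
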