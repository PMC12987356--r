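# Small deterministic fixtures shared across test files.

# two tiny labeled segments over two streams
toyCorpus <- function() {
  TokenCorpus(
    ids = c("a1", "a2"),
    tokens = list(
      d0 = list(c("1_2", "1_2", "3_4"), c("3_4", "5_6")),
      `d+30` = list(c("9_9"), character(0))
    ),
    labels = c("cooking", "eating"),
    folds = c(0L, 1L)
  )
}

# separable corpus with one component confined to the high folds, so the
# scarce-label protocol must fall back for it
unmappedClusterCorpus <- function(seed = 4L) {
  syn <- generateCorpus(KTrue = 3, M = 48, streams = "d0", V = 60,
                        beta = 0.05, segmentLength = 40,
                        mode = "disjoint-support", seed = seed)
  corpus <- syn$corpus
  z <- syn$truth$z
  folds <- integer(length(z))
  # components 1-2 rotate through all folds; component 3 only folds 2-3
  folds[z != 3] <- (seq_len(sum(z != 3)) - 1L) %% 4L
  folds[z == 3] <- 2L + (seq_len(sum(z == 3)) - 1L) %% 2L
  corpus@folds <- folds
  validObject(corpus)
  list(corpus = corpus, z = z)
}

writeTempCorpus <- function(corpus) {
  f <- tempfile(fileext = ".jsonl")
  writeCorpus(corpus, f)
  f
}
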