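# The probabilistic core, checked against independent oracles.

test_that("DM log pmf matches its closed forms and normalizes", {
  # single outcome: probability one regardless of N
  expect_equal(dmLogPmf(c(7), c(0.3)), 0)
  # one draw: the compound categorical, P(v) = beta_v / beta.
  beta <- c(0.5, 1.0, 2.0)
  for (v in 1:3) {
    x <- numeric(3)
    x[v] <- 1
    expect_equal(dmLogPmf(x, beta), log(beta[v] / sum(beta)))
  }
  # normalization over all count vectors, V = 3, N = 4
  xs <- allCountVectors(3, 4)
  expect_identical(nrow(xs), 15L)
  for (b in list(c(0.5, 1.0, 2.0), c(0.1, 0.1, 0.1), c(3, 7, 11))) {
    tot <- sum(exp(apply(xs, 1, dmLogPmf, beta = b)))
    expect_lt(abs(tot - 1), 1e-10)
  }
  expect_error(dmLogPmf(c(-1, 1), c(1, 1)), "non-negative")
  expect_error(dmLogPmf(c(1, 1), c(0, 1)), "positive")
})

test_that("sequence probability is the pmf without the multinomial coefficient", {
  expect_equal(dmSequenceLogProb(c(0, 0, 0), c(1, 2, 3)), 0)
  # hand-evaluated gamma ratios: x = (2,0), beta = (1,1) -> 1/3
  expect_equal(dmSequenceLogProb(c(2, 0), c(1, 1)), log(1 / 3))
  set.seed(11)
  for (i in 1:20) {
    V <- sample(2:5, 1)
    x <- sample(0:4, V, replace = TRUE)
    b <- runif(V, 0.1, 3)
    expect_equal(dmSequenceLogProb(x, b), dmLogPmf(x, b) - logMultinomCoef(x))
  }
})

test_that("collapsed joint factorizes as prior times per-stream terms", {
  corpus <- smallRandomCorpus(3, M = 1, nStreams = 1, V = 4, maxLen = 6)
  alpha <- c(0.7, 1.3)
  x <- tabulate(tokenSequences(corpus)[[1]], nbins = 4)
  for (k in 1:2)
    expect_equal(jointLogProb(corpus, k, alpha, 0.4, K = 2),
                 log(alpha[k] / sum(alpha)) + dmSequenceLogProb(x, rep(0.4, 4)))
  # duplicating a stream doubles the stream term
  c2 <- TokenCorpus(
    ids = segmentIds(corpus),
    tokens = list(s1 = list(vocabulary(corpus)[tokenSequences(corpus)[[1]]]),
                  s2 = list(vocabulary(corpus)[tokenSequences(corpus)[[1]]])),
    vocab = list(s1 = vocabulary(corpus), s2 = vocabulary(corpus)))
  prior <- log(alpha[1] / sum(alpha))
  expect_equal(jointLogProb(c2, 1L, alpha, 0.4, K = 2) - prior,
               2 * (jointLogProb(corpus, 1L, alpha, 0.4, K = 2) - prior))
})

test_that("summed joint equals the Polya-urn marginal (enumeration oracle)", {
  corpus <- smallRandomCorpus(5, M = 3, nStreams = 2, V = 4, maxLen = 4)
  K <- 2; alpha <- c(1, 0.5); beta <- 0.3
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), 3)))
  lw <- apply(grid, 1, function(z)
    jointLogProb(corpus, z, alpha, beta, K = K))
  viaJoint <- max(lw) + log(sum(exp(lw - max(lw))))
  viaUrn <- polyaUrnLogMarginal(corpus, alpha, beta, K)
  expect_lt(abs(viaJoint - viaUrn), 1e-10)
})

test_that("joint is invariant to within-segment token order", {
  corpus <- smallRandomCorpus(6, M = 4, nStreams = 2, V = 5)
  z <- c(1L, 2L, 1L, 2L)
  base <- jointLogProb(corpus, z, 1, 0.2, K = 2)
  set.seed(2)
  shuf <- corpus
  shuf@tokens <- lapply(shuf@tokens, function(seqs) lapply(seqs, function(w) if (length(w) > 1) sample(w) else w))
  expect_equal(jointLogProb(shuf, z, 1, 0.2, K = 2), base)
})

test_that("Gibbs conditional equals brute force and direct products", {
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    M <- sample(2:4, 1); K <- sample(2:3, 1); V <- sample(2:5, 1)
    corpus <- smallRandomCorpus(1000 + i, M = M, nStreams = 2, V = V)
    alpha <- runif(1, 0.3, 2); beta <- runif(1, 0.05, 1)
    z <- sample.int(K, M, replace = TRUE)
    m <- sample.int(M, 1)
    impl <- gibbsConditional(corpus, z, m, alpha, beta, K = K)
    bf <- bruteForceConditional(corpus, z, m, alpha, beta, K)
    dp <- directProductConditional(corpus, z, m, alpha, beta, K)
    worst <- max(worst, max(abs(impl - bf)), max(abs(impl - dp)))
    expect_equal(sum(impl), 1)
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate segments reduce the conditional to the occupancy prior", {
  corpus <- TokenCorpus(
    ids = c("a", "b", "c"),
    tokens = list(s1 = list(c("x", "x"), c("y"), character(0)),
                  s2 = list(character(0), c("u"), character(0))))
  alpha <- c(0.5, 1.5)
  z <- c(1L, 2L, 1L)
  cond <- gibbsConditional(corpus, z, 3, alpha, 0.2, K = 2)
  tauMinus <- c(1, 1)  # segment c removed
  expect_equal(cond, (tauMinus + alpha) / sum(tauMinus + alpha))
})

test_that("a constant one-word second stream leaves the conditional unchanged", {
  corpus <- smallRandomCorpus(13, M = 4, nStreams = 1, V = 5, maxLen = 6)
  aug <- TokenCorpus(
    ids = segmentIds(corpus),
    tokens = list(
      s1 = lapply(seq_len(4), function(m)
        vocabulary(corpus)[tokenSequences(corpus)[[m]]]),
      pad = lapply(1:4, function(m) rep("only", 3))),
    vocab = list(s1 = vocabulary(corpus), pad = "only"))
  z <- c(2L, 1L, 2L, 1L)
  for (m in 1:4)
    expect_equal(gibbsConditional(aug, z, m, 1, 0.2, K = 2),
                 gibbsConditional(corpus, z, m, 1, 0.2, K = 2))
})

test_that("fit is deterministic, conserves counts, and separates clean clusters", {
  syn <- generateCorpus(KTrue = 2, M = 40, streams = "d0", V = 30,
                        beta = 0.05, segmentLength = 30,
                        mode = "disjoint-support", seed = 1)
  fitA <- dmmFit(syn$corpus, K = 5, iterations = 40, seed = 8)
  fitB <- dmmFit(syn$corpus, K = 5, iterations = 40, seed = 8)
  expect_identical(assignments(fitA), assignments(fitB))
  expect_equal(sum(clusterSizes(fitA)), 40)
  expect_identical(estimatedClusterCount(fitA), 2L)
  # the partition matches the ground truth exactly (up to relabeling)
  canon <- function(z) {
    g <- unname(split(seq_along(z), z))
    g[order(vapply(g, min, integer(1)))]
  }
  expect_identical(canon(assignments(fitA)), canon(syn$truth$z))
  expect_error(dmmFit(syn$corpus, K = 5, iterations = 0, seed = 1),
               "iterations")
})

test_that("count tables always equal their recomputation after fitting", {
  corpus <- smallRandomCorpus(17, M = 10, nStreams = 2, V = 6)
  fit <- dmmFit(corpus, K = 4, iterations = 7, seed = 3)
  ct <- streamDMM:::countTables(corpus, assignments(fit), 4)
  expect_equal(clusterSizes(fit), ct$tau)
  for (s in streamNames(corpus))
    expect_equal(unname(fit@omega[[s]]), unname(ct$omega[[s]]))
  # total token conservation per stream
  for (s in streamNames(corpus))
    expect_equal(sum(fit@omega[[s]]),
                 sum(lengths(tokenSequences(corpus, s))))
})

test_that("shuffling tokens within segments leaves the fit trajectory unchanged", {
  corpus <- smallRandomCorpus(23, M = 12, nStreams = 2, V = 8, maxLen = 10)
  fitA <- dmmFit(corpus, K = 4, iterations = 10, seed = 2, recordHistory = TRUE)
  set.seed(77)
  shuf <- corpus
  shuf@tokens <- lapply(shuf@tokens, function(seqs) lapply(seqs, function(w) if (length(w) > 1) sample(w) else w))
  fitB <- dmmFit(shuf, K = 4, iterations = 10, seed = 2, recordHistory = TRUE)
  expect_identical(assignments(fitA), assignments(fitB))
  expect_identical(fitA@history, fitB@history)
  expect_equal(logJointTrace(fitA), logJointTrace(fitB))
})

test_that("the log joint reported per sweep matches jointLogProb", {
  corpus <- smallRandomCorpus(29, M = 8, nStreams = 2, V = 6)
  fit <- dmmFit(corpus, K = 3, iterations = 5, seed = 11)
  expect_equal(tail(logJointTrace(fit), 1),
               jointLogProb(corpus, assignments(fit), fit@alpha,
                            lapply(fit@beta, function(b) b), K = 3))
})

test_that("held-out assignment handles map mode, empty segments and OOV tokens", {
  syn <- generateCorpus(KTrue = 2, M = 40, streams = "d0", V = 30,
                        beta = 0.05, segmentLength = 30,
                        mode = "disjoint-support", seed = 2)
  fit <- dmmFit(syn$corpus, K = 4, iterations = 20, seed = 1)
  # a training segment maps back to its own cluster
  sub <- TokenCorpus(
    ids = "probe",
    tokens = list(d0 = list(vocabulary(syn$corpus)[tokenSequences(syn$corpus)[[1]]])),
    vocab = list(d0 = vocabulary(syn$corpus)))
  z <- dmmAssign(fit, sub, mode = "map")
  expect_identical(as.integer(z), assignments(fit)[1])
  # invariant to token order
  subShuf <- TokenCorpus(
    ids = "probe",
    tokens = list(d0 = list(rev(vocabulary(syn$corpus)[tokenSequences(syn$corpus)[[1]]]))),
    vocab = list(d0 = vocabulary(syn$corpus)))
  expect_identical(as.integer(dmmAssign(fit, subShuf, mode = "map")),
                   as.integer(z))
  # empty segment: prior argmax
  empty <- TokenCorpus(ids = "e", tokens = list(d0 = list(character(0))),
                       vocab = list(d0 = vocabulary(syn$corpus)))
  expect_identical(as.integer(dmmAssign(fit, empty, mode = "map")),
                   which.max(clusterSizes(fit) + fit@alpha))
  # fully out-of-vocabulary segment: warned, counted, prior assignment
  oov <- TokenCorpus(ids = "o", tokens = list(d0 = list(c("zz", "zz"))))
  expect_warning(zo <- dmmAssign(fit, oov, mode = "map"), "out-of-vocabulary")
  expect_identical(attr(zo, "oovCount"), 2L)
  expect_identical(as.integer(zo), which.max(clusterSizes(fit) + fit@alpha))
  # gibbs mode is seed-deterministic
  g1 <- dmmAssign(fit, sub, mode = "gibbs", iterations = 10, seed = 4)
  g2 <- dmmAssign(fit, sub, mode = "gibbs", iterations = 10, seed = 4)
  expect_identical(as.integer(g1), as.integer(g2))
})

test_that("estimated cluster count is the occupied-cluster count", {
  corpus <- smallRandomCorpus(31, M = 6, nStreams = 1, V = 4)
  fit <- dmmFit(corpus, K = 10, iterations = 3, seed = 1)
  expect_identical(estimatedClusterCount(fit),
                   sum(tabulate(assignments(fit), 10) > 0))
  expect_lte(estimatedClusterCount(fit), min(10, 6))
})

test_that("surplus capacity leaves the recovered cluster count stable", {
  syn <- generateCorpus(KTrue = 4, M = 120, streams = 2, V = 80,
                        beta = 0.05, segmentLength = 60, seed = 6)
  atTrue <- dmmFit(syn$corpus, K = 4, iterations = 30, seed = 9)
  atQuad <- dmmFit(syn$corpus, K = 16, iterations = 30, seed = 9)
  expect_lte(estimatedClusterCount(atQuad),
             estimatedClusterCount(atTrue) + 2)
})
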