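# Independent oracles for the probabilistic core, deliberately written
# along different code paths than the implementation: brute-force
# enumeration of the collapsed joint, explicit rising-factorial products,
# and a sequential Polya-urn evaluation of the marginal.

# a small random multi-stream corpus with ragged segment lengths
smallRandomCorpus <- function(seed, M = 4, nStreams = 2, V = 5, maxLen = 7) {
  set.seed(seed)
  sn <- paste0("s", seq_len(nStreams))
  vocab <- setNames(lapply(seq_len(nStreams), function(s)
    paste0("w", seq_len(V))), sn)
  tokens <- setNames(lapply(sn, function(s)
    lapply(seq_len(M), function(m) {
      n <- sample(0:maxLen, 1)
      if (!n) character(0) else sample(vocab[[s]], n, replace = TRUE)
    })), sn)
  TokenCorpus(ids = paste0("seg", seq_len(M)), tokens = tokens, vocab = vocab)
}

# conditional for segment m by evaluating the full collapsed joint for
# each candidate cluster (the numerators of the exact conditional)
bruteForceConditional <- function(corpus, z, m, alpha, beta, K) {
  lw <- vapply(seq_len(K), function(k) {
    z2 <- z
    z2[m] <- k
    jointLogProb(corpus, z2, alpha, beta, K = K)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w / sum(w)
}

# conditional from the explicit rising-factorial products, no log-gamma
directProductConditional <- function(corpus, z, m, alpha, beta, K) {
  M <- nSegments(corpus)
  alpha <- rep(alpha, length.out = K)
  w <- numeric(K)
  for (k in seq_len(K)) {
    tauK <- sum(z[-m] == k)
    val <- (tauK + alpha[k]) / (M - 1 + sum(alpha))
    for (s in streamNames(corpus)) {
      V <- length(vocabulary(corpus, s))
      betaV <- rep(beta, length.out = V)
      omK <- numeric(V)
      for (j in setdiff(seq_len(M), m))
        if (z[j] == k)
          omK <- omK + tabulate(tokenSequences(corpus, s)[[j]], nbins = V)
      x <- tabulate(tokenSequences(corpus, s)[[m]], nbins = V)
      num <- 1
      for (v in which(x > 0))
        for (l in seq_len(x[v]))
          num <- num * (omK[v] + betaV[v] + l - 1)
      den <- 1
      nm <- sum(x)
      if (nm > 0)
        for (n in seq_len(nm))
          den <- den * (sum(omK) + sum(betaV) + n - 1)
      val <- val * num / den
    }
    w[k] <- val
  }
  w / sum(w)
}

# log marginal P(tokens) by sequential Polya-urn predictive probabilities
# for a *given* assignment sequence, then log-sum-exp over all K^M
polyaUrnLogMarginal <- function(corpus, alpha, beta, K) {
  M <- nSegments(corpus)
  alpha <- rep(alpha, length.out = K)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  perZ <- apply(grid, 1, function(z) {
    lp <- 0
    nAssigned <- 0
    counts <- lapply(streamNames(corpus), function(s)
      matrix(0, K, length(vocabulary(corpus, s))))
    names(counts) <- streamNames(corpus)
    tauSoFar <- numeric(K)
    for (m in seq_len(M)) {
      k <- z[m]
      lp <- lp + log((tauSoFar[k] + alpha[k]) / (nAssigned + sum(alpha)))
      tauSoFar[k] <- tauSoFar[k] + 1
      nAssigned <- nAssigned + 1
      for (s in streamNames(corpus)) {
        V <- length(vocabulary(corpus, s))
        betaV <- rep(beta, length.out = V)
        inSeg <- numeric(V)
        for (v in tokenSequences(corpus, s)[[m]]) {
          lp <- lp + log((counts[[s]][k, v] + inSeg[v] + betaV[v]) /
                         (sum(counts[[s]][k, ]) + sum(inSeg) + sum(betaV)))
          inSeg[v] <- inSeg[v] + 1
        }
        counts[[s]][k, ] <- counts[[s]][k, ] + inSeg
      }
    }
    lp
  })
  mx <- max(perZ)
  mx + log(sum(exp(perZ - mx)))
}

# log multinomial coefficient
logMultinomCoef <- function(x) lgamma(sum(x) + 1) - sum(lgamma(x + 1))

# all count vectors of length V summing to N
allCountVectors <- function(V, N) {
  if (V == 1) return(matrix(N, ncol = 1))
  out <- NULL
  for (i in 0:N) {
    rest <- allCountVectors(V - 1, N - i)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}
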