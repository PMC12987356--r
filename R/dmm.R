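# The probabilistic core: Dirichlet multinomial (DM) likelihoods, the
# multi-stream collapsed joint, the collapsed Gibbs conditional, fitting
# by Gibbs sweeps (C++ inner loop) and held-out assignment.
#
# All probability arithmetic is in log space through log-gamma; the
# rising-factorial products in the collapsed conditional are evaluated as
# lgamma(omega + beta + n) - lgamma(omega + beta), which stays stable for
# the large denominators that a large vocabulary produces.

#' Dirichlet multinomial log pmf
#'
#' Log probability of a count vector under the compound of a multinomial
#' with a Dirichlet prior on its parameter:
#' `log G(N+1) + log G(b.) - log G(b.+N)
#'  + sum_v (log G(x_v+b_v) - log G(x_v+1) - log G(b_v))`
#' with `N = sum(x)` and `b. = sum(beta)`. This heavy-tailed pmf is what
#' lets the mixture capture burstiness: for large `x_v` with the other
#' counts fixed it decays like `x_v^(b_v - b.)`, a power law rather than
#' the exponential decay of a multinomial.
#'
#' @param x non-negative integer count vector (length V).
#' @param beta strictly positive concentration vector (length V or
#'   scalar, expanded).
#' @return log probability (finite for all valid inputs).
#' @seealso [dmSequenceLogProb()] for the sequence (no multinomial
#'   coefficient) variant.
#' @export
dmLogPmf <- function(x, beta) {
  if (any(x < 0) || any(x != floor(x))) stopf("x must be non-negative integers")
  beta <- expandPositive(beta, length(x), "beta")
  if (length(beta) != length(x)) stopf("x and beta must have equal length")
  N <- sum(x)
  lgamma(N + 1) + lgamma(sum(beta)) - lgamma(sum(beta) + N) +
    sum(lgamma(x + beta) - lgamma(x + 1) - lgamma(beta))
}

#' Dirichlet multinomial log probability of one token sequence
#'
#' The sequence variant of [dmLogPmf()]: the probability of observing one
#' particular token ordering with counts `x`, i.e.
#' `log B(x + beta) - log B(beta)` with `B` the multivariate beta
#' function. Equals `dmLogPmf(x, beta)` minus the log multinomial
#' coefficient; the all-zero count vector gives 0.
#'
#' @inheritParams dmLogPmf
#' @return log probability.
#' @export
dmSequenceLogProb <- function(x, beta) {
  if (any(x < 0) || any(x != floor(x))) stopf("x must be non-negative integers")
  beta <- expandPositive(beta, length(x), "beta")
  logBeta(x + beta) - logBeta(beta)
}

#' Collapsed log joint of a multi-stream DMM
#'
#' Log of `P(Z | alpha) * prod_streams P(stream | Z, beta_stream)` with
#' the mixture weights and all per-cluster emission distributions
#' integrated out:
#' `log B(tau + alpha) - log B(alpha)
#'  + sum_s sum_k (log B(omega_k + beta_k) - log B(beta_k))`.
#' Because only counts enter, the value is invariant to permuting tokens
#' within a segment, and to permuting segments together with their
#' assignments.
#'
#' @param corpus a [TokenCorpus-class].
#' @param z integer vector of 1-based cluster assignments (length M).
#' @param alpha scalar or length-K Dirichlet prior on cluster weights.
#' @param beta per-stream emission prior: scalar (shared), or a named
#'   list with, per stream, a scalar, length-V vector or K x V matrix.
#' @param K number of clusters (default `max(z)`).
#' @return log probability.
#' @export
jointLogProb <- function(corpus, z, alpha, beta, K = max(z)) {
  stopifnot(is(corpus, "TokenCorpus"))
  z <- as.integer(z)
  if (length(z) != length(corpus@ids))
    stopf("assignments must have one entry per segment")
  if (any(z < 1L) || any(z > K)) stopf("assignments must lie in [1, K]")
  hyper <- expandHyper(corpus, K, alpha, beta)
  ct <- countTables(corpus, z, K)
  lp <- logBeta(ct$tau + hyper$alpha) - logBeta(hyper$alpha)
  for (s in names(corpus@vocab)) {
    B <- hyper$beta[[s]]
    om <- ct$omega[[s]]
    for (k in seq_len(K))
      lp <- lp + logBeta(om[k, ] + B[k, ]) - logBeta(B[k, ])
  }
  lp
}

# expand user-facing (alpha, beta) to length-K vector and per-stream
# K x V matrices for a given corpus
expandHyper <- function(corpus, K, alpha, beta) {
  alpha <- expandPositive(alpha, K, "alpha")
  sn <- names(corpus@vocab)
  if (!is.list(beta)) beta <- setNames(rep(list(beta), length(sn)), sn)
  betaM <- lapply(sn, function(s)
    expandBetaMatrix(beta[[s]] %||% stopf("no beta for stream '%s'", s),
                     K, length(corpus@vocab[[s]]),
                     sprintf("beta[['%s']]", s)))
  names(betaM) <- sn
  list(alpha = alpha, beta = betaM)
}

#' Collapsed Gibbs full conditional for one segment
#'
#' Probability vector over clusters for resampling segment `m` given all
#' other assignments, with segment `m`'s contribution removed from the
#' count tables internally. The k-th unnormalized log weight is
#' `log(tau_k\\m + alpha_k)` plus, per stream, the log ratio of rising
#' factorials
#' `sum_v (lgamma(omega_kv\\m + beta_kv + n_mv) - lgamma(omega_kv\\m + beta_kv))
#'  - (lgamma(omega_k.\\m + beta_k. + n_m) - lgamma(omega_k.\\m + beta_k.))`,
#' where `n_mv` are segment `m`'s per-word counts. A segment with no
#' tokens in any stream reduces to the occupancy prior alone. The
#' returned vector sums to one.
#'
#' This is the reference (pure R) implementation of the conditional; the
#' sweep sampler in [dmmFit()] evaluates the same quantity in C++.
#'
#' @param corpus a [TokenCorpus-class].
#' @param z current assignment vector (1-based, length M).
#' @param m segment index in `[1, M]`.
#' @inheritParams jointLogProb
#' @return numeric length-K probability vector.
#' @export
gibbsConditional <- function(corpus, z, m, alpha, beta, K = max(z)) {
  m <- as.integer(m)
  M <- length(corpus@ids)
  if (m < 1L || m > M) stopf("segment index m out of range")
  hyper <- expandHyper(corpus, K, alpha, beta)
  ct <- countTables(corpus, z, K)
  tau <- ct$tau
  tau[z[m]] <- tau[z[m]] - 1
  logw <- log(tau + hyper$alpha)
  for (s in names(corpus@vocab)) {
    x <- segmentCountVector(corpus, s, m)
    om <- ct$omega[[s]]
    om[z[m], ] <- om[z[m], ] - x
    B <- hyper$beta[[s]]
    nm <- sum(x)
    if (nm == 0) next
    pos <- which(x > 0)
    for (k in seq_len(K)) {
      a <- om[k, pos] + B[k, pos]
      logw[k] <- logw[k] +
        sum(lgamma(a + x[pos]) - lgamma(a)) -
        (lgamma(sum(om[k, ]) + sum(B[k, ]) + nm) -
         lgamma(sum(om[k, ]) + sum(B[k, ])))
    }
  }
  w <- exp(logw - logSumExp(logw))
  w / sum(w)
}

#' Fit a multi-stream DMM by collapsed Gibbs sampling
#'
#' Assignments are initialized independently and uniformly at random,
#' then resampled segment by segment (in segment order) from the
#' collapsed full conditional for `iterations` full sweeps, with the
#' count tables updated incrementally. The final clustering is the
#' assignment vector after the last sweep; no posterior averaging is
#' done, which keeps cluster identities stable for the majority-vote
#' protocol. Runs are bit-reproducible: the fit owns the RNG, seeded
#' explicitly, and identical `(corpus, hyperparameters, K, iterations,
#' seed)` give identical results. When `K` is chosen generously the
#' sampler leaves surplus clusters empty, so the effective number of
#' clusters is determined by the data rather than by `K`.
#'
#' Per sweep and segment the conditional costs O(K L S) with L streams
#' and S tokens per segment; the count tables occupy O(K L V).
#'
#' @param corpus a [TokenCorpus-class].
#' @param K maximum number of clusters.
#' @param alpha cluster-weight Dirichlet prior (scalar symmetric by
#'   default, 1.0).
#' @param beta emission Dirichlet prior (scalar symmetric by default,
#'   0.1; values below 1 induce the sparse, bursty regime the model
#'   targets). Scalar, per-stream list, vector or K x V matrices accepted.
#' @param iterations number of full Gibbs sweeps (>= 1; default 50).
#' @param seed integer RNG seed (required unless resuming).
#' @param recordHistory keep the assignment vector after every sweep in
#'   the model's `history` slot.
#' @param resume a previously fitted [DmmModel-class]: sampling continues
#'   from its assignments and stored RNG state, exactly as if the
#'   original run had not stopped (hyperparameters and `K` are taken from
#'   the resumed model).
#' @param verbose log one line per sweep (sweep, log joint, non-empty
#'   clusters) to standard error.
#' @return A fitted [DmmModel-class].
#' @examples
#' syn <- generateCorpus(KTrue = 2, M = 40, streams = "d0", V = 30,
#'                       beta = 0.05, segmentLength = 30,
#'                       mode = "disjoint-support", seed = 1)
#' fit <- dmmFit(syn$corpus, K = 5, iterations = 20, seed = 1)
#' estimatedClusterCount(fit)
#' @export
dmmFit <- function(corpus, K, alpha = 1, beta = 0.1, iterations = 50L,
                   seed = NULL, recordHistory = FALSE, resume = NULL,
                   verbose = FALSE) {
  stopifnot(is(corpus, "TokenCorpus"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stopf("iterations must be >= 1")
  M <- length(corpus@ids)
  if (!is.null(resume)) {
    stopifnot(is(resume, "DmmModel"))
    if (!identical(resume@vocab, corpus@vocab))
      stopf("resumed model was fitted on a corpus with different vocabularies")
    K <- resume@K
    hyper <- list(alpha = resume@alpha, beta = resume@beta)
    assign(".Random.seed", resume@rngState, envir = globalenv())
    z0 <- resume@assignments
    seedUsed <- resume@seed
  } else {
    if (is.null(seed)) stopf("seed must be supplied for a fresh fit")
    K <- as.integer(K)
    if (is.na(K) || K < 1L) stopf("K must be >= 1")
    hyper <- expandHyper(corpus, K, alpha, beta)
    set.seed(as.integer(seed))
    z0 <- sample.int(K, M, replace = TRUE)
    seedUsed <- as.integer(seed)
  }
  sn <- names(corpus@vocab)
  segWords <- vector("list", length(sn))
  segCnts <- vector("list", length(sn))
  sparse <- segmentSparseCounts(corpus)
  for (i in seq_along(sn)) {
    segWords[[i]] <- lapply(sparse[[sn[i]]], function(p) p$idx - 1L)
    segCnts[[i]] <- lapply(sparse[[sn[i]]], function(p) as.integer(p$cnt))
  }
  res <- cppGibbsFit(segWords, segCnts,
                     vapply(sn, function(s) length(corpus@vocab[[s]]), integer(1)),
                     K, hyper$alpha, unname(hyper$beta[sn]),
                     z0 - 1L, iterations, isTRUE(recordHistory),
                     isTRUE(verbose))
  omega <- res$omega
  names(omega) <- sn
  history <- if (isTRUE(recordHistory)) res$history + 1L else emptyHistory()
  model <- new("DmmModel",
    K = K,
    alpha = hyper$alpha,
    beta = hyper$beta,
    tau = as.numeric(res$tau),
    omega = omega,
    assignments = as.integer(res$z) + 1L,
    vocab = corpus@vocab,
    seed = seedUsed,
    iterationsRun = as.integer(iterations +
      if (is.null(resume)) 0L else resume@iterationsRun),
    logJointTrace = c(if (is.null(resume)) numeric(0) else resume@logJointTrace,
                      as.numeric(res$logJoint)),
    history = history,
    rngState = get(".Random.seed", envir = globalenv()))
  checkModelCounts(model, corpus)
  validObject(model)
  model
}

#' Number of non-empty clusters of a fitted model
#'
#' The sampler's effective model size: `|{k : tau_k > 0}|`. Never exceeds
#' `min(K, M)`.
#'
#' @param model a [DmmModel-class].
#' @return integer count of occupied clusters.
#' @export
estimatedClusterCount <- function(model) {
  stopifnot(is(model, "DmmModel"))
  sum(model@tau > 0)
}

#' Assign held-out segments to clusters of a fitted model
#'
#' Tokens are first mapped into the model's vocabularies;
#' out-of-vocabulary tokens carry no probability under the model and are
#' dropped (their count is returned). Two modes:
#' \describe{
#'   \item{`map`}{argmax of the collapsed conditional computed against
#'     the training counts with the segment held out (nothing to
#'     decrement); ties broken toward the lowest cluster index; invariant
#'     to token order. Deterministic, no RNG used.}
#'   \item{`gibbs`}{`iterations` resampling draws from that conditional,
#'     the segment's own counts added after each draw and removed before
#'     the next; the final draw is returned. Deterministic given `seed`.}
#' }
#' A segment whose streams are all empty (or fully out-of-vocabulary) is
#' still assigned, from the cluster-occupancy prior factor alone.
#'
#' @param model a fitted [DmmModel-class].
#' @param corpus a [TokenCorpus-class] of segments to assign (streams must
#'   be named as in the model).
#' @param mode `"map"` or `"gibbs"`.
#' @param iterations resampling steps for `mode = "gibbs"`.
#' @param seed RNG seed for `mode = "gibbs"`.
#' @return integer vector of 1-based cluster indices, one per segment,
#'   with attribute `oovCount` giving the number of dropped tokens per
#'   segment.
#' @export
dmmAssign <- function(model, corpus, mode = c("map", "gibbs"),
                      iterations = 50L, seed = NULL) {
  stopifnot(is(model, "DmmModel"), is(corpus, "TokenCorpus"))
  mode <- match.arg(mode)
  sn <- names(model@vocab)
  missing <- setdiff(sn, names(corpus@vocab))
  if (length(missing))
    stopf("corpus lacks stream '%s' required by the model", missing[1L])
  M <- length(corpus@ids)
  K <- model@K
  if (mode == "gibbs") {
    if (is.null(seed)) stopf("seed must be supplied for gibbs-mode assignment")
    set.seed(as.integer(seed))
    iterations <- as.integer(iterations)
    if (iterations < 1L) stopf("iterations must be >= 1")
  }
  out <- integer(M)
  oov <- integer(M)
  Mtrain <- length(model@assignments)
  for (m in seq_len(M)) {
    logw <- log(model@tau + model@alpha) - log(Mtrain + sum(model@alpha))
    nOov <- 0L
    for (s in sn) {
      w <- corpus@vocab[[s]][corpus@tokens[[s]][[m]]]
      idx <- match(w, model@vocab[[s]])
      nOov <- nOov + sum(is.na(idx))
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      t <- tabulate(idx, nbins = length(model@vocab[[s]]))
      pos <- which(t > 0)
      B <- model@beta[[s]]
      om <- model@omega[[s]]
      nm <- sum(t)
      for (k in seq_len(K)) {
        a <- om[k, pos] + B[k, pos]
        logw[k] <- logw[k] + sum(lgamma(a + t[pos]) - lgamma(a)) -
          (lgamma(sum(om[k, ]) + sum(B[k, ]) + nm) -
           lgamma(sum(om[k, ]) + sum(B[k, ])))
      }
    }
    if (nOov > 0L)
      warning(sprintf("segment '%s': dropped %d out-of-vocabulary token(s)",
                      corpus@ids[m], nOov), call. = FALSE)
    oov[m] <- nOov
    p <- exp(logw - logSumExp(logw))
    if (mode == "map") {
      out[m] <- which.max(p)  # which.max takes the lowest index on ties
    } else {
      draw <- NA_integer_
      for (it in seq_len(iterations))
        draw <- sample.int(K, 1L, prob = p)
      out[m] <- draw
    }
  }
  attr(out, "oovCount") <- oov
  out
}
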