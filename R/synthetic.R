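# Synthetic corpora drawn from the model's own generative process, with
# known ground truth, so the sampler and the evaluation protocol can be
# exercised without any external recordings.

rdirichlet1 <- function(a) {
  g <- rgamma(length(a), shape = a, rate = 1)
  if (sum(g) == 0) g[which.max(a)] <- 1  # degenerate guard for tiny a
  g / sum(g)
}

#' Generate a multi-stream corpus from the DMM generative process
#'
#' Draws `theta ~ Dirichlet(alpha)`, component labels
#' `z_m ~ Categorical(theta)` i.i.d., one emission distribution
#' `phi_k ~ Dirichlet(beta)` per component and stream (drawn once per
#' component, so burstiness lives at the activity level), and then each
#' segment's tokens i.i.d. `Categorical(phi_{z_m})` per stream. In
#' `disjoint-support` mode each stream's vocabulary is instead
#' partitioned into `KTrue` blocks and component k's emission
#' distribution is supported only on block k — the maximal-separation
#' fixture. Labels of the returned corpus are the true component ids;
#' everything is deterministic given `seed`.
#'
#' @param KTrue number of mixture components.
#' @param M number of segments.
#' @param streams stream names (or an integer count).
#' @param V vocabulary size per stream (scalar or per-stream vector).
#' @param beta emission Dirichlet concentration (scalar; small values,
#'   e.g. 0.05, give sparse bursty components).
#' @param alpha mixture-weight Dirichlet concentration (scalar or
#'   length-`KTrue`).
#' @param segmentLength tokens per segment per stream: a single number,
#'   or a length-2 range `c(lo, hi)` sampled uniformly per segment.
#' @param mode `"shared-dirichlet"` (default) or `"disjoint-support"`.
#' @param seed integer seed.
#' @return list with `corpus` (a [TokenCorpus-class], labels = true
#'   components as `"k<j>"`) and `truth` (list: `theta`, `z` (1-based),
#'   per-stream `phi` matrices KTrue x V).
#' @export
generateCorpus <- function(KTrue, M, streams = c("d0", "d+30", "d-30"),
                           V = 200L, beta = 0.05, alpha = 1,
                           segmentLength = 100L,
                           mode = c("shared-dirichlet", "disjoint-support"),
                           seed) {
  mode <- match.arg(mode)
  KTrue <- as.integer(KTrue); M <- as.integer(M)
  if (KTrue < 1L || M < 1L) stopf("KTrue and M must be >= 1")
  if (is.numeric(streams)) streams <- paste0("s", seq_len(streams))
  L <- length(streams)
  V <- rep(as.integer(V), length.out = L)
  if (any(V < 1L)) stopf("V must be >= 1")
  if (beta <= 0) stopf("beta must be > 0")
  alpha <- expandPositive(alpha, KTrue, "alpha")
  segmentLength <- as.integer(segmentLength)
  if (any(segmentLength < 0L)) stopf("segmentLength must be non-negative")
  set.seed(as.integer(seed))

  theta <- rdirichlet1(alpha)
  z <- sample.int(KTrue, M, replace = TRUE, prob = theta)
  phi <- vector("list", L)
  names(phi) <- streams
  vocab <- vector("list", L)
  names(vocab) <- streams
  for (s in seq_len(L)) {
    vocab[[s]] <- paste0("w", seq_len(V[s]))
    P <- matrix(0, nrow = KTrue, ncol = V[s])
    if (mode == "shared-dirichlet") {
      for (k in seq_len(KTrue)) P[k, ] <- rdirichlet1(rep(beta, V[s]))
    } else {
      if (V[s] < KTrue) stopf("disjoint-support needs V >= KTrue")
      block <- rep(seq_len(KTrue), length.out = V[s])
      block <- sort(block)
      for (k in seq_len(KTrue)) {
        idx <- which(block == k)
        P[k, idx] <- rdirichlet1(rep(beta, length(idx)))
      }
    }
    phi[[s]] <- P
  }
  tokens <- vector("list", L)
  names(tokens) <- streams
  lens <- if (length(segmentLength) >= 2L)
    sample(segmentLength[1L]:segmentLength[2L], M, replace = TRUE)
  else rep(segmentLength[1L], M)
  for (s in seq_len(L)) {
    tokens[[s]] <- lapply(seq_len(M), function(m) {
      n <- lens[m]
      if (n == 0L) return(character(0))
      vocab[[s]][sample.int(V[s], n, replace = TRUE, prob = phi[[s]][z[m], ])]
    })
  }
  corpus <- TokenCorpus(ids = sprintf("seg%04d", seq_len(M)),
                        tokens = tokens,
                        labels = paste0("k", z),
                        vocab = vocab)
  list(corpus = corpus, truth = list(theta = theta, z = z, phi = phi))
}

#' Burstiness fixture: a sparse-emission corpus with activity structure
#'
#' A convenience wrapper around [generateCorpus()] whose defaults are
#' built for the word-count diagnostics: a single stream with a 500-word
#' vocabulary, emission concentration 0.05 (well inside the bursty
#' regime), and 60 activities of 10 segments each with 500 tokens per
#' segment. Within an activity the few words its emission distribution
#' concentrates on recur heavily, so word counts per counting unit show
#' a much heavier tail than a multinomial matched on mean frequencies.
#' The relatively large number of small activities mirrors, at desk
#' scale, the frequency dilution of a long recording: a word that is
#' globally rare because it belongs to one activity among many still
#' bursts well past the multinomial's reach inside that activity, which
#' is exactly the contrast the diagnostic quantifies.
#'
#' @param KTrue,M,V,beta,segmentLength,streams see [generateCorpus()];
#'   `beta` must be at most 0.1 (the fixture exists to exercise the
#'   bursty regime).
#' @param seed integer seed.
#' @return as [generateCorpus()].
#' @export
burstinessFixture <- function(seed, KTrue = 60L, M = 600L, V = 500L,
                              beta = 0.05, segmentLength = 500L,
                              streams = "d0") {
  if (beta > 0.1) stopf("burstinessFixture requires beta <= 0.1")
  generateCorpus(KTrue = KTrue, M = M, streams = streams, V = V,
                 beta = beta, alpha = 1, segmentLength = segmentLength,
                 mode = "shared-dirichlet", seed = seed)
}

#' Complementary-streams fixture: jointly separable, singly ambiguous
#'
#' Generates a 4-component, 3-stream corpus in which every single stream
#' is only weakly informative but the streams jointly identify all
#' components: in each stream the four components are paired up and the
#' two components of a pair share the *same* emission distribution
#' (pairs differ per stream — {1,2}/{3,4}, {1,3}/{2,4}, {1,4}/{2,3} — and
#' each pair owns a disjoint half of the stream's vocabulary). Any one
#' stream can therefore separate at most two super-groups, while the
#' intersection of the three pairings pins down each component exactly.
#'
#' @param M number of segments.
#' @param V vocabulary size per stream.
#' @param beta within-block emission concentration.
#' @param segmentLength tokens per segment per stream.
#' @param seed integer seed.
#' @return as [generateCorpus()] (`KTrue` fixed at 4, streams
#'   `"sA","sB","sC"`).
#' @export
complementaryStreamsCorpus <- function(M = 200L, V = 100L, beta = 0.05,
                                       segmentLength = 50L, seed) {
  set.seed(as.integer(seed))
  KTrue <- 4L
  pairings <- list(c(1L, 1L, 2L, 2L),   # stream sA merges {1,2} and {3,4}
                   c(1L, 2L, 1L, 2L),   # stream sB merges {1,3} and {2,4}
                   c(1L, 2L, 2L, 1L))   # stream sC merges {1,4} and {2,3}
  streams <- c("sA", "sB", "sC")
  M <- as.integer(M); V <- as.integer(V)
  z <- sample.int(KTrue, M, replace = TRUE)
  vocab <- list(); phi <- list(); tokens <- list()
  for (s in seq_along(streams)) {
    vocab[[streams[s]]] <- paste0("w", seq_len(V))
    half <- V %/% 2L
    blocks <- list(seq_len(half), (half + 1L):V)
    groupPhi <- lapply(1:2, function(g) {
      p <- numeric(V)
      p[blocks[[g]]] <- rdirichlet1(rep(beta, length(blocks[[g]])))
      p
    })
    P <- matrix(0, nrow = KTrue, ncol = V)
    for (k in seq_len(KTrue)) P[k, ] <- groupPhi[[pairings[[s]][k]]]
    phi[[streams[s]]] <- P
    tokens[[streams[s]]] <- lapply(seq_len(M), function(m)
      vocab[[streams[s]]][sample.int(V, segmentLength, replace = TRUE,
                                     prob = P[z[m], ])])
  }
  corpus <- TokenCorpus(ids = sprintf("seg%04d", seq_len(M)),
                        tokens = tokens, labels = paste0("k", z),
                        vocab = vocab)
  list(corpus = corpus, truth = list(z = z, phi = phi, pairings = pairings))
}

#' Matched-mean multinomial reference corpus
#'
#' Resamples a corpus in which every unit keeps its total token count but
#' tokens are drawn i.i.d. from the pooled per-word frequencies, i.e. a
#' multinomial with the same per-word means and unit sizes as the input
#' but none of its burstiness. Used as the reference in
#' [burstinessReport()].
#'
#' @param corpus a [TokenCorpus-class].
#' @param stream stream to resample.
#' @param seed integer seed.
#' @return a [TokenCorpus-class] with the same ids/labels and one stream.
#' @export
matchedMultinomialCorpus <- function(corpus, stream, seed) {
  if (missing(stream)) stream <- names(corpus@vocab)[1L]
  stream <- matchStream(corpus, stream)
  set.seed(as.integer(seed))
  counts <- vocabularyCounts(corpus, stream)
  p <- counts / sum(counts)
  voc <- corpus@vocab[[stream]]
  tokens <- lapply(corpus@tokens[[stream]], function(w) {
    n <- length(w)
    if (!n) return(character(0))
    voc[sample.int(length(voc), n, replace = TRUE, prob = p)]
  })
  TokenCorpus(ids = corpus@ids, tokens = setNames(list(tokens), stream),
              labels = corpus@labels, folds = corpus@folds,
              vocab = setNames(list(voc), stream))
}
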