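# Sufficient-statistic helpers: per-segment sparse counts and the
# cluster-level count tables tau / omega recomputed from assignments.

# per stream, per segment: list(idx = distinct 1-based word ids, cnt = counts)
segmentSparseCounts <- function(corpus) {
  lapply(corpus@tokens, function(seqs) {
    lapply(seqs, function(w) {
      if (!length(w)) return(list(idx = integer(0), cnt = integer(0)))
      t <- tabulate(w)
      idx <- which(t > 0L)
      list(idx = idx, cnt = t[idx])
    })
  })
}

# dense count vector (length V) for one segment in one stream
segmentCountVector <- function(corpus, stream, m) {
  V <- length(corpus@vocab[[stream]])
  tabulate(corpus@tokens[[stream]][[m]], nbins = V)
}

# recompute (tau, omega) from assignments; the reference for all
# incremental bookkeeping
countTables <- function(corpus, z, K) {
  M <- length(corpus@ids)
  stopifnot(length(z) == M)
  tau <- as.numeric(tabulate(z, nbins = K))
  omega <- lapply(names(corpus@vocab), function(s) {
    V <- length(corpus@vocab[[s]])
    om <- matrix(0, nrow = K, ncol = V)
    for (m in seq_len(M)) {
      w <- corpus@tokens[[s]][[m]]
      if (length(w)) {
        t <- tabulate(w, nbins = V)
        om[z[m], ] <- om[z[m], ] + t
      }
    }
    om
  })
  names(omega) <- names(corpus@vocab)
  list(tau = tau, omega = omega)
}

# exact agreement between a model's stored tables and their recomputation
checkModelCounts <- function(model, corpus) {
  ct <- countTables(corpus, model@assignments, model@K)
  if (!isTRUE(all.equal(ct$tau, model@tau)))
    stopf("model integrity: tau disagrees with recomputation from assignments")
  for (s in names(model@omega)) {
    if (!isTRUE(all.equal(unname(ct$omega[[s]]), unname(model@omega[[s]]))))
      stopf("model integrity: omega['%s'] disagrees with recomputation", s)
  }
  invisible(TRUE)
}
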