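# Burstiness diagnostics: frequency-grouped word-count probability curves
# on log-log axes, against a matched-mean multinomial reference. A
# multinomial count decays exponentially (a straight descending line on a
# semi-log plot); bursty Dirichlet-compound counts decay like a power law
# (straight on log-log), and the diagnostic makes that contrast visible
# and quantifiable.

#' Empirical per-word count distributions
#'
#' For each word of a stream, the empirical distribution of its
#' occurrence count across counting units. With `unit = "segment"` every
#' segment is one unit; with `unit = "block"` all segments sharing a
#' label (activity) are pooled into one unit per activity, so counts are
#' per-activity totals. Grouping `"label"` takes strata from segment
#' labels, `"cluster"` from a supplied assignment vector.
#'
#' @param corpus a [TokenCorpus-class].
#' @param stream stream name (default: first stream).
#' @param unit `"segment"` or `"block"`.
#' @param grouping `"label"` (default) or `"cluster"`.
#' @param clusters integer assignment vector, required when
#'   `grouping = "cluster"`.
#' @return integer matrix (words x units) of occurrence counts, with the
#'   per-word empirical count pmf derivable by tabulating rows; rows are
#'   named by word string.
#' @export
countDistribution <- function(corpus, stream,
                              unit = c("segment", "block"),
                              grouping = c("label", "cluster"),
                              clusters = NULL) {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping)
  if (missing(stream)) stream <- names(corpus@vocab)[1L]
  stream <- matchStream(corpus, stream)
  strata <- if (grouping == "label") corpus@labels else {
    if (is.null(clusters)) stopf("grouping = 'cluster' needs a clusters vector")
    as.character(clusters)
  }
  if (all(is.na(strata)))
    stopf("no %s information available for grouping", grouping)
  keep <- which(!is.na(strata))
  V <- length(corpus@vocab[[stream]])
  segCounts <- vapply(keep, function(m)
    tabulate(corpus@tokens[[stream]][[m]], nbins = V), numeric(V))
  if (is.null(dim(segCounts))) segCounts <- matrix(segCounts, nrow = V)
  if (unit == "segment") {
    out <- segCounts
    colnames(out) <- corpus@ids[keep]
  } else {
    f <- factor(strata[keep])
    out <- vapply(levels(f), function(lv)
      rowSums(segCounts[, f == lv, drop = FALSE]), numeric(V))
    if (is.null(dim(out))) out <- matrix(out, nrow = V,
                                         dimnames = list(NULL, levels(f)))
  }
  rownames(out) <- corpus@vocab[[stream]]
  out
}

# empirical pmf of one word's counts across units, as a named vector
# P(x) over x = 0..max; sums to one
countPmf <- function(countsRow) {
  t <- tabulate(countsRow + 1L)
  t / sum(t)
}

#' Frequency-grouped burstiness report
#'
#' Words are ranked by total corpus frequency (ties broken by word
#' string); the top `groupSizes[1]` form the frequent group, the bottom
#' `groupSizes[3]` the rare group, and a band of `groupSizes[2]` words
#' centered on the median rank forms the average group. Within each
#' group, the per-word empirical count pmfs (from [countDistribution()])
#' are averaged, giving a curve `P(count = x)` per group; a log-log
#' least-squares line and a semi-log line are fitted over the support
#' points with positive probability (x >= 1). The same curves are
#' computed for a matched-mean multinomial resampling of the corpus
#' ([matchedMultinomialCorpus()]), which preserves per-word means and
#' unit sizes but destroys burstiness, and tail masses
#' `P(count >= tailAt)` are reported for both.
#'
#' @param corpus a [TokenCorpus-class] with labels.
#' @param stream stream name (default: first stream).
#' @param groupSizes integer triple (frequent, average, rare); must sum
#'   to at most the vocabulary size and be pairwise non-overlapping.
#' @param unit counting unit, see [countDistribution()].
#' @param tailAt tail-mass threshold (default 10).
#' @param referenceSeed seed for the multinomial reference resampling.
#' @return object of class `BurstinessReport`: per group, the support
#'   `x`, averaged `p`, fitted log-log slope and R^2, semi-log R^2, tail
#'   mass, the group's word list, and the matching reference curve/tail.
#' @seealso [plotBurstiness()]
#' @export
burstinessReport <- function(corpus, stream, groupSizes,
                             unit = c("segment", "block"), tailAt = 10,
                             referenceSeed = 1L) {
  unit <- match.arg(unit)
  if (missing(stream)) stream <- names(corpus@vocab)[1L]
  stream <- matchStream(corpus, stream)
  counts <- vocabularyCounts(corpus, stream)
  W <- length(counts)
  groupSizes <- as.integer(groupSizes)
  if (length(groupSizes) != 3L || any(groupSizes < 1L))
    stopf("groupSizes must be three positive integers")
  if (sum(groupSizes) > W)
    stopf("group sizes (%d) exceed vocabulary size (%d)", sum(groupSizes), W)
  ord <- order(-counts, names(counts), method = "radix")
  ranked <- names(counts)[ord]
  nf <- groupSizes[1L]; na_ <- groupSizes[2L]; nr <- groupSizes[3L]
  freqWords <- ranked[seq_len(nf)]
  rareWords <- ranked[(W - nr + 1L):W]
  mid <- (nf + (W - nr)) / 2            # center of the unclaimed band
  aStart <- max(nf + 1L, min(floor(mid - na_ / 2) + 1L, W - nr - na_ + 1L))
  avgWords <- ranked[aStart:(aStart + na_ - 1L)]
  if (length(intersect(avgWords, c(freqWords, rareWords))))
    stopf("groups overlap; reduce group sizes")

  cd <- countDistribution(corpus, stream, unit = unit)
  ref <- matchedMultinomialCorpus(corpus, stream, seed = referenceSeed)
  cdRef <- countDistribution(ref, stream, unit = unit)

  nUnits <- ncol(cd)
  groupCurve <- function(mat, words) {
    pmfs <- lapply(words, function(w) countPmf(mat[w, ]))
    xmax <- max(vapply(pmfs, length, integer(1)))
    padded <- vapply(pmfs, function(p) c(p, rep(0, xmax - length(p))),
                     numeric(xmax))
    avg <- rowMeans(matrix(padded, nrow = xmax))
    x <- seq_len(xmax - 1L)              # counts 1..xmax-1 (drop x = 0)
    p <- avg[-1L]
    keep <- p > 0
    list(x = x[keep], p = p[keep], nWords = length(words),
         tail = sum(avg[seq_along(avg) - 1L >= tailAt]))
  }
  # Slope fits use logarithmic binning (factor-1.5 bins), the standard
  # estimator for empirical power laws: per-integer probabilities deep in
  # the tail rest on a handful of observations and would otherwise
  # dominate the least-squares fit as pure noise. Binned points are kept
  # only above the empirical resolution floor (an averaged probability
  # supported by fewer than ~3 observations across the group carries no
  # shape information). The same binned points feed the log-log and the
  # semi-log fit so their R^2 are comparable.
  fitSlopes <- function(curve) {
    floorP <- 3 / (curve$nWords * nUnits)
    x <- curve$x
    p <- curve$p
    if (length(x) >= 3L) {
      edges <- 1
      while (tail(edges, 1L) <= max(x))
        edges <- c(edges, max(tail(edges, 1L) + 1, ceiling(tail(edges, 1L) * 1.5)))
      bin <- cut(x, breaks = c(edges - 0.5, Inf), labels = FALSE)
      bx <- as.numeric(tapply(x, bin, function(v) exp(mean(log(v)))))
      bp <- as.numeric(tapply(p, bin, mean))
      keep <- bp >= floorP
      if (sum(keep) >= 3L) {
        x <- bx[keep]
        p <- bp[keep]
      }
    }
    if (length(x) < 3L)
      return(list(slope = NA_real_, r2log = NA_real_, r2semi = NA_real_))
    fl <- lm(log(p) ~ log(x))
    fs <- lm(log(p) ~ x)
    # degenerate toy curves can fit exactly; the R^2 of 1 is then meaningful
    list(slope = unname(coef(fl)[2L]),
         r2log = suppressWarnings(summary(fl)$r.squared),
         r2semi = suppressWarnings(summary(fs)$r.squared))
  }
  groups <- list(frequent = freqWords, average = avgWords, rare = rareWords)
  out <- lapply(names(groups), function(g) {
    dm <- groupCurve(cd, groups[[g]])
    rf <- groupCurve(cdRef, groups[[g]])
    rfFit <- fitSlopes(rf)
    c(list(words = groups[[g]], x = dm$x, p = dm$p, tailMass = dm$tail,
           refX = rf$x, refP = rf$p, refTailMass = rf$tail,
           refSlope = rfFit$slope, refR2log = rfFit$r2log,
           refR2semi = rfFit$r2semi),
      fitSlopes(dm))
  })
  names(out) <- names(groups)
  structure(list(groups = out, stream = stream, unit = unit,
                 tailAt = tailAt, groupSizes = groupSizes),
            class = "BurstinessReport")
}

#' @export
print.BurstinessReport <- function(x, ...) {
  cat(sprintf("BurstinessReport (stream '%s', unit %s, tail at >= %g)\n",
              x$stream, x$unit, x$tailAt))
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %-8s n=%4d  log-log slope %7.3f (R2 %.3f; semi-log R2 %.3f)  tail %.4g vs ref %.4g\n",
                g, length(gr$words), gr$slope, gr$r2log, gr$r2semi,
                gr$tailMass, gr$refTailMass))
  }
  invisible(x)
}

#' Plot burstiness curves on log-log axes
#'
#' One panel per frequency group: averaged empirical `P(count = x)`
#' against `x`, both axes logarithmic, with the matched multinomial
#' reference dashed. Power-law (bursty) counts show as straight lines;
#' the multinomial reference drops off sharply.
#'
#' @param report a `BurstinessReport`.
#' @param ... passed to [graphics::plot()].
#' @return `report`, invisibly.
#' @export
plotBurstiness <- function(report, ...) {
  stopifnot(inherits(report, "BurstinessReport"))
  old <- graphics::par(mfrow = c(1, length(report$groups)))
  on.exit(graphics::par(old))
  for (g in names(report$groups)) {
    gr <- report$groups[[g]]
    if (!length(gr$x)) {               # all counts zero: nothing to draw
      graphics::plot.new()
      graphics::title(main = sprintf("%s (no positive counts)", g))
      next
    }
    graphics::plot(gr$x, gr$p, log = "xy", type = "b", pch = 16,
                   xlab = "count x", ylab = "P(x)", main = g, ...)
    if (length(gr$refX))
      graphics::lines(gr$refX, gr$refP, lty = 2, col = "grey40")
  }
  invisible(report)
}

#' Asymptotic power-law slope of the DM count tail
#'
#' With all other counts held fixed, the DM pmf of a single count `x_v`
#' behaves like `x_v^(beta_v - beta.)` for large `x_v`. This helper
#' evaluates `log P(x_v)` on a log-spaced grid via [dmLogPmf()] and
#' returns the least-squares slope of `log P` against `log x_v`, which
#' should approach `beta_v - sum(beta)`.
#'
#' @param beta positive concentration vector.
#' @param v index of the varying count.
#' @param otherCounts fixed counts for the remaining categories
#'   (length `length(beta) - 1`).
#' @param xRange range of `x_v` (default `c(1e3, 1e4)`).
#' @param nGrid grid points (default 25).
#' @return list with `slope`, the theoretical `exponent`
#'   (`beta_v - sum(beta)`) and the grid (`x`, `logP`).
#' @export
dmTailSlope <- function(beta, v = 1L, otherCounts = NULL,
                        xRange = c(1e3, 1e4), nGrid = 25L) {
  V <- length(beta)
  if (is.null(otherCounts)) otherCounts <- rep(0L, V - 1L)
  if (length(otherCounts) != V - 1L)
    stopf("otherCounts must have length %d", V - 1L)
  xs <- unique(round(exp(seq(log(xRange[1L]), log(xRange[2L]),
                             length.out = nGrid))))
  logP <- vapply(xs, function(x) {
    cnt <- numeric(V)
    cnt[v] <- x
    cnt[-v] <- otherCounts
    dmLogPmf(cnt, beta)
  }, numeric(1))
  fit <- lm(logP ~ log(xs))
  list(slope = unname(coef(fit)[2L]),
       exponent = beta[v] - sum(beta),
       x = xs, logP = logP)
}
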