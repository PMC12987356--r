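---
title: "Multi-stream Dirichlet multinomial mixtures for acoustic activity discovery"
author: "streamDMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stream Dirichlet multinomial mixtures for acoustic activity discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamDMM)
```

## The problem

Ambient-assisted-living systems want to know which daily activity
(cooking, eating, vacuuming, watching TV, ...) is happening in a home,
from unobtrusive sensors, without asking anyone to label weeks of data.
streamDMM works on *discretized* sound: a neural audio codec with a
residual vector quantizer (RVQ) turns each audio frame into a short tuple
of integer codes, and the package's tokenizer concatenates the first few
codes of each frame into an "acoustic word". A 10-second audio segment
thus becomes a bag of a few hundred words per stream, where a stream is
one source of tokens — typically one beamforming direction of a
microphone array, but nothing in the model restricts streams to audio.

Clustering these bags unsupervised gives activity candidates; a user (or
a handful of labels) then names each cluster, and new segments inherit
the name of the cluster they fall into.

## The model

Each segment $m$ carries one token sequence per stream; only the
per-segment count vectors matter. Conditional on a latent activity
$z_m = k$, the count vector of stream $s$ follows a Dirichlet
multinomial (DM): a multinomial whose parameter is itself drawn from a
Dirichlet with concentration $\beta^{(s)}_k$ — once per activity, not
per segment. Streams are conditionally independent given $z_m$. The
activity proportions follow a Dirichlet prior with concentration
$\alpha$.

Integrating out all continuous parameters gives the collapsed joint over
assignments $Z$ and tokens,

$$
P(Z, W^{(1)}, \ldots, W^{(L)}) \;=\;
\frac{B(\tau + \alpha)}{B(\alpha)}
\prod_{s=1}^{L} \prod_{k=1}^{K}
\frac{B(\omega^{(s)}_k + \beta^{(s)}_k)}{B(\beta^{(s)}_k)},
$$

where $\tau_k$ counts segments in cluster $k$, $\omega^{(s)}_{k,v}$
counts occurrences of word $v$ of stream $s$ in cluster $k$, and $B$ is
the multivariate beta function. `jointLogProb()` computes exactly this.

### Why a DM and not a multinomial: burstiness

Because the emission distribution is drawn once per activity, a word
that appears during an activity tends to reappear there far more often
than its global frequency predicts. Marginally, with all other counts
fixed, the DM probability of observing a word $v$ exactly $x$ times
decays like $x^{\beta_v - \beta_\cdot}$ — a power law, where a
multinomial decays exponentially. `dmTailSlope()` exposes this exponent
numerically, and the diagnostics below make the contrast visible on
data.

### Inference

`dmmFit()` runs a collapsed Gibbs sampler: segment by segment, the
current segment's counts are removed from the tables and $z_m$ is
redrawn from the exact full conditional, which multiplies the occupancy
factor $(\tau_k^{\setminus m} + \alpha_k)$ by one ratio of rising
factorials per stream. All of it is evaluated in log space through
log-gamma differences,
$\log\Gamma(\omega + \beta + n) - \log\Gamma(\omega + \beta)$, which
stays finite and accurate where naive products over large vocabularies
overflow or degrade. The sweep loop is compiled code; the pure-R
`gibbsConditional()` computes the same quantity and the test suite
holds the two (and a brute-force enumeration of the joint) to within
$10^{-10}$ of each other.

One sweep costs $O(K L S)$ per segment ($L$ streams, $S$ tokens per
segment); the count tables occupy $O(K L V)$.

Design choices that were genuinely open, and what the package does:

* **Initialization** — independent uniform assignment from the seeded
  RNG; the simplest exchangeable choice.
* **Final clustering** — the assignment vector after the last sweep, no
  posterior averaging. Averaging would blur cluster identities, which
  the majority-vote protocol needs stable.
* **Hyperparameter defaults** — symmetric $\alpha = 1$, symmetric
  $\beta = 0.1$ for every stream. $\beta < 1$ induces the sparse bursty
  regime the model is built for; both are plain arguments and recorded
  in the fitted model.
* **Cluster capacity** — $K$ is an upper bound, not a choice to be
  optimized: with surplus capacity the sampler leaves clusters empty,
  and `estimatedClusterCount()` reports the occupied ones.
* **Determinism** — the fit owns its RNG, seeded explicitly, resampling
  in segment order, so identical inputs and seed are bit-reproducible.
  Saved models carry the RNG state, and `dmmFit(resume = )` continues a
  run exactly as if it had never stopped.
* **Held-out assignment** — the procedure for new segments is
  under-determined by the training algorithm, so both are provided:
  `map` (argmax of the held-out conditional, deterministic, ties to the
  lowest index) and `gibbs` (seeded resampling draws). Out-of-vocabulary
  tokens carry no probability under the model and are dropped with a
  reported count.

## Tokenization and vocabulary filtering

`codesToWords()` joins the first `prefixLength` (default 2) codes of
each frame with `"_"`; the separator keeps distinct code tuples distinct
(`1_23` vs `12_3`). Two filters then shrink the vocabulary:

1. **Noise-word removal** (`removeNoiseWords()`): every word type seen
   in designated noise segments — e.g. segments a presence sensor marks
   as "nobody in the room" — is removed everywhere, including from other
   activities, and the noise segments are dropped.
2. **Term-frequency-ratio cut** (`tfrFilter()`): words are ranked by
   descending count and kept until the cumulative frequency share first
   exceeds $r$ (default 0.6); ties break lexicographically so reruns are
   identical.

`tokenizeCorpus()` applies them in that order — noise removal first, so
the frequency ranking is computed on the cleaned vocabulary. The order
is a package decision: the filters commute only approximately, and
cleaning before ranking is what makes the TFR cut operate on
activity-relevant frequencies. Occurrences of filtered words are
silently dropped from token sequences (that is the filter's documented
semantics); an unknown token under an *explicit schema* at read time is
an error instead.

## The synthetic generator

`generateCorpus()` draws corpora from the model's own generative
process: mixture weights from $\mathrm{Dir}(\alpha)$, one emission
distribution per component and stream from $\mathrm{Dir}(\beta)$, then
i.i.d. tokens. `disjoint-support` mode instead gives each component a
private block of the vocabulary — the maximal-separation fixture used
when a test needs recovery to be unambiguous. Because emissions are
drawn once per component, burstiness lives at the activity level,
matching the model's assumption.

What passing tests on this generator do and do not show: they verify
that the sampler recovers the structure the model assumes (correct
implementation, calibrated behavior under its own assumptions). Real
codec tokens violate those assumptions in known ways — temporal
dependence between frames, activities that drift within a segment,
vocabulary overlap between acoustically similar activities — so
performance on generated corpora is an upper bound in kind, not a claim
about any recording.

Two purpose-built fixtures:

* `complementaryStreamsCorpus()` — four components, three streams; in
  each stream two pairs of components share identical emissions (the
  pairings differ per stream), so any single stream can separate only
  two super-groups while the streams jointly identify all four. This is
  the minimal construction in which multi-stream modeling is provably
  necessary, and it is what the multi-stream-benefit check runs on.
* `burstinessFixture()` — one stream, $V = 500$, $\beta = 0.05$, 60
  activities of 10 segments with 500 tokens each. The many small
  activities reproduce, at desk scale, the frequency dilution of a long
  recording: a globally rare word still bursts inside its home
  activity. The scale is chosen so that pooled per-segment means stay
  well below the diagnostic's tail threshold for every frequency group
  while within-activity bursts exceed it — the regime in which the
  DM-vs-multinomial contrast is identifiable at all. Outside that
  regime (very frequent words, or unit sizes that push pooled means
  past the threshold) the matched multinomial reaches the threshold
  deterministically and the comparison inverts; that is a property of
  the statistic, not of the model.

## Burstiness diagnostics

`burstinessReport()` ranks a stream's words by total frequency, forms
three groups (most frequent, a band centered on the median rank, least
frequent; the reference configuration uses sizes in the proportion
30 : 907 : 762), averages each word's empirical count pmf within the
group, and fits straight lines to the curves on log-log and semi-log
axes. A matched-mean multinomial corpus
(`matchedMultinomialCorpus()` — same unit sizes, same pooled word
frequencies, no burstiness) provides the reference curves and tail
masses.

Numerical choices:

* **Counting unit** — "counts within an activity" is ambiguous between
  per-segment counts stratified by activity and per-activity pooled
  blocks; both are implemented (`unit = "segment"` / `"block"`,
  default `segment`) and the choice is reported with the result.
* **Slope estimation** — fits use logarithmic binning (factor-1.5
  bins), the standard estimator for empirical power laws, and only
  binned points above the resolution floor $3/(n_\text{words} \cdot
  n_\text{units})$: averaged probabilities supported by fewer than
  about three observations are sampling noise, not shape. Log-log and
  semi-log fits use the same binned points so their $R^2$ compare
  fairly.
* **Small groups** — the 30-word frequent group is too small for a
  smooth averaged curve at desk scale; its fit is reported but the
  package's own acceptance checks assert goodness-of-fit only for the
  average and rare groups, and tail-mass dominance for all three.

## The evaluation protocol

Clustering is transductive: the model is fit once over all segments.
For evaluation, segments carry 0-based fold indices; for a pivot fold
$i$ out of $F$ (reference $F = 64$), `E1V1T62` evaluates on fold $i$,
validates on $i+1 \bmod F$ and lets the rest vote, while `T1V1E62`
reverses the balance (vote with two folds, evaluate on the rest — the
scarce-label regime). `majorityVoteMap()` gives each cluster the most
frequent label among its voting members (ties alphabetical); clusters
with no voting member predict the fallback label (default `"other"`).
`scorePredictions()` reports accuracy and macro-F1, where a class with
no true and no predicted positives contributes 0 — a stated convention,
since macro-F1 is undefined without one. `crossValidate()` runs every
pivot against the shared assignment vector and aggregates mean and
standard deviation; `refit = TRUE` refits per pivot for comparison,
though the reference protocol clusters once.

The scarce-label scheme degrades through a measurable mechanism: with
few voting folds, clusters populated only by evaluation segments stay
unmapped and fall back to `"other"`. The `fallbackRate` column makes
that visible directly.

## Conventions and formats

Corpora travel as JSON Lines (one segment object per line), models as a
single JSON document, vocabularies and manifests as TSV — all plain
text, all round-tripping exactly. In files, fold and cluster indices
are 0-based; inside R everything is 1-based, converted at the I/O
boundary. The `streamdmm` executable (in the package's `exec/`
directory) exposes `tokenize`, `simulate`, `fit`, `assign`,
`burstiness` and `evaluate` subcommands over these formats; flags
override a `--config` YAML file, which overrides built-in defaults, and
every stochastic subcommand records its seed in its output.

## Problem sizes in the test suite

The packaged checks run at sizes chosen to finish in seconds while
remaining non-trivial: oracle comparisons enumerate joints up to
$K^M \le 81$; recovery uses the default fixture (4 components, 400
segments, 3 streams, 200-word vocabularies, 100 tokens per stream and
segment) fit with $K = 20$ for 50 sweeps over 5 seeds; the
multi-stream-benefit check uses 200 segments over 5 seeds; the
burstiness fixture is described above. These sizes are the package's
own reference conditions and are restated in the acceptance script.

## Known limitations

* The model ignores token order entirely; temporal structure within and
  between segments (activity transitions, Markov dependence) is out of
  scope.
* Hyperparameters are fixed, not optimized; no variational alternative
  is provided.
* The diagnostic's power-law fits are descriptive (least squares on
  binned curves), not formal heavy-tail hypothesis tests.
* Majority voting needs every activity to appear among the voting
  segments of some cluster; under extreme label scarcity the fallback
  label dominates, which the protocol reports rather than repairs.
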