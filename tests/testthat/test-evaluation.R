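# Majority-vote mapping, scoring and the fold-based protocols.

test_that("fold roles partition all folds under both schemes", {
  for (Fn in c(4L, 64L)) for (pivot in c(0L, 1L, Fn - 1L)) {
    e <- foldRoles("E1V1T62", pivot, Fn)
    expect_identical(e$evaluation, pivot)
    expect_identical(e$validation, (pivot + 1L) %% Fn)
    expect_identical(sort(c(e$train, e$validation, e$evaluation)),
                     seq_len(Fn) - 1L)
    t <- foldRoles("T1V1E62", pivot, Fn)
    expect_identical(t$train, pivot)
    expect_identical(sort(c(t$train, t$validation, t$evaluation)),
                     seq_len(Fn) - 1L)
  }
  expect_error(foldRoles("E1V1T62", 64, 64), "pivot")
})

test_that("majority voting maps clusters and ties break alphabetically", {
  clusters <- c(1, 1, 1, 1, 2, 2, 3, 3)
  labels <- c("cooking", "cooking", "cooking", "eating",
              "eating", "cooking", "working", "working")
  map <- majorityVoteMap(clusters, labels)
  expect_identical(unname(map["1"]), "cooking")
  expect_identical(unname(map["2"]), "cooking")  # 1-1 tie -> alphabetical
  expect_identical(unname(map["3"]), "working")
  # clusters without voting members stay unmapped
  map2 <- majorityVoteMap(clusters, labels, voterIdx = 1:6)
  expect_false("3" %in% names(map2))
  pred <- predictLabels(clusters, map2, fallback = "other")
  expect_identical(pred[7:8], c("other", "other"))
  expect_identical(attr(pred, "fallbackCount"), 2L)
  expect_error(majorityVoteMap(clusters, c(labels[-8], NA),
                               voterIdx = seq_along(clusters)),
               "labeled")
})

test_that("a growing voter set never unmaps a mapped cluster", {
  set.seed(14)
  clusters <- sample(1:4, 30, replace = TRUE)
  labels <- sample(c("a", "b", "c"), 30, replace = TRUE)
  for (i in 1:10) {
    small <- sort(sample(30, 10))
    grown <- sort(union(small, sample(30, 10)))
    mSmall <- majorityVoteMap(clusters, labels, small)
    mGrown <- majorityVoteMap(clusters, labels, grown)
    expect_true(all(names(mSmall) %in% names(mGrown)))
  }
})

test_that("accuracy and macro-F1 match hand-computed values", {
  sc <- scorePredictions(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(sc$accuracy, 0.75)
  expect_equal(sc$macroF1, 11 / 15)
  expect_equal(sc$perClass$f1, c(2 / 3, 0.8))
  perfect <- scorePredictions(c("x", "y"), c("x", "y"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macroF1, 1)
  # all-fallback predictions score zero when 'other' is not a true label
  allOther <- scorePredictions(rep("other", 4), c("A", "A", "B", "B"))
  expect_equal(allOther$accuracy, 0)
  expect_equal(allOther$macroF1, 0)
  expect_error(scorePredictions(character(0), character(0)), "empty")
})

test_that("scores are invariant to cluster relabeling", {
  set.seed(8)
  clusters <- sample(1:5, 40, replace = TRUE)
  labels <- sample(c("a", "b"), 40, replace = TRUE)
  voters <- 1:30
  evalIdx <- 31:40
  perm <- sample(5)
  relabeled <- perm[clusters]
  s1 <- scorePredictions(
    predictLabels(clusters[evalIdx],
                  majorityVoteMap(clusters, labels, voters)),
    labels[evalIdx])
  s2 <- scorePredictions(
    predictLabels(relabeled[evalIdx],
                  majorityVoteMap(relabeled, labels, voters)),
    labels[evalIdx])
  expect_equal(s1$accuracy, s2$accuracy)
  expect_equal(s1$macroF1, s2$macroF1)
})

test_that("cross validation is perfect on a separable corpus and shares assignments", {
  syn <- generateCorpus(KTrue = 3, M = 48, streams = "d0", V = 60,
                        beta = 0.05, segmentLength = 40,
                        mode = "disjoint-support", seed = 4)
  corpus <- syn$corpus
  corpus@folds <- (seq_len(48) - 1L) %% 4L
  model <- dmmFit(corpus, K = 8, iterations = 30, seed = 2)
  cvE <- crossValidate(corpus, "E1V1T62", model = model)
  cvT <- crossValidate(corpus, "T1V1E62", model = model)
  expect_equal(cvE$aggregate$accuracyMean, 1)
  expect_equal(cvE$aggregate$macroF1Mean, 1)
  expect_equal(cvT$aggregate$accuracyMean, 1)
  # the clustering itself is shared between the two schemes
  expect_identical(cvE$assignments, cvT$assignments)
  expect_identical(cvE$assignments, assignments(model))
  # single pivot reproduces the plain train/eval split
  roles <- foldRoles("E1V1T62", 0, 4)
  voters <- corpus@folds %in% c(roles$train, roles$validation)
  evalIdx <- corpus@folds %in% roles$evaluation
  pred <- predictLabels(assignments(model)[evalIdx],
                        majorityVoteMap(assignments(model),
                                        segmentLabels(corpus), voters))
  sc <- scorePredictions(pred, segmentLabels(corpus)[evalIdx])
  expect_equal(sc$accuracy, cvE$perPivot$accuracy[1])
})

test_that("scarce-label folds trigger the fallback mechanism", {
  fx <- unmappedClusterCorpus()
  model <- dmmFit(fx$corpus, K = 8, iterations = 30, seed = 2)
  cv <- crossValidate(fx$corpus, "T1V1E62", model = model)
  # with training restricted to fold 0 (pivot 0), the component confined
  # to folds 2-3 has no voting member: its cluster goes to 'other'
  expect_gt(cv$perPivot$fallbackRate[1], 0)
  expect_gt(cv$aggregate$fallbackRateMean, 0)
  # the plentiful-label scheme maps every cluster
  cvE <- crossValidate(fx$corpus, "E1V1T62", model = model)
  expect_equal(cvE$aggregate$fallbackRateMean, 0)
  expect_lt(cv$aggregate$accuracyMean, cvE$aggregate$accuracyMean)
})

test_that("cross validation validates its inputs", {
  corpus <- toyCorpus()
  corpus@folds <- rep(NA_integer_, 2)
  expect_error(crossValidate(corpus, "E1V1T62", K = 2, iterations = 2),
               "fold")
  corpus2 <- toyCorpus()
  corpus2@labels <- rep(NA_character_, 2)
  expect_error(crossValidate(corpus2, "E1V1T62", K = 2, iterations = 2),
               "label")
})
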