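# Score matrices, argmax linking, Gaussian nulls, thresholded linking.

.toyScores <- function(m, qIds = paste0("q", seq_len(nrow(m))),
                       cIds = paste0("c", seq_len(ncol(m))), scorer = "toy") {
  dimnames(m) <- list(qIds, cIds)
  new("ScoreMatrix", m, scorer = scorer)
}

test_that("scoreAll agrees with the pairwise scorers and is order-invariant", {
  set.seed(61)
  K <- 4; V <- 8
  panel <- HaplotypePanel(matrix(rbinom(K * V, 1, 0.5), K, V))
  dsm <- randomDSM(panel)
  qs <- lapply(1:3, function(i) randomExpressionFor(dsm, paste0("q", i)))
  cs <- lapply(1:4, function(i)
    GenotypeProfile(rbinom(V, 1, 0.5), rbinom(V, 1, 0.5), paste0("c", i)))
  sc <- scoreAll(qs, cs, dsm)
  expect_s4_class(sc, "ScoreMatrix")
  expect_equal(dim(sc@.Data), c(3L, 4L))
  for (j in 1:3) for (i in 1:4)
    expect_equal(sc@.Data[j, i], dsmLogScore(cs[[i]], qs[[j]], dsm),
                 tolerance = 1e-12)
  # 1 x 1 case and duplicated-candidate determinism
  one <- scoreAll(qs[[1]], cs[[1]], dsm)
  expect_equal(as.numeric(one@.Data), dsmLogScore(cs[[1]], qs[[1]], dsm))
  dup <- GenotypeProfile(cs[[1]]@maternal, cs[[1]]@paternal, "c1b")
  sc2 <- scoreAll(qs, c(cs[1], list(dup)), dsm)
  expect_equal(unname(sc2@.Data[, 1]), unname(sc2@.Data[, 2]))
  # reordering inputs permutes, never changes, the entries
  perm <- scoreAll(rev(qs), rev(cs), dsm)
  expect_equal(perm@.Data[rev(rownames(sc)), rev(colnames(sc))], sc@.Data[rev(rownames(sc)), rev(colnames(sc))])
})

test_that("forward linking takes the row argmax with deterministic ties", {
  m <- matrix(0, 3, 3)
  diag(m) <- 5
  links <- linkForward(.toyScores(m))
  expect_equal(links$best_candidate, paste0("c", 1:3))
  expect_false(any(links$tie))
  expect_true(all(links$called))
  # a constant matrix ties everywhere and is flagged, lowest id wins
  expect_warning(flat <- linkForward(.toyScores(matrix(1, 2, 3))), "tied")
  expect_equal(flat$best_candidate, c("c1", "c1"))
  expect_true(all(flat$tie))
})

test_that("corrupting rows of a dominant matrix costs exactly those queries", {
  set.seed(62)
  n <- 292
  m <- matrix(rnorm(n * n), n, n)
  diag(m) <- 10
  bad <- sample(n, 10)
  m[cbind(bad, (bad %% n) + 1L)] <- 20      # a wrong column now wins those rows
  sc <- .toyScores(m)
  truth <- stats::setNames(paste0("c", 1:n), paste0("q", 1:n))
  expect_equal(linkAccuracy(sc, truth, count = TRUE), 282L)
})

test_that("reverse linking reads the transposed score matrix", {
  set.seed(63)
  K <- 3; V <- 6
  panel <- HaplotypePanel(matrix(rbinom(K * V, 1, 0.5), K, V))
  dsm <- randomDSM(panel)
  x <- GenotypeProfile(rbinom(V, 1, 0.5), rbinom(V, 1, 0.5), "g1")
  es <- lapply(1:5, function(i) randomExpressionFor(dsm, paste0("e", i)))
  res <- linkReverse(x, es, dsm)
  expect_equal(nrow(res), 1L)
  expect_equal(res$query_id, "g1")
  fwd <- scoreAll(es, list(x), dsm)
  expect_equal(res$best_candidate,
               rownames(fwd@.Data)[which.max(fwd@.Data[, 1])])
  expect_equal(res$log_score, max(fwd@.Data[, 1]))
  one <- linkReverse(x, es[2], dsm)
  expect_equal(one$best_candidate, "e2")
})

test_that("reverse linking finds the true expression among permuted decoys", {
  fx <- recoveryFixture()
  dsm <- recoveryDSM()
  hits <- vapply(1:50, function(i) {
    truthE <- fx$test$expressions[[i]]
    decoys <- fx$test$expressions[setdiff(seq_len(60), i)][1:19]
    res <- linkReverse(fx$test$genotypes[[i]], c(list(truthE), decoys), dsm)
    res$best_candidate == sampleId(truthE)
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("per-query Gaussian nulls recover the generating moments", {
  set.seed(64)
  m <- matrix(rnorm(3 * 10000), 3)
  null <- fitNull(.toyScores(m))
  expect_lt(max(abs(null@mean)), 0.05)
  expect_lt(max(abs(null@sd - 1)), 0.05)
  # scale equivariance
  null2 <- fitNull(.toyScores(2 * m))
  expect_equal(null2@mean, 2 * null@mean)
  expect_equal(null2@sd, 2 * null@sd)
  # the true column is excluded from the fit
  m2 <- matrix(rnorm(2 * 100), 2)
  truth <- c(q1 = "c1", q2 = "c2")
  m2[1, 1] <- m2[2, 2] <- 1e6
  nullT <- fitNull(.toyScores(m2), trueMap = truth)
  expect_lt(max(nullT@mean), 1)
  expect_equal(nullT@n, c(99L, 99L))
})

test_that("degenerate nulls are refused", {
  expect_error(fitNull(.toyScores(matrix(rnorm(20), 1))), "mismatching")
  m <- matrix(1, 2, 50)
  expect_error(fitNull(.toyScores(m)), "constant")
})

test_that("match P-values hit Gaussian quantiles and stay in (0, 1]", {
  null <- new("NullModel", queryIds = "q1", mean = 2, sd = 3, n = 100L)
  expect_equal(matchPValue(2, null), 0.5)
  expect_equal(matchPValue(2 + 1.959964 * 3, null), 0.025, tolerance = 1e-6)
  expect_gt(matchPValue(1e9, null), 0)
  expect_lte(matchPValue(-1e9, null), 1)
  nul2 <- new("NullModel", queryIds = c("a", "b"), mean = c(0, 10),
              sd = c(1, 1), n = c(50L, 50L))
  expect_equal(matchPValue(c(10, 0), nul2, query = c("b", "a")), c(0.5, 0.5))
  expect_error(matchPValue(1, nul2, query = "zz"), "unknown")
})

test_that("thresholded linking sweeps to the published metric definitions", {
  # perfectly separated: present-match queries all score above the absent ones
  m <- matrix(-10, 6, 4)
  m[cbind(1:4, 1:4)] <- 5                  # queries 1-4 match candidates 1-4
  m[5:6, ] <- -20                           # absent queries score low
  truth <- stats::setNames(c(paste0("c", 1:4), NA, NA), paste0("q", 1:6))
  res <- thresholdedLinking(.toyScores(m), truth)
  expect_equal(res$auroc, 1)
  expect_equal(res$auprc, 1)
  expect_equal(max(res$curve$tpr), 1)
  # the -Inf threshold row reproduces unthresholded linking accuracy
  lastRow <- res$curve[nrow(res$curve), ]
  expect_equal(lastRow$tpr,
               linkAccuracy(.toyScores(m[1:4, ]), truth[1:4]))
  expect_error(thresholdedLinking(.toyScores(m), stats::setNames(
    paste0("c", c(1:4, 1, 2)), paste0("q", 1:6))), "FPR undefined")
})

test_that("scores carrying no membership signal give chance-level AUROC", {
  # present and absent queries draw best scores from the same distribution,
  # so thresholding cannot separate them: the sweep integrates to 1/2
  set.seed(65)
  aurocs <- vapply(1:100, function(i) {
    m <- matrix(rnorm(40), 40, 1)
    truth <- stats::setNames(c(rep("c1", 20), rep(NA, 20)), paste0("q", 1:40))
    thresholdedLinking(.toyScores(m), truth)$auroc
  }, 0)
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})

test_that("holdout trials average the threshold sweep", {
  set.seed(66)
  m <- matrix(rnorm(30 * 40), 30)
  diag(m) <- diag(m) + 6
  truth <- stats::setNames(paste0("c", 1:30), paste0("q", 1:30))
  res <- holdoutLinking(.toyScores(m), truth, nTrials = 20, seed = 3)
  expect_length(res$auroc, 20)
  expect_equal(res$meanAuroc, mean(res$auroc))
  expect_gt(res$meanAuroc, 0.9)
  # reproducible under the same seed
  res2 <- holdoutLinking(.toyScores(m), truth, nTrials = 20, seed = 3)
  expect_equal(res$auroc, res2$auroc)
})

test_that("adding candidates never improves linking accuracy", {
  fx <- defaultFixture()
  sc <- defaultScores(scorer = "dsm")
  truth <- fx$truth
  nTest <- length(fx$test$genotypes)
  sizes <- c(nTest, nTest + 50, nTest + 150, ncol(sc@.Data))
  accs <- vapply(sizes, function(k) {
    sub <- .toyScores(sc@.Data[, 1:k, drop = FALSE], rownames(sc@.Data),
                      colnames(sc@.Data)[1:k], "dsm")
    linkAccuracy(sub, truth)
  }, 0)
  expect_true(all(diff(accs) <= 0))
})
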