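# Greedy eQTL pruning and the GNB / EBL baseline linkers.

test_that("greedy pruning keeps one site per LD block", {
  D <- .pruneFixture()
  map <- EQTLMap(siteIndex = 1:15, geneSets = as.list(paste0("g", 1:15)),
                 significance = c(15:1))
  pruned <- pruneEQTLs(D, map, corrThreshold = 0.1)
  expect_length(pruned@siteIndex, 6)
  expect_equal(pruned@siteIndex, c(1L, 11:15))         # block rep = most significant
  # idempotence
  again <- pruneEQTLs(D[pruned@siteIndex, ], EQTLMap(
    siteIndex = seq_along(pruned@siteIndex), geneSets = pruned@geneSets,
    significance = pruned@significance), corrThreshold = 0.1)
  expect_length(again@siteIndex, 6)
})

test_that("pruning keeps the more significant of two identical sites", {
  D <- rbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2))
  map <- EQTLMap(siteIndex = 1:2, geneSets = list("gA", "gB"),
                 significance = c(1, 5))
  pruned <- pruneEQTLs(D, map, corrThreshold = 0.1)
  expect_equal(pruned@siteIndex, 2L)
  expect_equal(pruned@geneSets[[1]], "gB")
})

test_that("orthogonal sites all survive and threshold 1 retains everything", {
  D <- .pruneFixture()
  map <- EQTLMap(siteIndex = 1:15, geneSets = as.list(paste0("g", 1:15)))
  expect_length(pruneEQTLs(D[11:15, ],
                           EQTLMap(siteIndex = 1:5,
                                   geneSets = as.list(paste0("g", 1:5))),
                           corrThreshold = 0.1)@siteIndex, 5)
  expect_length(pruneEQTLs(D, map, corrThreshold = 1)@siteIndex, 15)
})

test_that("constant-dosage sites are excluded with a warning", {
  D <- rbind(c(0, 1, 2, 1, 0, 2), rep(2, 6))
  map <- EQTLMap(siteIndex = 1:2, geneSets = list("gA", "gB"))
  expect_warning(pruned <- pruneEQTLs(D, map, 0.1), "constant")
  expect_equal(pruned@siteIndex, 1L)
})

test_that("GNB log scores match per-site hand computation", {
  # single eQTL, mu0 = 0, mu1 = 1, sigma = 1, uniform prior, e = 1:
  # the dosage-1 vs dosage-0 log-score difference is exactly +0.5
  map <- EQTLMap(siteIndex = 1L, geneSets = list("gA"))
  gnb <- new("GNBParams", map = map, gene = "gA",
             mu = matrix(c(0, 1, 2), 1), sigma = 1,
             logPrior = matrix(log(1 / 3), 1, 3))
  e <- ExpressionProfile(1, "gA", "q")
  x0 <- GenotypeProfile(0, 0, "a"); x1 <- GenotypeProfile(1, 0, "b")
  expect_equal(gnbLogScore(x1, e, gnb) - gnbLogScore(x0, e, gnb), 0.5)
  # midpoint ties the two classes
  eMid <- ExpressionProfile(0.5, "gA", "q")
  expect_equal(gnbLogScore(x0, eMid, gnb), gnbLogScore(x1, eMid, gnb))
  expect_equal(logScore(x1, e, gnb), gnbLogScore(x1, e, gnb))
})

test_that("fitted GNB scores equal an independent scalar route", {
  set.seed(51)
  cfg <- simConfig(seed = 51, kPanel = 20, vSites = 12, nTrain = 120, nTest = 5,
                   nDecoys = 0, nEQTLs = 3, genesPerEQTL = 1, nNoiseGenes = 2,
                   effectSize = 1.5, ldBlockSize = 1)
  fx <- makeLinkingFixture(cfg)
  gnb <- gnbFit(fx$train$genotypes, fx$train$expressions, fx$map)
  for (i in 1:5) {
    x <- fx$test$genotypes[[i]]; e <- fx$test$expressions[[i]]
    ev <- exprValues(e)
    manual <- 0
    for (s in seq_along(gnb@map@siteIndex)) {
      d <- dosage(x)[gnb@map@siteIndex[s]]
      manual <- manual +
        stats::dnorm(ev[gnb@gene[s]], gnb@mu[s, d + 1], gnb@sigma[s], log = TRUE) +
        gnb@logPrior[s, d + 1]
    }
    expect_equal(gnbLogScore(x, e, gnb), unname(manual), tolerance = 1e-12)
  }
})

test_that("the GNB class posterior for dosage 2 is monotone in expression", {
  map <- EQTLMap(siteIndex = 1L, geneSets = list("gA"))
  gnb <- new("GNBParams", map = map, gene = "gA",
             mu = matrix(c(-1, 0, 1), 1), sigma = 0.8,
             logPrior = matrix(log(1 / 3), 1, 3))
  xs <- list(GenotypeProfile(0, 0, "d0"), GenotypeProfile(1, 0, "d1"),
             GenotypeProfile(1, 1, "d2"))
  post2 <- vapply(seq(-3, 3, by = 0.5), function(v) {
    e <- ExpressionProfile(v, "gA", "q")
    ll <- vapply(xs, gnbLogScore, 0, e = e, params = gnb)
    exp(ll[3]) / sum(exp(ll))
  }, 0)
  expect_true(all(diff(post2) > 0))
})

test_that("zero-variance eGenes floor sigma with a warning", {
  geno <- lapply(1:6, function(i)
    GenotypeProfile(i %% 2, (i %/% 2) %% 2, paste0("s", i)))
  expr <- lapply(geno, function(g)
    ExpressionProfile(c(1, rnorm(1)), c("flat", "ok"), sampleId(g)))
  map <- EQTLMap(siteIndex = 1L, geneSets = list("flat"))
  expect_warning(gnb <- gnbFit(geno, expr, map), "floored")
  expect_gte(min(gnb@sigma), 1e-6)
})

test_that("EBL collapses to GNB when nothing is extreme", {
  set.seed(52)
  cfg <- simConfig(seed = 52, kPanel = 20, vSites = 12, nTrain = 100, nTest = 6,
                   nDecoys = 0, nEQTLs = 5, genesPerEQTL = 1, nNoiseGenes = 1,
                   effectSize = 1, ldBlockSize = 1)
  fx <- makeLinkingFixture(cfg)
  ebl <- eblFit(fx$train$genotypes, fx$train$expressions, fx$map,
                extremityQ = 0.9, corrMin = 0.3)
  # queries sitting at the training median are never extreme
  med <- apply(expressionMatrix(fx$train$expressions), 1, stats::median)
  eMid <- ExpressionProfile(med, names(med), "mid")
  for (x in fx$test$genotypes)
    expect_identical(eblLogScore(x, eMid, ebl), gnbLogScore(x, eMid, ebl@gnb))
})

test_that("extreme genes contribute 0 or -lambda by predicted homozygote", {
  # hand-built model: one eQTL, positive direction, known thresholds
  map <- EQTLMap(siteIndex = 1L, geneSets = list("gA"))
  gnb <- new("GNBParams", map = map, gene = "gA",
             mu = matrix(c(-1, 0, 1), 1), sigma = 1,
             logPrior = matrix(log(1 / 3), 1, 3))
  ebl <- new("EBLParams", gnb = gnb, extremityQ = 0.9, corrMin = 0.3,
             lambda = 5, corr = 0.8, lo = -2, hi = 2)
  eHigh <- ExpressionProfile(3, "gA", "q")       # beyond hi, r > 0 -> predict 2
  x2 <- GenotypeProfile(1, 1, "hom2")
  x0 <- GenotypeProfile(0, 0, "hom0")
  expect_equal(eblLogScore(x2, eHigh, ebl), 0)
  expect_equal(eblLogScore(x0, eHigh, ebl), -5)
  eLow <- ExpressionProfile(-3, "gA", "q")       # beyond lo, r > 0 -> predict 0
  expect_equal(eblLogScore(x0, eLow, ebl), 0)
  expect_equal(eblLogScore(x2, eLow, ebl), -5)
  # below the correlation filter the site falls back to GNB
  weak <- new("EBLParams", gnb = gnb, extremityQ = 0.9, corrMin = 0.9,
              lambda = 5, corr = 0.8, lo = -2, hi = 2)
  expect_equal(eblLogScore(x2, eHigh, weak), gnbLogScore(x2, eHigh, gnb))
})

test_that("extremity calls beat the Gaussian model under heavy-tailed noise", {
  accs <- vapply(1:20, function(sd) {
    cfg <- simConfig(seed = sd, kPanel = 30, vSites = 40, nTrain = 150,
                     nTest = 30, nDecoys = 70, nEQTLs = 25, genesPerEQTL = 1,
                     nNoiseGenes = 5, effectSize = 1.5, noiseSd = 1,
                     noiseDf = 3, ldBlockSize = 1, cmPerSite = 0.5)
    fx <- makeLinkingFixture(cfg)
    pruned <- suppressWarnings(pruneEQTLs(fx$train$genotypes, fx$map, 0.2))
    gnb <- suppressWarnings(gnbFit(fx$train$genotypes, fx$train$expressions, pruned))
    ebl <- suppressWarnings(tuneEBL(fx$train$genotypes, fx$train$expressions,
                                    pruned, extremityGrid = c(0.85, 0.95),
                                    corrGrid = c(0.1, 0.3)))
    cands <- c(fx$test$genotypes, fx$decoys)
    c(linkAccuracy(scoreAll(fx$test$expressions, cands, gnb), fx$truth),
      linkAccuracy(scoreAll(fx$test$expressions, cands, ebl), fx$truth))
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("the EBL grid search reports its grid and best accuracy", {
  fx <- defaultFixture()
  pruned <- suppressWarnings(pruneEQTLs(fx$train$genotypes[1:80], fx$map, 0.2))
  ebl <- suppressWarnings(tuneEBL(fx$train$genotypes[1:80],
                                  fx$train$expressions[1:80], pruned,
                                  extremityGrid = c(0.9), corrGrid = c(0.1, 0.5)))
  grid <- attr(ebl, "grid")
  expect_equal(nrow(grid), 2)
  expect_true(all(is.finite(grid$accuracy)))
  expect_equal(attr(ebl, "accuracy"), max(grid$accuracy))
})
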