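# Joint factor learning: gradients, recovery, calibration, windowing.

test_that("analytic gradients match central finite differences", {
  set.seed(41)
  for (i in 1:20) {
    cfg <- simConfig(seed = 41 + i, kPanel = sample(2:4, 1),
                     vSites = sample(5:8, 1), nTrain = 10, nTest = 2,
                     nDecoys = 0, nEQTLs = 4, genesPerEQTL = sample(1:2, 1),
                     nNoiseGenes = 1, ldBlockSize = 2)
    fx <- makeLinkingFixture(cfg)
    hmm <- buildHMMParams(fx$panel, 1, 0.05)
    ctx <- dsmlink:::.dsmTrainContext(fx$train$genotypes, fx$train$expressions,
                                      fx$panel, fx$map, hmm)
    theta <- rnorm(length(ctx$nBeta) + sum(ctx$nBeta), sd = 0.5)
    og <- dsmlink:::.dsmObjGrad(theta, ctx)
    h <- 1e-5
    num <- vapply(seq_along(theta), function(j) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (dsmlink:::.dsmObjGrad(tp, ctx, wantGrad = FALSE)$objective -
         dsmlink:::.dsmObjGrad(tm, ctx, wantGrad = FALSE)$objective) / (2 * h)
    }, 0)
    relerr <- max(abs(num - og$gradient) / pmax(abs(num), 1e-8))
    expect_lt(relerr, 1e-4)
  }
})

test_that("training recovers effect signs and predictive posteriors", {
  fx <- recoveryFixture()
  dsm <- recoveryDSM()
  trueSign <- vapply(fx$effects, function(e) sign(e[[1]]), 0)
  fitSign <- vapply(dsm@qtl@beta, function(b) sign(b[1]), 0)
  expect_gte(mean(fitSign == trueSign), 0.95)
  post <- dsmPosteriors(fx$test$expressions, dsm, fx$panel)
  acc <- mean(post$dosage == dosageMatrix(fx$test$genotypes))
  expect_gt(acc, 0.9)
  # the training objective is non-decreasing up to optimizer noise
  expect_gt(utils::tail(dsm@history, 1), dsm@history[1])
  expect_lt(sum(diff(dsm@history) < -1e-6), length(dsm@history) * 0.1)
})

test_that("permuting expression against genotypes destroys the signal", {
  fx <- recoveryFixture()
  set.seed(12)
  perm <- sample(length(fx$train$expressions))
  dsmP <- trainDSM(fx$train$genotypes, fx$train$expressions[perm], fx$panel,
                   fx$map, epochs = 400)
  post <- dsmPosteriors(fx$test$expressions, dsmP, fx$panel)
  expect_gt(mean(post$allele), 0.4)
  expect_lt(mean(post$allele), 0.6)
})

test_that("duplicated eGenes calibrate to the single-gene logit", {
  set.seed(31)
  cfg <- simConfig(seed = 31, kPanel = 20, vSites = 10, nTrain = 400, nTest = 50,
                   nEQTLs = 10, genesPerEQTL = 1, nNoiseGenes = 0,
                   effectSize = 1.5, noiseSd = 0.8, ldBlockSize = 1,
                   nFounders = 2, cmPerSite = 100, nDecoys = 0)
  panel <- simulatePanel(cfg, seed = NA)
  geno <- simulateIndividuals(panel, cfg, 400, seed = NA)
  map1 <- EQTLMap(siteIndex = 1L, geneSets = list("gA"))
  expr <- simulateExpression(geno, map1, cfg, effects = list(c(gA = 1.5)), seed = NA)
  dup <- lapply(expr, function(e)
    ExpressionProfile(c(e@values, e@values[e@geneIds == "gA"]),
                      c(e@geneIds, "gB"), e@sampleId))
  mapD <- EQTLMap(siteIndex = 1L, geneSets = list(c("gA", "gB")))
  fit1 <- trainDSM(geno, expr, panel, map1, epochs = 300)
  fitD <- trainDSM(geno, dup, panel, mapD, epochs = 300)
  ho <- simulateExpression(simulateIndividuals(panel, cfg, 100, "ho", seed = NA),
                           map1, cfg, effects = list(c(gA = 1.5)), seed = NA)
  E <- expressionMatrix(ho)
  l1 <- fit1@qtl@alpha +
    fit1@qtl@beta[[1]] * (E["gA", ] - fit1@exprCenter["gA"]) / fit1@exprScale["gA"]
  lD <- fitD@qtl@alpha +
    sum(fitD@qtl@beta[[1]]) * (E["gA", ] - fitD@exprCenter["gA"]) / fitD@exprScale["gA"]
  expect_lt(max(abs(l1 - lD)), 0.01 * (1 + max(abs(l1))))
  # symmetric start splits the weight evenly between the duplicates
  expect_equal(fitD@qtl@beta[[1]][1], fitD@qtl@beta[[1]][2], tolerance = 1e-8)
})

test_that("joint training absorbs redundant signal at linked sites", {
  # duplicated-signal LD blocks; the naive product of independent per-site
  # logistic fits double-counts them and loses on held-out log loss
  cfg <- simConfig(seed = 21, kPanel = 30, vSites = 30, nTrain = 300, nTest = 100,
                   nDecoys = 0, nEQTLs = 30, genesPerEQTL = 1, nNoiseGenes = 2,
                   effectSize = 1.5, noiseSd = 1, ldBlockSize = 3,
                   cmPerSite = 0.001)
  fx <- makeLinkingFixture(cfg)
  dsm <- trainDSM(fx$train$genotypes, fx$train$expressions, fx$panel, fx$map)
  Etr <- expressionMatrix(fx$train$expressions)
  Ete <- expressionMatrix(fx$test$expressions)
  Dtr <- dosageMatrix(fx$train$genotypes)
  Dte <- dosageMatrix(fx$test$genotypes)
  m <- fx$map
  llNaive <- 0
  for (s in seq_along(m@siteIndex)) {
    g <- m@geneSets[[s]][1]
    df <- data.frame(y1 = Dtr[m@siteIndex[s], ], e = Etr[g, ])
    fit <- suppressWarnings(stats::glm(cbind(y1, 2 - y1) ~ e, data = df,
                                       family = stats::binomial))
    p <- stats::predict(fit, newdata = data.frame(e = Ete[g, ]), type = "response")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    d <- Dte[m@siteIndex[s], ]
    llNaive <- llNaive - sum(d * log(p) + (2 - d) * log(1 - p))
  }
  llNaive <- llNaive / (2 * ncol(Dte))
  # both are per-haplotype joint log losses: the naive product of independent
  # factors against the normalized sequence model
  llDSM <- dsmLogLoss(fx$test$genotypes, fx$test$expressions, dsm, fx$panel)
  expect_lte(llDSM, llNaive)
})

test_that("window partitioning follows the site order", {
  fx <- recoveryFixture()
  # 40 eQTLs, windows of 12 -> 12, 12, 12, 4
  wins <- trainDSMWindows(fx$train$genotypes[1:40], fx$train$expressions[1:40],
                          fx$panel, fx$map, windowSize = 12, epochs = 2)
  expect_length(wins, 4)
  expect_equal(vapply(wins, function(m) length(m@qtl@alpha), 0L),
               c(12L, 12L, 12L, 4L))
  ranges <- vapply(wins, function(m) attr(m, "siteRange"), integer(2))
  expect_equal(ranges[1, ], c(1L, ranges[2, -4] + 1L), ignore_attr = TRUE)
  expect_equal(ranges[2, 4], nVariants(fx$panel))
  expect_error(trainDSMWindows(fx$train$genotypes[1:3], fx$train$expressions[1:3],
                               fx$panel, fx$map, windowSize = 0), "windowSize")
})

test_that("a window covering everything reproduces plain training", {
  cfg <- simConfig(seed = 33, kPanel = 8, vSites = 6, nTrain = 40, nTest = 2,
                   nDecoys = 0, nEQTLs = 6, genesPerEQTL = 1, nNoiseGenes = 0,
                   ldBlockSize = 1)
  fx <- makeLinkingFixture(cfg)
  full <- trainDSM(fx$train$genotypes, fx$train$expressions, fx$panel, fx$map,
                   epochs = 30)
  wins <- trainDSMWindows(fx$train$genotypes, fx$train$expressions, fx$panel,
                          fx$map, windowSize = 100, epochs = 30)
  expect_length(wins, 1)
  expect_equal(wins[[1]]@qtl@alpha, full@qtl@alpha, tolerance = 1e-12)
  expect_equal(wins[[1]]@qtl@beta, full@qtl@beta, tolerance = 1e-12)
})

test_that("certain recombination at the boundary makes windows exact", {
  cfg <- simConfig(seed = 32, kPanel = 8, vSites = 6, nTrain = 60, nTest = 2,
                   nDecoys = 0, nEQTLs = 6, genesPerEQTL = 1, nNoiseGenes = 0,
                   effectSize = 1, noiseSd = 1, ldBlockSize = 1)
  panel <- simulatePanel(cfg, seed = NA)
  # a gap so large the switch probability saturates at 1 between sites 3 and 4
  panel <- applyGeneticMap(panel, c(0, 0.01, 0.02, 1e4, 1e4 + 0.01, 1e4 + 0.02))
  geno <- simulateIndividuals(panel, cfg, 60, seed = NA)
  map <- EQTLMap(siteIndex = 1:6, geneSets = lapply(1:6, function(s) paste0("g", s)))
  expr <- simulateExpression(geno, map, cfg, seed = NA)
  full <- trainDSM(geno, expr, panel, map, epochs = 40)
  comb <- combineDSMWindows(trainDSMWindows(geno, expr, panel, map,
                                            windowSize = 3, epochs = 40), panel)
  expect_equal(comb@qtl@alpha, full@qtl@alpha, tolerance = 1e-10)
  expect_equal(unlist(comb@qtl@beta), unlist(full@qtl@beta), tolerance = 1e-10)
  # and the merged model scores like the windowed sum
  e <- expr[[1]]; x <- geno[[1]]
  wins <- trainDSMWindows(geno, expr, panel, map, windowSize = 3, epochs = 40)
  sFromWindows <- scoreAll(list(e), list(x), wins)@.Data[1, 1]
  expect_equal(dsmLogScore(x, e, comb), sFromWindows, tolerance = 1e-9)
})

test_that("training validates its inputs", {
  fx <- recoveryFixture()
  expect_error(trainDSM(fx$train$genotypes[1], fx$train$expressions[1],
                        fx$panel, fx$map), "at least 2")
  expect_error(trainDSM(fx$train$genotypes[1:3], fx$train$expressions[1:2],
                        fx$panel, fx$map), "matched")
  badMap <- EQTLMap(siteIndex = 1L, geneSets = list("absent_gene"))
  expect_error(trainDSM(fx$train$genotypes[1:5], fx$train$expressions[1:5],
                        fx$panel, badMap), "unresolvable")
})
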