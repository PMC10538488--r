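# Shared fixture builders and a per-session cache for the expensive trained
# models reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# A random small chain instance for oracle comparisons.
randomInstance <- function(K = NULL, V = NULL, evidence = TRUE) {
  if (is.null(K)) K <- sample(2:4, 1)
  if (is.null(V)) V <- sample(2:6, 1)
  panel <- HaplotypePanel(matrix(rbinom(K * V, 1, 0.5), K, V))
  prior <- runif(K)
  params <- HMMParams(switchProb = runif(max(V - 1, 0)),
                      emissionError = runif(1, 0.02, 0.45),
                      prior = prior / sum(prior))
  list(panel = panel, params = params,
       h = rbinom(V, 1, 0.5),
       evidence = if (evidence) SiteEvidence(runif(V, 0.1, 2), runif(V, 0.1, 2)))
}

# A small random DSM with non-trivial factors over every site.
randomDSM <- function(panel, genesPerSite = 2) {
  V <- nVariants(panel)
  genes <- paste0("g", seq_len(V * genesPerSite))
  map <- EQTLMap(siteIndex = seq_len(V),
                 geneSets = split(genes, rep(seq_len(V), each = genesPerSite)))
  new("DSMParams",
      hmm = buildHMMParams(panel, 1, 0.1),
      qtl = new("QTLFactorParams", alpha = rnorm(V, sd = 0.5),
                beta = replicate(V, rnorm(genesPerSite, sd = 0.5),
                                 simplify = FALSE)),
      map = map,
      exprCenter = stats::setNames(rep(0, length(genes)), genes),
      exprScale = stats::setNames(rep(1, length(genes)), genes),
      history = 0)
}

randomExpressionFor <- function(params, sampleId = "q1") {
  genes <- unique(unlist(params@map@geneSets))
  ExpressionProfile(rnorm(length(genes)), genes, sampleId)
}

# The package's standard linking fixture plus trained scorers (computed once).
defaultFixture <- function(seed = 1) {
  cached(paste0("fx", seed), makeLinkingFixture(simConfig(seed = seed)))
}

defaultDSM <- function(seed = 1) {
  cached(paste0("dsm", seed), {
    fx <- defaultFixture(seed)
    trainDSM(fx$train$genotypes, fx$train$expressions, fx$panel, fx$map)
  })
}

defaultGNB <- function(seed = 1) {
  cached(paste0("gnb", seed), {
    fx <- defaultFixture(seed)
    pruned <- suppressWarnings(pruneEQTLs(fx$train$genotypes, fx$map, 0.1))
    suppressWarnings(gnbFit(fx$train$genotypes, fx$train$expressions, pruned))
  })
}

defaultScores <- function(seed = 1, scorer = c("dsm", "gnb")) {
  scorer <- match.arg(scorer)
  cached(paste0("scores.", scorer, seed), {
    fx <- defaultFixture(seed)
    params <- if (scorer == "dsm") defaultDSM(seed) else defaultGNB(seed)
    scoreAll(fx$test$expressions, c(fx$test$genotypes, fx$decoys), params)
  })
}

# Strong-signal recovery fixture: independent (unlinked), common-frequency
# single-gene eQTLs.
recoveryConfig <- function(seed = 11) {
  simConfig(seed = seed, kPanel = 30, vSites = 40, nTrain = 500, nTest = 100,
            nDecoys = 0, nEQTLs = 40, genesPerEQTL = 1, nNoiseGenes = 5,
            effectSize = 2, noiseSd = 0.25, ldBlockSize = 1, nFounders = 2,
            cmPerSite = 100)
}

recoveryFixture <- function() cached("recoveryFx", makeLinkingFixture(recoveryConfig()))

recoveryDSM <- function() {
  cached("recoveryDsm", {
    fx <- recoveryFixture()
    trainDSM(fx$train$genotypes, fx$train$expressions, fx$panel, fx$map,
             epochs = 400)
  })
}

# Calibration fixture: one 750-eQTL window of weak, nearly independent
# single-gene effects, the regime in which the Gaussian match-score null is
# expected to hold.
calibrationConfig <- function(seed = 1) {
  simConfig(seed = seed, kPanel = 60, vSites = 600, nTrain = 300, nTest = 10,
            nDecoys = 0, nEQTLs = 450, genesPerEQTL = 1, nNoiseGenes = 20,
            effectSize = 0.2, ldBlockSize = 2)
}

calibrationModel <- function() {
  cached("calibModel", {
    fx <- cached("calibFx", makeLinkingFixture(calibrationConfig()))
    list(fx = fx,
         dsm = trainDSM(fx$train$genotypes, fx$train$expressions, fx$panel,
                        fx$map))
  })
}

# deterministic dosage profiles with exact correlation structure: Walsh
# functions over 16 individuals are mutually orthogonal by construction
.pruneFixture <- function() {
  bits <- as.matrix(expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1, b4 = 0:1))
  walsh <- function(S) apply(bits[, S, drop = FALSE] * 2 - 1, 1, prod)
  # sites 1-10: one perfect-LD block (the first Walsh function up to sign);
  # sites 11-15: five other Walsh functions, all pairwise uncorrelated
  block <- matrix(rep(walsh(1), 10), nrow = 10, byrow = TRUE)
  block[2, ] <- -walsh(1)                # perfectly anti-correlated copies
  block[4, ] <- -walsh(1)
  ind <- rbind(walsh(2), walsh(3), walsh(4), walsh(c(1, 2)), walsh(c(3, 4)))
  D <- rbind(block, ind) + 1            # dosages in {0, 2}
  stopifnot(max(abs(cor(t(D[c(1, 11:15), ])) - diag(6))) < 1e-12)
  D
}

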