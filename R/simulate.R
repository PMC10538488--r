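# Seeded generators: reference panels with block LD, diploid mosaic
# individuals drawn from the copying process itself, eQTL-coupled expression,
# and complete linking fixtures. Individuals are simulated from the same
# copying-chain family used for inference, so recovery tests isolate
# implementation correctness from model misfit; `hotspots` provides a
# misspecified recombination mode for robustness checks.

#' Simulate an LD-structured reference panel
#'
#' Sites are grouped into consecutive blocks of `ldBlockSize`; each block has
#' its own pool of `nFounders` founder haplotypes (never monomorphic within
#' the pool), and every panel haplotype copies one founder per block with a
#' small per-site copy error. Adjacent sites within a block are therefore
#' correlated while blocks are independent. Per-site allele frequencies are
#' nudged into `[0.05, 0.95]` by flipping the minimal number of entries.
#'
#' @param cfg a [SimConfig-class].
#' @param seed optional seed; defaults to `cfg@seed`. Pass NA to leave the
#'   random-number state untouched (used internally by the fixture builder).
#' @return a [HaplotypePanel-class] with 1 kb physical spacing and a uniform
#'   genetic map of `cfg@cmPerSite` cM per interval.
#' @export
simulatePanel <- function(cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  if (!is.na(seed)) set.seed(seed)
  K <- cfg@kPanel; V <- cfg@vSites
  blocks <- split(seq_len(V), ceiling(seq_len(V) / cfg@ldBlockSize))
  A <- matrix(0L, K, V)
  for (sites in blocks) {
    nf <- cfg@nFounders
    founders <- matrix(stats::rbinom(nf * length(sites), 1, 0.5), nf)
    # keep every site polymorphic within the founder pool
    mono <- which(colSums(founders) %in% c(0L, nf))
    for (s in mono) founders[sample.int(nf, 1), s] <- 1L - founders[1, s]
    pick <- sample.int(nf, K, replace = TRUE)
    blockAll <- founders[pick, , drop = FALSE]
    flip <- matrix(stats::rbinom(K * length(sites), 1, cfg@founderError), K)
    A[, sites] <- abs(blockAll - flip)
  }
  # bound allele frequencies in [0.05, 0.95]
  for (s in seq_len(V)) {
    f <- mean(A[, s])
    if (f < 0.05) {
      k <- ceiling((0.05 - f) * K)
      zero <- which(A[, s] == 0L)
      A[zero[sample.int(length(zero), k)], s] <- 1L
    } else if (f > 0.95) {
      k <- ceiling((f - 0.95) * K)
      one <- which(A[, s] == 1L)
      A[one[sample.int(length(one), k)], s] <- 0L
    }
  }
  HaplotypePanel(A, positions = seq_len(V) * 1000,
                 geneticPos = (seq_len(V) - 1) * cfg@cmPerSite)
}

#' Simulate diploid individuals as panel mosaics
#'
#' Each haplotype is generated from the copying process itself: a hidden path
#' over panel haplotypes with the switch probabilities of
#' [buildHMMParams()] and per-site copy error `cfg@emissionError`, so the
#' chain prior used at inference time is exactly the generating distribution.
#'
#' @param panel a [HaplotypePanel-class].
#' @param cfg a [SimConfig-class].
#' @param n number of individuals.
#' @param idPrefix sample identifier prefix.
#' @param seed optional seed (NA = leave RNG state alone).
#' @param hotspots optional integer sites at whose preceding interval the
#'   generating switch probability is forced to 0.5 (a recombination-hotspot
#'   misspecification unknown to the inference model).
#' @return list of [GenotypeProfile-class].
#' @export
simulateIndividuals <- function(panel, cfg, n, idPrefix = "ind", seed = NA,
                                hotspots = NULL) {
  stopifnot(is(panel, "HaplotypePanel"), is(cfg, "SimConfig"))
  if (!is.na(seed)) set.seed(seed)
  params <- buildHMMParams(panel, cfg@recombScale, cfg@emissionError)
  rho <- params@switchProb
  if (length(hotspots)) rho[pmax(hotspots - 1L, 1L)] <- 0.5
  K <- nHaplotypes(panel); V <- nVariants(panel)
  eps <- cfg@emissionError
  drawHap <- function() {
    z <- integer(V)
    z[1] <- sample.int(K, 1)
    if (V > 1) {
      sw <- stats::runif(V - 1) < rho
      for (s in 2:V) z[s] <- if (sw[s - 1]) sample.int(K, 1) else z[s - 1]
    }
    h <- panel@alleles[cbind(z, seq_len(V))]
    flip <- stats::runif(V) < eps
    h[flip] <- 1L - h[flip]
    h
  }
  lapply(seq_len(n), function(i)
    GenotypeProfile(drawHap(), drawHap(), sprintf("%s%03d", idPrefix, i)))
}

#' Draw per-(eQTL, eGene) effect sizes
#'
#' Effects have magnitude `cfg@effectSize` and a random sign per eQTL (shared
#' by all of that eQTL's eGenes, so redundant eGenes reinforce rather than
#' cancel).
#'
#' @param eqtlMap an [EQTLMap-class].
#' @param cfg a [SimConfig-class].
#' @param seed optional seed (NA = leave RNG state alone).
#' @return list of named numeric effect vectors, one per eQTL.
#' @export
simulateEffects <- function(eqtlMap, cfg, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  lapply(eqtlMap@geneSets, function(genes) {
    sgn <- sample(c(-1, 1), 1)
    stats::setNames(rep(sgn * cfg@effectSize, length(genes)), genes)
  })
}

#' Simulate eQTL-coupled expression
#'
#' Each gene's expression is the sum of the linear dosage effects of the
#' eQTLs it is associated with plus Gaussian noise:
#' `e_g = sum_{s: g in Q(s)} effect_{s,g} * dosage_s + noise`, where the noise
#' is Gaussian with standard deviation `noiseSd` (or Student-t with
#' `noiseDf` degrees of freedom and scale `noiseSd` when `noiseDf` is
#' finite). Genes in no Q(s) (the `noise_*` genes) are pure noise. With more
#' than one gene per eQTL the shared dosage creates redundant, correlated
#' signals.
#'
#' @param genotypes list of [GenotypeProfile-class].
#' @param eqtlMap an [EQTLMap-class].
#' @param cfg a [SimConfig-class].
#' @param effects optional effect list from [simulateEffects()]; drawn from
#'   `cfg` when missing.
#' @param seed optional seed (NA = leave RNG state alone).
#' @return list of [ExpressionProfile-class] (same sample ids as `genotypes`).
#' @export
simulateExpression <- function(genotypes, eqtlMap, cfg, effects = NULL,
                               seed = NA) {
  stopifnot(is(eqtlMap, "EQTLMap"), is(cfg, "SimConfig"))
  if (!is.na(seed)) set.seed(seed)
  if (is.null(effects)) effects <- simulateEffects(eqtlMap, cfg)
  genes <- unique(unlist(eqtlMap@geneSets, use.names = FALSE))
  if (cfg@nNoiseGenes > 0) genes <- c(genes, paste0("noise_", seq_len(cfg@nNoiseGenes)))
  D <- dosageMatrix(genotypes)[eqtlMap@siteIndex, , drop = FALSE]
  n <- length(genotypes)
  E <- matrix(0, length(genes), n, dimnames = list(genes, colnames(D)))
  for (s in seq_along(effects)) {
    eff <- effects[[s]]
    E[names(eff), ] <- E[names(eff), , drop = FALSE] + outer(eff, D[s, ])
  }
  noise <- if (is.finite(cfg@noiseDf)) {
    cfg@noiseSd * stats::rt(length(E), df = cfg@noiseDf)
  } else stats::rnorm(length(E), sd = cfg@noiseSd)
  E <- E + matrix(noise, nrow(E))
  lapply(seq_len(n), function(i)
    ExpressionProfile(E[, i], geneIds = genes, sampleId = sampleId(genotypes[[i]])))
}

#' Place eQTLs on a panel
#'
#' Samples `cfg@nEQTLs` distinct sites uniformly and assigns each
#' `cfg@genesPerEQTL` dedicated eGenes (`g<site>_<k>`); significance is drawn
#' uniformly to give pruning a well-defined order.
#'
#' @param cfg a [SimConfig-class].
#' @param seed optional seed (NA = leave RNG state alone).
#' @return an [EQTLMap-class].
#' @export
simulateEQTLMap <- function(cfg, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  sites <- sort(sample.int(cfg@vSites, cfg@nEQTLs))
  EQTLMap(siteIndex = sites,
          geneSets = lapply(sites, function(s)
            sprintf("g%d_%d", s, seq_len(cfg@genesPerEQTL))),
          variantIds = paste0("v", sites),
          significance = stats::runif(cfg@nEQTLs))
}

#' Build a complete linking fixture
#'
#' Generates, under one seed: a reference panel, an eQTL map with effects,
#' disjoint train/test individuals with matched expression, and a pool of
#' unmatched decoy genotypes from the same panel (optionally from a
#' frequency-shifted panel, emulating an ancestry-mismatched candidate set).
#' Test expression sample ids are suffixed `.e` so that queries and candidates
#' have distinct identifiers; `truth` maps each query id to its matching
#' genotype id.
#'
#' @param cfg a [SimConfig-class].
#' @param decoyShift fraction of panel haplotypes re-drawn at random allele
#'   frequencies before simulating decoys (0 = same population).
#' @return list with `panel`, `map`, `effects`, `train` / `test` (each a list
#'   of `genotypes` and `expressions`), `decoys`, and `truth`.
#' @export
makeLinkingFixture <- function(cfg = simConfig(), decoyShift = 0) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  panel <- simulatePanel(cfg, seed = NA)
  map <- simulateEQTLMap(cfg, seed = NA)
  effects <- simulateEffects(map, cfg, seed = NA)
  train <- simulateIndividuals(panel, cfg, cfg@nTrain, idPrefix = "tr", seed = NA)
  test <- simulateIndividuals(panel, cfg, cfg@nTest, idPrefix = "te", seed = NA)
  trainE <- simulateExpression(train, map, cfg, effects, seed = NA)
  testE <- simulateExpression(test, map, cfg, effects, seed = NA)
  testE <- lapply(testE, function(e) {
    e@sampleId <- paste0(e@sampleId, ".e"); e
  })
  decoys <- list()
  if (cfg@nDecoys > 0) {
    dpanel <- panel
    if (decoyShift > 0) {
      K <- nHaplotypes(panel); V <- nVariants(panel)
      redraw <- sample.int(K, max(1L, round(decoyShift * K)))
      freq <- stats::runif(V, 0.05, 0.95)
      A <- panel@alleles
      for (k in redraw) A[k, ] <- stats::rbinom(V, 1, freq)
      dpanel <- HaplotypePanel(A, variantIds = panel@variantIds,
                               positions = panel@positions,
                               geneticPos = panel@geneticPos)
    }
    decoys <- simulateIndividuals(dpanel, cfg, cfg@nDecoys, idPrefix = "dc",
                                  seed = NA)
  }
  truth <- stats::setNames(vapply(test, sampleId, ""),
                           paste0(vapply(test, sampleId, ""), ".e"))
  list(panel = panel, map = map, effects = effects,
       train = list(genotypes = train, expressions = trainE),
       test = list(genotypes = test, expressions = testE),
       decoys = decoys, truth = truth, cfg = cfg)
}
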