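# S4 classes for the core data objects.

#' Reference haplotype panel
#'
#' A `HaplotypePanel` holds the K phased reference haplotypes over V biallelic
#' sites that the haplotype-copying hidden Markov model (HMM) copies from.
#' Alleles are coded 0 (reference) / 1 (alternate). Each site carries a
#' physical coordinate (bp, 1-based, strictly increasing) and a genetic-map
#' coordinate (centimorgan, non-decreasing); the genetic map drives the
#' between-site switch probabilities of the copying process.
#'
#' @slot alleles integer matrix, K haplotypes x V sites, entries in \{0, 1\}.
#' @slot variantIds character vector of V unique variant identifiers.
#' @slot positions numeric vector of V physical positions (bp).
#' @slot geneticPos numeric vector of V genetic-map positions (cM).
#'
#' @examples
#' p <- HaplotypePanel(matrix(c(0L, 1L, 1L, 0L), 2, 2))
#' nHaplotypes(p); nVariants(p)
#' @export
setClass("HaplotypePanel",
  slots = c(alleles = "matrix", variantIds = "character",
            positions = "numeric", geneticPos = "numeric"))

setValidity("HaplotypePanel", function(object) {
  a <- object@alleles
  if (nrow(a) < 1L || ncol(a) < 1L) return("panel needs K >= 1 and V >= 1")
  if (!all(a %in% c(0L, 1L))) return("panel alleles must all be 0 or 1")
  V <- ncol(a)
  if (length(object@variantIds) != V) return("variantIds length must equal V")
  if (anyDuplicated(object@variantIds)) return("variantIds must be unique")
  if (length(object@positions) != V) return("positions length must equal V")
  if (V > 1 && any(diff(object@positions) <= 0))
    return("physical positions must be strictly increasing")
  if (length(object@geneticPos) != V) return("geneticPos length must equal V")
  if (V > 1 && any(diff(object@geneticPos) < 0))
    return("genetic-map positions must be non-decreasing")
  TRUE
})

#' @param alleles K x V matrix of 0/1 alleles.
#' @param variantIds,positions,geneticPos per-site metadata; defaults are
#'   generated identifiers, 1 kb spacing, and a 1 cM/Mb map.
#' @rdname HaplotypePanel-class
#' @export
HaplotypePanel <- function(alleles,
                           variantIds = paste0("v", seq_len(ncol(alleles))),
                           positions = seq_len(ncol(alleles)) * 1000,
                           geneticPos = positions / 1e6) {
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  new("HaplotypePanel", alleles = alleles, variantIds = as.character(variantIds),
      positions = as.numeric(positions), geneticPos = as.numeric(geneticPos))
}

#' Copying-HMM parameters
#'
#' Transition, emission and prior parameters of the Li-Stephens style copying
#' chain: per-interval switch probabilities, a symmetric per-site copying
#' error, and the distribution over the initial copied haplotype.
#'
#' @slot switchProb numeric vector of V-1 probabilities of switching the
#'   copied haplotype between consecutive sites (a switch re-selects the state
#'   uniformly, self included).
#' @slot emissionError single numeric in (0, 0.5): probability the observed
#'   allele differs from the copied panel allele.
#' @slot prior numeric length-K initial-state distribution.
#' @export
setClass("HMMParams",
  slots = c(switchProb = "numeric", emissionError = "numeric", prior = "numeric"))

setValidity("HMMParams", function(object) {
  if (any(object@switchProb < 0 | object@switchProb > 1))
    return("switch probabilities must lie in [0, 1]")
  e <- object@emissionError
  if (length(e) != 1L || e <= 0 || e >= 0.5)
    return("emissionError must be a scalar in (0, 0.5)")
  if (abs(sum(object@prior) - 1) > 1e-12) return("prior must sum to 1")
  if (any(object@prior < 0)) return("prior must be non-negative")
  TRUE
})

#' @param switchProb,emissionError,prior see slots.
#' @rdname HMMParams-class
#' @export
HMMParams <- function(switchProb, emissionError, prior) {
  new("HMMParams", switchProb = as.numeric(switchProb),
      emissionError = as.numeric(emissionError), prior = as.numeric(prior))
}

#' Per-site external evidence for the copying chain
#'
#' Non-negative weights `w_s(a)` attached to the observed allele `a` at each
#' site, multiplying the chain's emission there. This is the interface through
#' which the eQTL factors enter the HMM: the factor value for each allele acts
#' as a noisy observation of the haplotype.
#'
#' @slot weights numeric V x 2 matrix; column 1 is `w_s(0)`, column 2 `w_s(1)`.
#' @export
setClass("SiteEvidence", slots = c(weights = "matrix"))

setValidity("SiteEvidence", function(object) {
  w <- object@weights
  if (ncol(w) != 2L) return("weights must have two columns (allele 0, allele 1)")
  if (any(w < 0) || any(!is.finite(w))) return("weights must be finite and >= 0")
  if (any(rowSums(w) <= 0)) return("each site needs at least one positive weight")
  TRUE
})

#' @param w0,w1 per-site weights for alleles 0 and 1.
#' @rdname SiteEvidence-class
#' @export
SiteEvidence <- function(w0, w1) {
  new("SiteEvidence", weights = cbind(w0 = as.numeric(w0), w1 = as.numeric(w1)))
}

#' Phased genotype profile of one individual
#'
#' The pair of haplotypes (maternal, paternal) of one individual over the
#' panel's sites, i.e. x = (h^m, h^p) with entries in \{0, 1\}.
#'
#' @slot maternal,paternal integer vectors of 0/1 alleles, equal length.
#' @slot sampleId single character identifier.
#' @export
setClass("GenotypeProfile",
  slots = c(maternal = "integer", paternal = "integer", sampleId = "character"))

setValidity("GenotypeProfile", function(object) {
  if (length(object@maternal) != length(object@paternal))
    return("haplotypes must have equal length")
  if (!all(c(object@maternal, object@paternal) %in% c(0L, 1L)))
    return("alleles must be 0 or 1")
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  TRUE
})

#' @param maternal,paternal 0/1 allele vectors.
#' @param sampleId sample identifier.
#' @rdname GenotypeProfile-class
#' @export
GenotypeProfile <- function(maternal, paternal, sampleId = "sample") {
  new("GenotypeProfile", maternal = as.integer(maternal),
      paternal = as.integer(paternal), sampleId = as.character(sampleId))
}

#' Normalized gene expression profile
#'
#' A length-G vector of normalized expression values keyed by gene identifier.
#' Expression is assumed already normalized upstream (the package standardizes
#' genes internally where a model requires it).
#'
#' @slot values numeric expression values.
#' @slot geneIds character gene identifiers, unique, same length as `values`.
#' @slot sampleId single character identifier.
#' @export
setClass("ExpressionProfile",
  slots = c(values = "numeric", geneIds = "character", sampleId = "character"))

setValidity("ExpressionProfile", function(object) {
  if (length(object@values) != length(object@geneIds))
    return("values and geneIds must have equal length")
  if (any(!is.finite(object@values))) return("expression values must be finite")
  if (anyDuplicated(object@geneIds)) return("gene identifiers must be unique")
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  TRUE
})

#' @param values,geneIds,sampleId see slots.
#' @rdname ExpressionProfile-class
#' @export
ExpressionProfile <- function(values, geneIds = names(values), sampleId = "sample") {
  if (is.null(geneIds)) geneIds <- paste0("g", seq_along(values))
  new("ExpressionProfile", values = unname(as.numeric(values)),
      geneIds = as.character(geneIds), sampleId = as.character(sampleId))
}

#' eQTL-to-eGene map
#'
#' For each eQTL: its site index into the panel, its variant identifier, the
#' non-empty set Q(s) of associated genes (eGenes), an optional association
#' direction hint (sign, used by extremity-based linking), and an optional
#' significance score (larger = more significant, used to order greedy
#' pruning).
#'
#' @slot siteIndex integer site indices into the panel (unique).
#' @slot variantIds character variant identifiers, parallel to `siteIndex`.
#' @slot geneSets list of character vectors, the eGene set per eQTL.
#' @slot direction numeric signs (may be NA).
#' @slot significance numeric scores (larger = more significant; may be NA).
#' @export
setClass("EQTLMap",
  slots = c(siteIndex = "integer", variantIds = "character", geneSets = "list",
            direction = "numeric", significance = "numeric"))

setValidity("EQTLMap", function(object) {
  n <- length(object@siteIndex)
  if (length(object@variantIds) != n || length(object@geneSets) != n ||
      length(object@direction) != n || length(object@significance) != n)
    return("all per-eQTL slots must have equal length")
  if (n == 0L) return("eQTL map must contain at least one eQTL")
  if (anyDuplicated(object@siteIndex)) return("each eQTL must map to a distinct site")
  if (any(object@siteIndex < 1L)) return("site indices must be positive")
  if (any(lengths(object@geneSets) < 1L)) return("every Q(s) must be non-empty")
  TRUE
})

#' @param siteIndex,variantIds,geneSets,direction,significance see slots.
#' @rdname EQTLMap-class
#' @export
EQTLMap <- function(siteIndex, geneSets, variantIds = paste0("v", siteIndex),
                    direction = rep(NA_real_, length(siteIndex)),
                    significance = rep(NA_real_, length(siteIndex))) {
  if (is.character(geneSets)) geneSets <- as.list(geneSets)
  new("EQTLMap", siteIndex = as.integer(siteIndex),
      variantIds = as.character(variantIds),
      geneSets = lapply(geneSets, as.character),
      direction = as.numeric(direction), significance = as.numeric(significance))
}

#' Learned per-eQTL factor parameters
#'
#' The intercept `alpha_s` and eGene weight vector `beta_s` of the logistic
#' factor attached to each eQTL: the factor assigns allele 1 probability
#' `sigmoid(alpha_s + beta_s' e_Q(s))`.
#'
#' @slot alpha numeric intercepts, one per eQTL.
#' @slot beta list of numeric weight vectors, `|Q(s)|` each.
#' @export
setClass("QTLFactorParams", slots = c(alpha = "numeric", beta = "list"))

setValidity("QTLFactorParams", function(object) {
  if (length(object@alpha) != length(object@beta))
    return("alpha and beta must have equal length")
  if (!all(is.finite(object@alpha)) || !all(is.finite(unlist(object@beta, use.names = FALSE))))
    return("factor parameters must be finite")
  TRUE
})

#' Full discriminative sequence model
#'
#' Bundles the copying-HMM parameters, the eQTL map, the learned factor
#' parameters, and the frozen per-gene standardization (centre/scale computed
#' on training expression) applied before factor evaluation.
#'
#' @slot hmm an [HMMParams-class].
#' @slot qtl a [QTLFactorParams-class].
#' @slot map an [EQTLMap-class].
#' @slot exprCenter,exprScale named numeric standardization per gene.
#' @slot history numeric training objective trace (mean conditional
#'   log-likelihood per epoch).
#' @export
setClass("DSMParams",
  slots = c(hmm = "HMMParams", qtl = "QTLFactorParams", map = "EQTLMap",
            exprCenter = "numeric", exprScale = "numeric", history = "numeric"))

setValidity("DSMParams", function(object) {
  if (length(object@qtl@alpha) != length(object@map@siteIndex))
    return("factor parameters must align with the eQTL map")
  need <- lengths(object@map@geneSets)
  if (!all(lengths(object@qtl@beta) == need))
    return("each beta_s must match |Q(s)|")
  genes <- unique(unlist(object@map@geneSets, use.names = FALSE))
  if (!all(genes %in% names(object@exprCenter)) ||
      !all(genes %in% names(object@exprScale)))
    return("standardization must cover every mapped gene")
  if (any(object@exprScale[genes] <= 0)) return("exprScale must be positive")
  TRUE
})

#' Gaussian naive Bayes linker parameters
#'
#' Per retained eQTL (singleton eGene): the per-dosage-class Gaussian means of
#' the eGene's expression, a shared class standard deviation, and the
#' log genotype prior estimated from training dosage frequencies.
#'
#' @slot map pruned [EQTLMap-class].
#' @slot gene character, the single eGene used per site.
#' @slot mu numeric V x 3 matrix of class means (dosage 0, 1, 2).
#' @slot sigma numeric shared standard deviation per site (> 0).
#' @slot logPrior numeric V x 3 matrix of log genotype priors.
#' @export
setClass("GNBParams",
  slots = c(map = "EQTLMap", gene = "character", mu = "matrix",
            sigma = "numeric", logPrior = "matrix"))

setValidity("GNBParams", function(object) {
  n <- length(object@map@siteIndex)
  if (length(object@gene) != n || nrow(object@mu) != n ||
      length(object@sigma) != n || nrow(object@logPrior) != n)
    return("per-site slots must align with the map")
  if (ncol(object@mu) != 3L || ncol(object@logPrior) != 3L)
    return("mu and logPrior need one column per dosage class")
  if (any(object@sigma <= 0)) return("sigma must be positive")
  pr <- rowSums(exp(object@logPrior))
  if (any(abs(pr - 1) > 1e-8)) return("priors must sum to 1 per site")
  TRUE
})

#' Extremity-based linker parameters
#'
#' Per retained eQTL: the extremity quantile thresholds of the eGene's
#' training expression, the eQTL-eGene correlation and its direction, and the
#' Gaussian naive Bayes fallback used for non-extreme expression values.
#'
#' @slot gnb the fallback [GNBParams-class].
#' @slot extremityQ single numeric in (0.5, 1): quantile defining "extreme".
#' @slot corrMin single numeric in (0, 1]: minimum `|r|` for an eQTL to make
#'   extremity calls.
#' @slot lambda disagreement penalty (natural-log units) when a candidate does
#'   not carry the predicted homozygote.
#' @slot corr,lo,hi per-site training correlation and lower/upper expression
#'   thresholds.
#' @export
setClass("EBLParams",
  slots = c(gnb = "GNBParams", extremityQ = "numeric", corrMin = "numeric",
            lambda = "numeric", corr = "numeric", lo = "numeric", hi = "numeric"))

setValidity("EBLParams", function(object) {
  q <- object@extremityQ
  if (length(q) != 1L || q <= 0.5 || q >= 1) return("extremityQ must lie in (0.5, 1)")
  cm <- object@corrMin
  if (length(cm) != 1L || cm <= 0 || cm > 1) return("corrMin must lie in (0, 1]")
  n <- length(object@gnb@map@siteIndex)
  if (length(object@corr) != n || length(object@lo) != n || length(object@hi) != n)
    return("per-site slots must align with the map")
  TRUE
})

#' Matrix of pairwise log match scores
#'
#' Rows are query profiles, columns candidate profiles; entry (j, i) is the
#' log match score of candidate i for query j. Behaves as a numeric matrix
#' with unique row/column sample identifiers.
#'
#' @slot scorer character tag of the scoring model ("dsm", "gnb", "ebl", ...).
#' @export
setClass("ScoreMatrix", contains = "matrix", slots = c(scorer = "character"))

setValidity("ScoreMatrix", function(object) {
  if (any(!is.finite(object@.Data))) return("scores must be finite")
  dn <- dimnames(object@.Data)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    return("score matrix needs row and column sample identifiers")
  if (anyDuplicated(dn[[1]]) || anyDuplicated(dn[[2]]))
    return("sample identifiers must be unique per axis")
  TRUE
})

ScoreMatrix <- function(scores, scorer = "custom") {
  new("ScoreMatrix", scores, scorer = as.character(scorer))
}

#' Per-query Gaussian null model of match scores
#'
#' Mean and standard deviation of the mismatching-pair log scores of each
#' query, used to convert a match score into an upper-tail P-value.
#'
#' @slot queryIds character query identifiers.
#' @slot mean,sd numeric per-query Gaussian parameters (sd > 0).
#' @slot n integer number of mismatching scores used per query.
#' @export
setClass("NullModel",
  slots = c(queryIds = "character", mean = "numeric", sd = "numeric", n = "integer"))

setValidity("NullModel", function(object) {
  k <- length(object@queryIds)
  if (length(object@mean) != k || length(object@sd) != k || length(object@n) != k)
    return("per-query slots must have equal length")
  if (any(object@sd <= 0)) return("null standard deviations must be positive")
  TRUE
})

#' Synthetic-data configuration
#'
#' Parameters of the seeded generators: reference panel, mosaic diploid
#' individuals, and eQTL-coupled expression. Defaults define the package's
#' standard linking fixture (see the methods vignette for the rationale).
#'
#' @slot kPanel number of reference haplotypes.
#' @slot vSites number of biallelic sites.
#' @slot nTrain,nTest,nDecoys individuals in the training set, the matched
#'   test set, and the unmatched decoy candidate pool.
#' @slot nEQTLs number of eQTL sites (sampled uniformly among sites).
#' @slot genesPerEQTL eGenes per eQTL (> 1 creates redundant signals).
#' @slot nNoiseGenes genes unlinked to any eQTL.
#' @slot effectSize per-(eQTL, eGene) linear dosage effect magnitude.
#' @slot noiseSd scale of the expression noise.
#' @slot noiseDf degrees of freedom of the Student-t expression noise
#'   (`Inf`, the default, gives Gaussian noise; small values give the heavy
#'   tails that motivate extremity-based linking).
#' @slot ldBlockSize consecutive sites sharing one founder pool (LD blocks).
#' @slot nFounders founder haplotypes per block.
#' @slot founderError per-site copy error when panel haplotypes copy founders.
#' @slot cmPerSite genetic-map spacing between consecutive sites (cM).
#' @slot recombScale,emissionError copying-chain parameters used both to
#'   simulate individuals and as model defaults.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig",
  representation(kPanel = "integer", vSites = "integer", nTrain = "integer",
                 nTest = "integer", nDecoys = "integer", nEQTLs = "integer",
                 genesPerEQTL = "integer", nNoiseGenes = "integer",
                 effectSize = "numeric", noiseSd = "numeric",
                 noiseDf = "numeric",
                 ldBlockSize = "integer", nFounders = "integer",
                 founderError = "numeric", cmPerSite = "numeric",
                 recombScale = "numeric", emissionError = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  counts <- c(object@kPanel, object@vSites, object@nTrain, object@nTest,
              object@nEQTLs, object@genesPerEQTL, object@ldBlockSize,
              object@nFounders)
  if (any(counts < 1L)) return("all counts must be >= 1")
  if (object@nDecoys < 0L || object@nNoiseGenes < 0L)
    return("nDecoys and nNoiseGenes must be >= 0")
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  if (object@noiseDf <= 2) return("noiseDf must exceed 2 (Inf = Gaussian)")
  if (object@nEQTLs > object@vSites) return("cannot place more eQTLs than sites")
  if (length(object@seed) != 1L || is.na(object@seed)) return("seed must be set")
  TRUE
})

#' @param kPanel,vSites,nTrain,nTest,nDecoys,nEQTLs,genesPerEQTL,nNoiseGenes,effectSize,noiseSd,noiseDf,ldBlockSize,nFounders,founderError,cmPerSite,recombScale,emissionError,seed
#'   see the class slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(kPanel = 60, vSites = 300, nTrain = 300, nTest = 50,
                      nDecoys = 250, nEQTLs = 150, genesPerEQTL = 3,
                      nNoiseGenes = 50, effectSize = 1, noiseSd = 1,
                      noiseDf = Inf, ldBlockSize = 5, nFounders = 4, founderError = 0.02,
                      cmPerSite = 0.02, recombScale = 1, emissionError = 0.01,
                      seed = 1) {
  new("SimConfig", kPanel = as.integer(kPanel), vSites = as.integer(vSites),
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      nDecoys = as.integer(nDecoys), nEQTLs = as.integer(nEQTLs),
      genesPerEQTL = as.integer(genesPerEQTL), nNoiseGenes = as.integer(nNoiseGenes),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      noiseDf = as.numeric(noiseDf),
      ldBlockSize = as.integer(ldBlockSize), nFounders = as.integer(nFounders),
      founderError = as.numeric(founderError), cmPerSite = as.numeric(cmPerSite),
      recombScale = as.numeric(recombScale), emissionError = as.numeric(emissionError),
      seed = as.integer(seed))
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d sites (%s..%s)\n",
              nrow(object@alleles), ncol(object@alleles),
              object@variantIds[1], object@variantIds[length(object@variantIds)]))
})

setMethod("show", "HMMParams", function(object) {
  cat(sprintf("HMMParams: K = %d, emission error = %.4g, mean switch prob = %.4g\n",
              length(object@prior), object@emissionError,
              if (length(object@switchProb)) mean(object@switchProb) else 0))
})

setMethod("show", "GenotypeProfile", function(object) {
  cat(sprintf("GenotypeProfile '%s': %d phased sites, dosage sum = %d\n",
              object@sampleId, length(object@maternal),
              sum(object@maternal + object@paternal)))
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s': %d genes\n",
              object@sampleId, length(object@values)))
})

setMethod("show", "EQTLMap", function(object) {
  cat(sprintf("EQTLMap: %d eQTLs, %d distinct eGenes\n",
              length(object@siteIndex),
              length(unique(unlist(object@geneSets, use.names = FALSE)))))
})

setMethod("show", "DSMParams", function(object) {
  cat(sprintf("DSMParams: %d eQTL factors over %d genes%s\n",
              length(object@qtl@alpha),
              length(unique(unlist(object@map@geneSets, use.names = FALSE))),
              if (length(object@history))
                sprintf("; final training objective %.4f", tail(object@history, 1))
              else " (untrained)"))
})

setMethod("show", "GNBParams", function(object) {
  cat(sprintf("GNBParams: %d retained eQTLs\n", length(object@map@siteIndex)))
})

setMethod("show", "EBLParams", function(object) {
  cat(sprintf("EBLParams: %d retained eQTLs, extremity q = %.2f, |r| >= %.2f, lambda = %.2f\n",
              length(object@gnb@map@siteIndex), object@extremityQ,
              object@corrMin, object@lambda))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix (%s): %d queries x %d candidates\n",
              object@scorer, nrow(object), ncol(object)))
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel: %d per-query Gaussians (median sd %.3g)\n",
              length(object@queryIds), stats::median(object@sd)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: K = %d, V = %d, train/test/decoys = %d/%d/%d, ",
                     "%d eQTLs x %d genes, effect %.2f, noise sd %.2f, seed %d\n"),
              object@kPanel, object@vSites, object@nTrain, object@nTest,
              object@nDecoys, object@nEQTLs, object@genesPerEQTL,
              object@effectSize, object@noiseSd, object@seed))
})
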