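# Joint gradient learning of all eQTL factors.
#
# The trainer maximizes the normalized conditional log likelihood of the
# training haplotypes,
#   sum_i sum_{h in {h^m_i, h^p_i}} [ log p_HMM(h) + sum_s log phi_s(h_s, e_i)
#                                     - log Z(e_i) ],
# where Z(e) = sum_h p_HMM(h) prod_s phi_s(h_s, e) is the evidence-weighted
# chain normalizer. Normalizing by Z is what couples the factors across sites:
# redundant signals at linked eQTLs are absorbed instead of double-counted.
# The gradient w.r.t. the factor logit l_s = alpha_s + beta_s' e_Q(s) has the
# classic observed-minus-expected form d_is - 2 q_is, with d the dosage and q
# the posterior allele probability from the forward-backward pass.

# Assemble everything the objective needs once per training run.
.dsmTrainContext <- function(genotypes, expressions, panel, map, hmm,
                             standardize = TRUE) {
  stopifnot(is(panel, "HaplotypePanel"), is(map, "EQTLMap"), is(hmm, "HMMParams"))
  if (length(genotypes) < 2L) .stopf("training requires at least 2 pairs")
  if (length(genotypes) != length(expressions))
    .stopf("genotype and expression lists must be matched")
  V <- nVariants(panel)
  if (any(map@siteIndex > V)) .stopf("eQTL site index outside the panel")
  E <- .asExpressionMatrix(expressions)
  genes <- unique(unlist(map@geneSets, use.names = FALSE))
  if (!all(genes %in% rownames(E)))
    .stopf("unresolvable gene id(s) in Q(s): %s",
           paste(utils::head(setdiff(genes, rownames(E)), 3), collapse = ", "))
  if (standardize) {
    center <- rowMeans(E[genes, , drop = FALSE])
    scale <- apply(E[genes, , drop = FALSE], 1, stats::sd)
    scale[!is.finite(scale) | scale <= 0] <- 1
  } else {
    center <- stats::setNames(rep(0, length(genes)), genes)
    scale <- stats::setNames(rep(1, length(genes)), genes)
  }
  names(center) <- names(scale) <- genes
  Z <- .standardizeExpr(E, genes, center, scale)
  rownames(Z) <- genes
  H <- haplotypeMatrix(genotypes)
  D <- dosageMatrix(genotypes)[map@siteIndex, , drop = FALSE]
  logPrior <- .hmmLogLikBatch(H, panel, hmm)
  n <- length(genotypes)
  logPriorPair <- logPrior[2 * seq_len(n) - 1] + logPrior[2 * seq_len(n)]
  list(panel = panel, map = map, hmm = hmm, Z = Z, D = D, n = n, V = V,
       geneSets = map@geneSets, center = center, scale = scale,
       logPriorPair = logPriorPair,
       nBeta = lengths(map@geneSets))
}

.packTheta <- function(alpha, beta) c(alpha, unlist(beta, use.names = FALSE))

.unpackTheta <- function(theta, nBeta) {
  m <- length(nBeta)
  alpha <- theta[seq_len(m)]
  beta <- vector("list", m)
  off <- m
  for (s in seq_len(m)) {
    beta[[s]] <- theta[off + seq_len(nBeta[s])]
    off <- off + nBeta[s]
  }
  list(alpha = alpha, beta = beta)
}

# Mean per-haplotype conditional log likelihood and its gradient at theta.
.dsmObjGrad <- function(theta, ctx, wantGrad = TRUE) {
  par <- .unpackTheta(theta, ctx$nBeta)
  m <- length(par$alpha)
  n <- ctx$n
  L <- matrix(par$alpha, m, n)
  for (s in seq_len(m)) {
    b <- par$beta[[s]]
    if (length(b))
      L[s, ] <- L[s, ] + drop(crossprod(ctx$Z[ctx$geneSets[[s]], , drop = FALSE], b))
  }
  p1 <- .clipProb(.sigmoid(L))
  W0 <- matrix(1, ctx$V, n)
  W1 <- matrix(1, ctx$V, n)
  W0[ctx$map@siteIndex, ] <- 1 - p1
  W1[ctx$map@siteIndex, ] <- p1
  fb <- .fb_sum_batch(ctx$panel@alleles, W0, W1, ctx$hmm@switchProb,
                      ctx$hmm@emissionError, ctx$hmm@prior)
  obsTerm <- colSums(ctx$D * log(p1) + (2 - ctx$D) * log(1 - p1))
  obj <- sum(obsTerm + ctx$logPriorPair - 2 * fb$logZ) / (2 * n)
  if (!is.finite(obj)) .stopf("non-finite training objective; check inputs")
  out <- list(objective = obj)
  if (wantGrad) {
    Q <- fb$allelePosterior[ctx$map@siteIndex, , drop = FALSE]
    G <- (ctx$D - 2 * Q) / (2 * n)           # d obj / d l_s per sample
    dalpha <- rowSums(G)
    dbeta <- vector("list", m)
    for (s in seq_len(m)) {
      dbeta[[s]] <- drop(ctx$Z[ctx$geneSets[[s]], , drop = FALSE] %*% G[s, ])
    }
    out$gradient <- .packTheta(dalpha, dbeta)
  }
  out
}

#' Train a discriminative sequence model
#'
#' Jointly fits all eQTL factor parameters (alpha_s, beta_s) by full-batch
#' Adam ascent on the normalized conditional log likelihood of the training
#' haplotypes given their expression profiles. The copying-chain parameters
#' are held fixed; parameters start at zero (the flat, symmetric factor).
#' Per-gene expression standardization is computed on the training data and
#' frozen into the returned model.
#'
#' @param genotypes list of [GenotypeProfile-class] (training individuals).
#' @param expressions matched list of [ExpressionProfile-class].
#' @param panel reference [HaplotypePanel-class].
#' @param eqtlMap an [EQTLMap-class] over the panel's sites.
#' @param hmm optional [HMMParams-class]; defaults to
#'   `buildHMMParams(panel, recombScale, emissionError)`.
#' @param lr Adam learning rate (default 0.025).
#' @param epochs number of full-batch epochs (default 50).
#' @param recombScale,emissionError chain defaults used when `hmm` is NULL.
#' @param standardize standardize mapped genes to zero mean, unit variance on
#'   the training data (default TRUE).
#' @param verbose print the objective every 10 epochs.
#' @return a trained [DSMParams-class]; `@history` holds the per-epoch mean
#'   conditional log likelihood (non-decreasing up to optimizer noise).
#' @seealso [trainDSMWindows()] for windowed training, [dsmLogScore()] and
#'   [scoreAll()] for scoring.
#' @export
trainDSM <- function(genotypes, expressions, panel, eqtlMap, hmm = NULL,
                     lr = 0.025, epochs = 50, recombScale = 1,
                     emissionError = 0.01, standardize = TRUE, verbose = FALSE) {
  if (is.null(hmm)) hmm <- buildHMMParams(panel, recombScale, emissionError)
  ctx <- .dsmTrainContext(genotypes, expressions, panel, eqtlMap, hmm,
                          standardize)
  theta <- numeric(length(ctx$nBeta) + sum(ctx$nBeta))
  adam <- .adamInit(length(theta))
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    og <- .dsmObjGrad(theta, ctx)
    adam <- .adamStep(adam, og$gradient, lr)
    theta <- theta + adam$delta
    history[ep] <- og$objective
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: objective %.6f", ep, og$objective))
  }
  par <- .unpackTheta(theta, ctx$nBeta)
  new("DSMParams", hmm = hmm,
      qtl = new("QTLFactorParams", alpha = par$alpha, beta = par$beta),
      map = eqtlMap, exprCenter = ctx$center, exprScale = ctx$scale,
      history = history)
}

#' Subset a reference panel to a range of sites
#'
#' @param panel a [HaplotypePanel-class].
#' @param sites integer site indices (must be sorted, unique).
#' @return a [HaplotypePanel-class] over the selected sites.
#' @export
subsetPanel <- function(panel, sites) {
  sites <- as.integer(sites)
  stopifnot(!is.unsorted(sites, strictly = TRUE), all(sites >= 1),
            all(sites <= nVariants(panel)))
  HaplotypePanel(panel@alleles[, sites, drop = FALSE],
                 variantIds = panel@variantIds[sites],
                 positions = panel@positions[sites],
                 geneticPos = panel@geneticPos[sites])
}

#' Windowed DSM training
#'
#' Partitions the eQTLs (in site order) into consecutive windows of at most
#' `windowSize` eQTLs, trains a separate DSM per window on the corresponding
#' contiguous segment of panel sites, and returns the per-window models. The
#' per-individual total log score of the windowed model is the sum of the
#' per-window scores; [combineDSMWindows()] merges the windows back into one
#' [DSMParams-class] for scoring.
#'
#' @inheritParams trainDSM
#' @param windowSize maximum eQTLs per window (>= 1; the published default for
#'   chromosome-scale runs is 750).
#' @param ... passed to [trainDSM()].
#' @return list of [DSMParams-class], one per window, with the panel-site
#'   range of each window in `attr(, "siteRange")`.
#' @export
trainDSMWindows <- function(genotypes, expressions, panel, eqtlMap,
                            windowSize = 750, ...) {
  stopifnot(windowSize >= 1)
  ord <- order(eqtlMap@siteIndex)
  m <- length(ord)
  if (m == 0L) .stopf("empty eQTL map")
  windows <- split(ord, ceiling(seq_len(m) / windowSize))
  V <- nVariants(panel)
  models <- vector("list", length(windows))
  segStart <- 1L
  for (w in seq_along(windows)) {
    idx <- windows[[w]]
    segEnd <- if (w == length(windows)) V else max(eqtlMap@siteIndex[idx])
    sites <- segStart:segEnd
    subPanel <- subsetPanel(panel, sites)
    subMap <- EQTLMap(siteIndex = eqtlMap@siteIndex[idx] - segStart + 1L,
                      geneSets = eqtlMap@geneSets[idx],
                      variantIds = eqtlMap@variantIds[idx],
                      direction = eqtlMap@direction[idx],
                      significance = eqtlMap@significance[idx])
    subGeno <- lapply(genotypes, function(g)
      GenotypeProfile(g@maternal[sites], g@paternal[sites], g@sampleId))
    models[[w]] <- trainDSM(subGeno, expressions, subPanel, subMap, ...)
    attr(models[[w]], "siteRange") <- c(segStart, segEnd)
    segStart <- segEnd + 1L
  }
  models
}

#' Merge windowed DSM models for scoring
#'
#' Concatenates the per-window factor parameters and eQTL maps back onto the
#' full panel coordinate system. The merged model scores identically to the
#' sum of per-window scores.
#'
#' @param models list returned by [trainDSMWindows()].
#' @param panel the full [HaplotypePanel-class]; used to rebuild the chain
#'   parameters so that posterior computation also works on the merged model.
#' @param recombScale,emissionError chain parameters for the rebuilt
#'   [HMMParams-class].
#' @return a single [DSMParams-class].
#' @export
combineDSMWindows <- function(models, panel, recombScale = 1,
                              emissionError = 0.01) {
  stopifnot(length(models) >= 1L)
  offs <- vapply(models, function(m) attr(m, "siteRange")[1] - 1L, integer(1))
  siteIndex <- unlist(mapply(function(m, o) m@map@siteIndex + o, models, offs,
                             SIMPLIFY = FALSE))
  map <- EQTLMap(siteIndex = siteIndex,
                 geneSets = do.call(c, lapply(models, function(m) m@map@geneSets)),
                 variantIds = unlist(lapply(models, function(m) m@map@variantIds)),
                 direction = unlist(lapply(models, function(m) m@map@direction)),
                 significance = unlist(lapply(models, function(m) m@map@significance)))
  center <- do.call(c, lapply(models, function(m) m@exprCenter))
  scale <- do.call(c, lapply(models, function(m) m@exprScale))
  center <- center[!duplicated(names(center))]
  scale <- scale[!duplicated(names(scale))]
  new("DSMParams",
      hmm = buildHMMParams(panel, recombScale, emissionError),
      qtl = new("QTLFactorParams",
                alpha = unlist(lapply(models, function(m) m@qtl@alpha)),
                beta = do.call(c, lapply(models, function(m) m@qtl@beta))),
      map = map, exprCenter = center, exprScale = scale,
      history = unlist(lapply(models, function(m) m@history)))
}
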