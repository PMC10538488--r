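# eQTL factors and DSM inference: haplotype-decoupled marginals, match
# scores, allele posteriors, and the exact (paired-chain) diploid variant.

#' Logistic eQTL factor
#'
#' The per-eQTL factor couples a haplotype allele to the expression of the
#' eQTL's eGene set: `phi(1, e) = sigmoid(alpha + beta' e)` and
#' `phi(0, e) = 1 - phi(1, e)`, so the two allele values always sum to one.
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param hAllele 0 or 1.
#' @param eSub expression values of the eGene set Q(s) (standardized as the
#'   model was trained).
#' @param alpha scalar intercept.
#' @param beta weight vector, same length as `eSub`.
#' @return factor probability in (0, 1).
#' @examples
#' qtlFactor(1, 0, alpha = log(3), beta = 0)  # 0.75
#' @export
qtlFactor <- function(hAllele, eSub, alpha, beta) {
  if (length(beta) != length(eSub)) .stopf("beta and e_Q(s) must have equal length")
  stopifnot(hAllele %in% c(0, 1))
  p1 <- .clipProb(.sigmoid(alpha + sum(beta * eSub)))
  if (hAllele == 1) p1 else 1 - p1
}

# Standardized expression matrix for mapped genes: rows = genes in `genes`,
# columns = samples. E is a raw G x n expression matrix with rownames.
.standardizeExpr <- function(E, genes, center, scale) {
  idx <- match(genes, rownames(E))
  if (anyNA(idx))
    .stopf("expression matrix is missing mapped gene(s): %s",
           paste(utils::head(genes[is.na(idx)], 3), collapse = ", "))
  (E[idx, , drop = FALSE] - center[genes]) / scale[genes]
}

# Per-eQTL logits l_s = alpha_s + beta_s' e_Q(s) for each sample.
# Returns a (number of eQTLs) x n matrix.
.dsmLogits <- function(params, E) {
  map <- params@map
  genes <- unique(unlist(map@geneSets, use.names = FALSE))
  Z <- .standardizeExpr(E, genes, params@exprCenter, params@exprScale)
  rownames(Z) <- genes
  n <- ncol(Z)
  L <- matrix(params@qtl@alpha, length(map@siteIndex), n)
  for (s in seq_along(map@siteIndex)) {
    b <- params@qtl@beta[[s]]
    L[s, ] <- L[s, ] + drop(crossprod(Z[map@geneSets[[s]], , drop = FALSE], b))
  }
  L
}

# Evidence weight matrices over all V panel sites for each sample: weight 1 at
# non-eQTL sites, the clipped factor probabilities at eQTL sites.
.dsmEvidence <- function(params, E, V) {
  L <- .dsmLogits(params, E)
  p1 <- .clipProb(.sigmoid(L))
  n <- ncol(p1)
  W0 <- matrix(1, V, n)
  W1 <- matrix(1, V, n)
  W0[params@map@siteIndex, ] <- 1 - p1
  W1[params@map@siteIndex, ] <- p1
  list(W0 = W0, W1 = W1, logits = L)
}

.asExpressionMatrix <- function(e) {
  if (is(e, "ExpressionProfile")) e <- list(e)
  if (is.list(e)) return(expressionMatrix(e))
  stopifnot(is.matrix(e), !is.null(rownames(e)))
  e
}

#' Unnormalized DSM log marginal of one haplotype
#'
#' The haplotype-decoupled DSM marginal: the copying-chain marginal of `h`
#' with the eQTL factor of each mapped site injected as external evidence,
#' i.e. `log sum_z pi tau eps(h_s|z_s) phi_s(h_s, e_Q(s))`. Sites of the panel
#' not covered by the eQTL map carry evidence weight 1. Runtime and memory are
#' linear in the panel depth K and the number of sites.
#'
#' @param h length-V 0/1 allele vector.
#' @param e an [ExpressionProfile-class].
#' @param params a trained [DSMParams-class].
#' @param panel the [HaplotypePanel-class] the model was trained against.
#' @return scalar log marginal.
#' @export
dsmLogMarginal <- function(h, e, params, panel) {
  stopifnot(is(params, "DSMParams"))
  V <- nVariants(panel)
  h <- .asAlleleVector(h, V)
  E <- .asExpressionMatrix(e)
  ev <- .dsmEvidence(params, E, V)
  w <- SiteEvidence(ev$W0[, 1], ev$W1[, 1])
  forwardBackward(h, panel, params@hmm, evidence = w)$logMarginal
}

#' DSM log match score
#'
#' The log of the match score `M(x, e) = p~_DSM(x | e) / p_HMM(x)`: the
#' DSM marginal of the diploid profile normalized by its copying-chain prior
#' probability, so that candidates are not favoured merely for being likely
#' haplotypes. Under the haplotype-decoupled factorization the chain terms
#' cancel exactly and the score reduces to the sum of log factor values at the
#' eQTL sites, which is how it is computed.
#'
#' @param x a [GenotypeProfile-class].
#' @param e an [ExpressionProfile-class].
#' @param params a trained [DSMParams-class].
#' @return scalar log match score.
#' @export
dsmLogScore <- function(x, e, params) {
  stopifnot(is(x, "GenotypeProfile"), is(params, "DSMParams"))
  E <- .asExpressionMatrix(e)
  L <- .dsmLogits(params, E)[, 1]
  p1 <- .clipProb(.sigmoid(L))
  s <- params@map@siteIndex
  d <- (x@maternal + x@paternal)[s]
  sum(d * log(p1) + (2 - d) * log(1 - p1))
}

#' @describeIn dsmLogScore generic pairwise score method for DSM parameters.
#' @export
setMethod("logScore", signature(params = "DSMParams"),
          function(x, e, params, ...) dsmLogScore(x, e, params))

#' Posterior allele and dosage probabilities given expression
#'
#' Sums the haplotype out of the evidence-weighted copying chain to obtain,
#' for each site, the posterior probability `q_s = P(h_s = 1 | e)` that a
#' haplotype of the profiled individual carries the alternate allele. Under
#' the haplotype-decoupled model the two haplotypes are exchangeable given
#' `e`, so the dosage posterior is Binomial(2, q_s).
#'
#' @param e an [ExpressionProfile-class], a list of them, or a G x n matrix.
#' @param params a trained [DSMParams-class].
#' @param panel the reference [HaplotypePanel-class].
#' @return list with `allele` (V x n matrix of q values), `dosage` (V x n
#'   matrix of maximum-a-posteriori dosages), and `logZ` (per-sample log
#'   normalizer of the evidence-weighted chain).
#' @export
dsmPosteriors <- function(e, params, panel) {
  stopifnot(is(params, "DSMParams"), is(panel, "HaplotypePanel"))
  E <- .asExpressionMatrix(e)
  V <- nVariants(panel)
  ev <- .dsmEvidence(params, E, V)
  res <- .fb_sum_batch(panel@alleles, ev$W0, ev$W1, params@hmm@switchProb,
                       params@hmm@emissionError, params@hmm@prior)
  q <- res$allelePosterior
  # MAP dosage under Binomial(2, q): boundaries at q = 1/3 and 2/3
  dmap <- matrix(1L, nrow(q), ncol(q))
  dmap[q < 1 / 3] <- 0L
  dmap[q > 2 / 3] <- 2L
  colnames(q) <- colnames(E)
  list(allele = q, dosage = dmap, logZ = as.numeric(res$logZ))
}

#' Exact diploid DSM log score
#'
#' Runs the paired-chain forward recursion over the joint hidden state
#' `(z^m, z^p)` (a quadratic, K^2 state space) with a genotype-level factor at
#' each eQTL site, without the haplotype decoupling. This exists to quantify
#' the effect of the haplotype approximation on small instances: when the
#' genotype factor is the product of the two haplotype factors
#' (`factorForm = "product"`) the exact score equals the decoupled score; the
#' `"ordinal"` form is a genuinely non-factorizable 3-level cumulative-logit
#' factor over the dosage with cutpoints `ordinalCuts`.
#'
#' @inheritParams dsmLogScore
#' @param panel the reference [HaplotypePanel-class].
#' @param factorForm `"product"` or `"ordinal"`.
#' @param ordinalCuts increasing length-2 cutpoints of the ordinal factor.
#' @param maxStates refuse instances whose joint state space K^2 exceeds this.
#' @return scalar log match score (joint marginal minus the diploid chain
#'   prior log likelihood).
#' @export
dsmExactDiploidLogScore <- function(x, e, params, panel,
                                    factorForm = c("product", "ordinal"),
                                    ordinalCuts = c(-1, 1), maxStates = 1e4) {
  factorForm <- match.arg(factorForm)
  stopifnot(is(x, "GenotypeProfile"), is(params, "DSMParams"))
  K <- nHaplotypes(panel)
  V <- nVariants(panel)
  if (K^2 > maxStates) .stopf("joint state space too large (K^2 = %d)", K^2)
  E <- .asExpressionMatrix(e)
  L <- .dsmLogits(params, E)[, 1]
  p1 <- .clipProb(.sigmoid(L))
  # genotype-level factor value at the observed x_s, per eQTL site
  d <- (x@maternal + x@paternal)[params@map@siteIndex]
  phi <- switch(factorForm,
    product = p1^d * (1 - p1)^(2 - d),
    ordinal = {
      cum0 <- .clipProb(.sigmoid(ordinalCuts[1] - L))        # P(d <= 0)
      cum1 <- .clipProb(.sigmoid(ordinalCuts[2] - L))        # P(d <= 1)
      cbind(cum0, pmax(cum1 - cum0, .PROB_FLOOR), pmax(1 - cum1, .PROB_FLOOR))[
        cbind(seq_along(d), d + 1L)]
    })
  w <- rep(1, V)
  w[params@map@siteIndex] <- phi
  logJoint <- .diploidForward(x, panel, params@hmm, w)
  logJoint - hmmLogLik(x, panel, params@hmm)
}

# Scaled forward pass over the joint (z^m, z^p) chain with per-site scalar
# genotype evidence w. The joint transition is the product of two independent
# switch operators, applied coordinate-wise to the K x K forward mass.
.diploidForward <- function(x, panel, params, w) {
  K <- nHaplotypes(panel)
  V <- nVariants(panel)
  eps <- params@emissionError
  A <- panel@alleles
  logZ <- 0
  f <- NULL
  for (s in seq_len(V)) {
    em <- ifelse(A[, s] == x@maternal[s], 1 - eps, eps)
    ep <- ifelse(A[, s] == x@paternal[s], 1 - eps, eps)
    emit <- outer(em, ep) * w[s]
    if (s == 1L) {
      f <- outer(params@prior, params@prior) * emit
    } else {
      rho <- params@switchProb[s - 1]
      # apply (1-rho) I + rho/K 1 along each coordinate
      g <- (1 - rho) * f + rho * matrix(colSums(f), K, K, byrow = TRUE) / K
      g <- (1 - rho) * g + rho * matrix(rowSums(g), K, K) / K
      f <- g * emit
    }
    c0 <- sum(f)
    if (c0 <= 0) .stopf("degenerate evidence at site %d", s)
    f <- f / c0
    logZ <- logZ + log(c0)
  }
  logZ
}

# Brute-force oracle for the joint diploid chain: enumerates all (K^2)^V joint
# state paths. Internal; used by tests.
.bruteForceDiploid <- function(x, panel, params, w) {
  K <- nHaplotypes(panel)
  V <- nVariants(panel)
  if ((K^2)^V > 1e6) .stopf("instance too large for diploid path enumeration")
  eps <- params@emissionError
  A <- panel@alleles
  states <- as.matrix(expand.grid(zm = seq_len(K), zp = seq_len(K)))
  S <- nrow(states)
  logEmit <- sapply(seq_len(V), function(s) {
    em <- ifelse(A[states[, 1], s] == x@maternal[s], 1 - eps, eps)
    ep <- ifelse(A[states[, 2], s] == x@paternal[s], 1 - eps, eps)
    log(em * ep * w[s])
  })
  logEmit <- matrix(logEmit, nrow = S)
  logPrior <- log(params@prior[states[, 1]] * params@prior[states[, 2]])
  trans1 <- function(rho) {
    m <- matrix(rho / K, K, K); diag(m) <- diag(m) + 1 - rho; m
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), V)))
  lp <- logPrior[paths[, 1]] + logEmit[cbind(paths[, 1], 1L)]
  if (V > 1) {
    for (s in 2:V) {
      Tm <- trans1(params@switchProb[s - 1])
      Tj <- Tm[cbind(states[paths[, s - 1], 1], states[paths[, s], 1])] *
            Tm[cbind(states[paths[, s - 1], 2], states[paths[, s], 2])]
      lp <- lp + log(Tj) + logEmit[cbind(paths[, s], s)]
    }
  }
  .logSumExp(lp)
}

#' Held-out conditional log loss of a DSM
#'
#' Mean negative normalized conditional log likelihood
#' `-(1/2n) sum_i sum_{h in x_i} log p_DSM(h | e_i)` per haplotype, where
#' `p_DSM(h|e) = p_HMM(h) prod_s phi_s(h_s, e) / Z(e)`. This is the quantity
#' the trainer maximizes (negated) and the calibration yardstick used to
#' compare against naive per-site factor products.
#'
#' @param genotypes,expressions matched lists of profiles.
#' @param params a trained [DSMParams-class].
#' @param panel the reference [HaplotypePanel-class].
#' @return mean per-haplotype log loss (nats).
#' @export
dsmLogLoss <- function(genotypes, expressions, params, panel) {
  E <- .asExpressionMatrix(expressions)
  V <- nVariants(panel)
  ev <- .dsmEvidence(params, E, V)
  res <- .fb_sum_batch(panel@alleles, ev$W0, ev$W1, params@hmm@switchProb,
                       params@hmm@emissionError, params@hmm@prior)
  H <- haplotypeMatrix(genotypes)
  logPrior <- .hmmLogLikBatch(H, panel, params@hmm)
  p1 <- .clipProb(.sigmoid(ev$logits))
  s <- params@map@siteIndex
  n <- length(genotypes)
  ll <- 0
  for (i in seq_len(n)) {
    for (hcol in c(2L * i - 1L, 2L * i)) {
      hs <- H[s, hcol]
      ll <- ll + sum(hs * log(p1[, i]) + (1 - hs) * log(1 - p1[, i])) +
        logPrior[hcol] - res$logZ[i]
    }
  }
  -ll / (2 * n)
}
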