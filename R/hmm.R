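# Li-Stephens haplotype-copying chain: parameter construction, scaled
# forward-backward with optional external per-site evidence, and a brute-force
# path-enumeration oracle.

#' Build copying-chain parameters from a genetic map
#'
#' Derives the per-interval switch probabilities from the panel's genetic-map
#' coordinates using the standard Li-Stephens form
#' `switchProb_s = 1 - exp(-recombScale * dg_s / K)`, where `dg_s` is the
#' genetic distance (cM) between consecutive sites and K the panel depth.
#' Conditional on a switch the new state is uniform over the K haplotypes
#' (self included), and the initial prior is uniform.
#'
#' @param panel a [HaplotypePanel-class].
#' @param recombScale positive scalar multiplying the map distances.
#' @param emissionError copying error in (0, 0.5).
#' @return an [HMMParams-class].
#' @examples
#' p <- HaplotypePanel(matrix(0:1, 2, 3), geneticPos = c(0, 0.01, 0.02))
#' buildHMMParams(p, recombScale = 1)
#' @export
buildHMMParams <- function(panel, recombScale = 1, emissionError = 0.01) {
  stopifnot(is(panel, "HaplotypePanel"))
  if (recombScale <= 0) .stopf("recombScale must be positive")
  dg <- diff(panel@geneticPos)
  if (any(dg < 0)) .stopf("invalid genetic map: positions must be non-decreasing")
  K <- nHaplotypes(panel)
  HMMParams(switchProb = 1 - exp(-recombScale * dg / K),
            emissionError = emissionError,
            prior = rep(1 / K, K))
}

.asAlleleVector <- function(h, V) {
  if (is(h, "GenotypeProfile")) .stopf("expected a single haplotype, not a diploid profile")
  h <- as.integer(h)
  if (length(h) != V) .stopf("haplotype length %d does not match panel width %d", length(h), V)
  if (!all(h %in% c(0L, 1L))) .stopf("haplotype alleles must be 0 or 1")
  h
}

.evidenceAtObserved <- function(evidence, h) {
  if (is.null(evidence)) return(numeric(0))
  stopifnot(is(evidence, "SiteEvidence"))
  w <- evidence@weights
  if (nrow(w) != length(h)) .stopf("evidence has %d sites, haplotype %d", nrow(w), length(h))
  w[cbind(seq_along(h), h + 1L)]
}

#' Forward-backward over the copying chain
#'
#' Computes the log marginal likelihood of an observed haplotype under the
#' copying chain, optionally weighted by per-site external evidence, together
#' with the posterior distribution over the copied reference haplotype at each
#' site. The recursion is scaled per site, so chains of length up to at least
#' 1e5 sites run without underflow.
#'
#' With evidence `w`, the quantity returned is
#' `log sum_z pi(z_1) prod_s tau(z_s|z_{s-1}) eps(h_s|z_s) w_s(h_s)`.
#'
#' @param h length-V vector of 0/1 alleles.
#' @param panel a [HaplotypePanel-class].
#' @param params an [HMMParams-class] (see [buildHMMParams()]).
#' @param evidence optional [SiteEvidence-class].
#' @return list with `logMarginal` (scalar) and `statePosteriors` (V x K
#'   matrix whose rows sum to 1).
#' @examples
#' p <- HaplotypePanel(matrix(c(0L, 1L, 1L, 0L), 2, 2))
#' forwardBackward(c(0, 1), p, buildHMMParams(p))$logMarginal
#' @export
forwardBackward <- function(h, panel, params, evidence = NULL) {
  stopifnot(is(panel, "HaplotypePanel"), is(params, "HMMParams"))
  h <- .asAlleleVector(h, nVariants(panel))
  w <- .evidenceAtObserved(evidence, h)
  res <- .fb_hap(panel@alleles, h, w, params@switchProb,
                 params@emissionError, params@prior)
  list(logMarginal = res$logMarginal, statePosteriors = res$statePosteriors)
}

#' Copying-chain log likelihood of a haplotype or diploid profile
#'
#' `hmmLogLik` is [forwardBackward()] without evidence. For a
#' [GenotypeProfile-class] the diploid log likelihood is the sum of the two
#' haplotype log likelihoods, reflecting the factorization of the joint model
#' over the two parental chains.
#'
#' @inheritParams forwardBackward
#' @param h a 0/1 allele vector or a [GenotypeProfile-class].
#' @return scalar log likelihood.
#' @export
hmmLogLik <- function(h, panel, params) {
  if (is(h, "GenotypeProfile"))
    return(hmmLogLik(h@maternal, panel, params) + hmmLogLik(h@paternal, panel, params))
  h <- .asAlleleVector(h, nVariants(panel))
  as.numeric(.fb_hap_batch(panel@alleles, matrix(h, ncol = 1), NULL,
                           params@switchProb, params@emissionError, params@prior))
}

# Batched fixed-haplotype log likelihoods; H is V x M (columns = haplotypes),
# W an optional V x M matrix of evidence at the observed alleles.
.hmmLogLikBatch <- function(H, panel, params, W = NULL) {
  storage.mode(H) <- "integer"
  as.numeric(.fb_hap_batch(panel@alleles, H, W, params@switchProb,
                           params@emissionError, params@prior))
}

#' Brute-force marginal by path enumeration
#'
#' Reference oracle for [forwardBackward()]: sums the joint probability over
#' all `K^V` hidden state paths explicitly. Refuses instances with more than
#' 1e6 paths.
#'
#' @inheritParams forwardBackward
#' @return scalar log marginal.
#' @export
bruteForceMarginal <- function(h, panel, params, evidence = NULL) {
  stopifnot(is(panel, "HaplotypePanel"), is(params, "HMMParams"))
  V <- nVariants(panel)
  K <- nHaplotypes(panel)
  if (K^V > 1e6) .stopf("instance too large for path enumeration (K^V = %g)", K^V)
  h <- .asAlleleVector(h, V)
  w <- .evidenceAtObserved(evidence, h)
  if (!length(w)) w <- rep(1, V)
  eps <- params@emissionError
  # per-site, per-state log emission (including evidence)
  logEmit <- sapply(seq_len(V), function(s) {
    log(ifelse(panel@alleles[, s] == h[s], 1 - eps, eps) * w[s])
  })
  logEmit <- matrix(logEmit, nrow = K)  # K x V
  rho <- params@switchProb
  logTrans <- lapply(seq_len(max(V - 1, 0)), function(s) {
    m <- matrix(rho[s] / K, K, K)
    diag(m) <- diag(m) + (1 - rho[s])
    log(m)
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), V)))
  lp <- log(params@prior)[paths[, 1]] + logEmit[cbind(paths[, 1], 1L)]
  if (V > 1) {
    for (s in 2:V) {
      lp <- lp + logTrans[[s - 1]][cbind(paths[, s - 1], paths[, s])] +
        logEmit[cbind(paths[, s], s)]
    }
  }
  .logSumExp(lp)
}

# ---- cohort matrix helpers --------------------------------------------------

#' Assemble cohort matrices from profile lists
#'
#' `haplotypeMatrix` stacks the phased haplotypes of a list of
#' [GenotypeProfile-class] into a V x 2n matrix (maternal then paternal per
#' individual); `dosageMatrix` returns the V x n matrix of allele dosages;
#' `expressionMatrix` aligns a list of [ExpressionProfile-class] into a G x n
#' matrix keyed by the first profile's gene order.
#'
#' @param profiles list of profiles.
#' @return a matrix with sample identifiers as column names.
#' @export
haplotypeMatrix <- function(profiles) {
  if (is(profiles, "GenotypeProfile")) profiles <- list(profiles)
  H <- vapply(profiles, function(g) c(g@maternal, g@paternal),
              integer(2L * length(profiles[[1]]@maternal)))
  V <- length(profiles[[1]]@maternal)
  out <- matrix(0L, V, 2L * length(profiles))
  out[, seq_along(profiles) * 2L - 1L] <- H[seq_len(V), , drop = FALSE]
  out[, seq_along(profiles) * 2L] <- H[V + seq_len(V), , drop = FALSE]
  colnames(out) <- as.vector(rbind(paste0(vapply(profiles, sampleId, ""), ".m"),
                                   paste0(vapply(profiles, sampleId, ""), ".p")))
  out
}

#' @rdname haplotypeMatrix
#' @export
dosageMatrix <- function(profiles) {
  if (is(profiles, "GenotypeProfile")) profiles <- list(profiles)
  D <- vapply(profiles, function(g) g@maternal + g@paternal,
              integer(length(profiles[[1]]@maternal)))
  D <- matrix(D, nrow = length(profiles[[1]]@maternal))
  colnames(D) <- vapply(profiles, sampleId, "")
  D
}

#' @rdname haplotypeMatrix
#' @export
expressionMatrix <- function(profiles) {
  if (is(profiles, "ExpressionProfile")) profiles <- list(profiles)
  genes <- profiles[[1]]@geneIds
  E <- vapply(profiles, function(e) {
    if (identical(e@geneIds, genes)) return(e@values)
    idx <- match(genes, e@geneIds)
    if (anyNA(idx)) .stopf("expression profile '%s' is missing mapped genes", e@sampleId)
    e@values[idx]
  }, numeric(length(genes)))
  E <- matrix(E, nrow = length(genes))
  dimnames(E) <- list(genes, vapply(profiles, sampleId, ""))
  E
}
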