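# Published baseline linkers: Gaussian naive Bayes (GNB) and extremity-based
# linking (EBL, with the hybrid GNB fallback), plus greedy correlation pruning
# of eQTLs. Both baselines treat eQTLs independently and use a single eGene
# per eQTL, which is why they require the pruned map.

#' Greedy correlation-based eQTL pruning
#'
#' Orders eQTLs by significance (most significant first), then greedily
#' retains each eQTL whose training-dosage Pearson correlation with every
#' already-retained eQTL is at most `corrThreshold` in absolute value.
#' Constant-dosage sites have undefined correlation and are excluded with a
#' warning.
#'
#' @param genotypes list of training [GenotypeProfile-class], or a dosage
#'   matrix with one row per panel site.
#' @param eqtlMap an [EQTLMap-class]; its `significance` slot (larger = more
#'   significant) orders the greedy pass, with the map order breaking ties and
#'   standing in where significance is missing.
#' @param corrThreshold retain only pairs with `|r| <=` this (default 0.1, the
#'   published operating point).
#' @return the pruned [EQTLMap-class], in site order.
#' @export
pruneEQTLs <- function(genotypes, eqtlMap, corrThreshold = 0.1) {
  stopifnot(is(eqtlMap, "EQTLMap"))
  D <- if (is.matrix(genotypes)) genotypes else dosageMatrix(genotypes)
  if (max(eqtlMap@siteIndex) > nrow(D)) .stopf("dosage matrix does not cover the map")
  D <- D[eqtlMap@siteIndex, , drop = FALSE]
  m <- length(eqtlMap@siteIndex)
  sig <- eqtlMap@significance
  sig[is.na(sig)] <- -Inf
  ord <- order(-sig, seq_len(m))
  sds <- apply(D, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    .warnf("excluding %d constant-dosage site(s) with undefined correlation",
           sum(degenerate))
  kept <- integer(0)
  for (s in ord) {
    if (degenerate[s]) next
    ok <- TRUE
    for (k in kept) {
      if (abs(stats::cor(D[s, ], D[k, ])) > corrThreshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  if (!length(kept)) .stopf("pruning removed every eQTL")
  kept <- sort(kept)
  EQTLMap(siteIndex = eqtlMap@siteIndex[kept],
          geneSets = eqtlMap@geneSets[kept],
          variantIds = eqtlMap@variantIds[kept],
          direction = eqtlMap@direction[kept],
          significance = eqtlMap@significance[kept])
}

#' Fit the Gaussian naive Bayes linker
#'
#' For each retained eQTL (with its first eGene), fits per-dosage-class
#' Gaussian means of the eGene's training expression with a shared (pooled
#' within-class) standard deviation, and a smoothed genotype-class prior from
#' the training dosage frequencies. Classes with fewer than two training
#' samples fall back to a linear dosage-on-expression fit for their mean.
#'
#' @param genotypes,expressions matched training lists.
#' @param eqtlMap a pruned [EQTLMap-class] (see [pruneEQTLs()]).
#' @param pseudocount additive smoothing of the genotype-class prior.
#' @param sigmaFloor lower bound applied to the shared standard deviation
#'   (with a warning), guarding zero-variance genes.
#' @return a [GNBParams-class].
#' @export
gnbFit <- function(genotypes, expressions, eqtlMap, pseudocount = 1,
                   sigmaFloor = 1e-6) {
  E <- .asExpressionMatrix(expressions)
  D <- dosageMatrix(genotypes)[eqtlMap@siteIndex, , drop = FALSE]
  m <- length(eqtlMap@siteIndex)
  gene <- vapply(eqtlMap@geneSets, `[[`, "", 1L)
  if (!all(gene %in% rownames(E)))
    .stopf("unresolvable eGene(s): %s",
           paste(utils::head(setdiff(gene, rownames(E)), 3), collapse = ", "))
  n <- ncol(D)
  mu <- matrix(NA_real_, m, 3)
  sigma <- numeric(m)
  logPrior <- matrix(NA_real_, m, 3)
  flooredAny <- FALSE
  for (s in seq_len(m)) {
    ev <- E[gene[s], ]
    d <- D[s, ]
    counts <- tabulate(d + 1L, 3L)
    logPrior[s, ] <- log((counts + pseudocount) / (n + 3 * pseudocount))
    # linear fallback for thin classes
    lin <- if (stats::sd(d) > 0) stats::coef(stats::lm(ev ~ d)) else c(mean(ev), 0)
    ssq <- 0
    for (cls in 0:2) {
      idx <- d == cls
      if (counts[cls + 1L] >= 2L) {
        mu[s, cls + 1L] <- mean(ev[idx])
        ssq <- ssq + sum((ev[idx] - mu[s, cls + 1L])^2)
      } else {
        mu[s, cls + 1L] <- lin[1] + lin[2] * cls
      }
    }
    dof <- n - sum(counts >= 2L)
    sigma[s] <- if (dof > 0 && ssq > 0) sqrt(ssq / dof) else stats::sd(ev)
    if (!is.finite(sigma[s]) || sigma[s] < sigmaFloor) {
      sigma[s] <- sigmaFloor
      flooredAny <- TRUE
    }
  }
  if (flooredAny) .warnf("zero-variance eGene(s): sigma floored at %g", sigmaFloor)
  new("GNBParams", map = eqtlMap, gene = gene, mu = mu, sigma = sigma,
      logPrior = logPrior)
}

# Per-class site x query log terms: list of three V x nq matrices.
.gnbClassTerms <- function(params, E) {
  idx <- match(params@gene, rownames(E))
  if (anyNA(idx)) .stopf("query expression is missing eGene(s)")
  Eg <- E[idx, , drop = FALSE]                      # m x nq
  lapply(0:2, function(cls) {
    stats::dnorm(Eg, mean = params@mu[, cls + 1L], sd = params@sigma, log = TRUE) +
      params@logPrior[, cls + 1L]
  })
}

.gnbScoreMatrix <- function(params, E, Dc) {
  terms <- .gnbClassTerms(params, E)
  sc <- 0
  for (cls in 0:2) sc <- sc + crossprod(terms[[cls + 1L]], Dc == cls)
  sc  # nq x nc
}

#' Gaussian naive Bayes log match score
#'
#' `sum_s [ log N(e_Q(s); mu_{s, x_s}, sigma_s) + log p(x_s) ]` over the
#' retained eQTLs, with the genotype treated as the dosage class in
#' \{0, 1, 2\} (phase carries no expression signal in this model).
#'
#' @param x a [GenotypeProfile-class].
#' @param e an [ExpressionProfile-class].
#' @param params a [GNBParams-class].
#' @return scalar log score.
#' @export
gnbLogScore <- function(x, e, params) {
  stopifnot(is(x, "GenotypeProfile"), is(params, "GNBParams"))
  E <- .asExpressionMatrix(e)
  Dc <- matrix(dosage(x)[params@map@siteIndex], ncol = 1)
  as.numeric(.gnbScoreMatrix(params, E, Dc))
}

#' @describeIn gnbLogScore generic pairwise score method for GNB parameters.
#' @export
setMethod("logScore", signature(params = "GNBParams"),
          function(x, e, params, ...) gnbLogScore(x, e, params))

#' Fit the extremity-based linker (hybrid form)
#'
#' For each retained eQTL, records the training eQTL-eGene Pearson correlation
#' (direction of association) and the two-sided extremity thresholds of the
#' eGene's training expression at quantiles `1 - extremityQ` and `extremityQ`.
#' At linking time, a query whose eGene expression is beyond a threshold (and
#' whose eQTL passes the correlation filter `|r| >= corrMin`) predicts the
#' corresponding homozygote; candidates carrying it contribute 0, others a
#' penalty of `-lambda` nats. Genes with non-extreme expression fall back to
#' their Gaussian naive Bayes term, so with no extreme gene the score
#' collapses to [gnbLogScore()] exactly.
#'
#' @inheritParams gnbFit
#' @param extremityQ extremity quantile in (0.5, 1).
#' @param corrMin minimum `|r|` for an eQTL to make extremity calls.
#' @param lambda disagreement penalty in nats; `lambda = Inf` recovers hard
#'   filtering.
#' @return an [EBLParams-class].
#' @export
eblFit <- function(genotypes, expressions, eqtlMap, extremityQ = 0.9,
                   corrMin = 0.3, lambda = 5) {
  gnb <- gnbFit(genotypes, expressions, eqtlMap)
  E <- .asExpressionMatrix(expressions)
  D <- dosageMatrix(genotypes)[eqtlMap@siteIndex, , drop = FALSE]
  m <- length(eqtlMap@siteIndex)
  corr <- numeric(m)
  lo <- hi <- numeric(m)
  for (s in seq_len(m)) {
    ev <- E[gnb@gene[s], ]
    r <- suppressWarnings(stats::cor(D[s, ], ev))
    corr[s] <- if (is.finite(r)) r else 0
    lo[s] <- stats::quantile(ev, 1 - extremityQ, names = FALSE)
    hi[s] <- stats::quantile(ev, extremityQ, names = FALSE)
  }
  new("EBLParams", gnb = gnb, extremityQ = extremityQ, corrMin = corrMin,
      lambda = lambda, corr = corr, lo = lo, hi = hi)
}

.eblScoreMatrix <- function(params, E, Dc) {
  gnb <- params@gnb
  idx <- match(gnb@gene, rownames(E))
  if (anyNA(idx)) .stopf("query expression is missing eGene(s)")
  Eg <- E[idx, , drop = FALSE]                      # m x nq
  active <- abs(params@corr) >= params@corrMin
  extHi <- active & (Eg > params@hi)                # m x nq
  extLo <- active & (Eg < params@lo)
  pos <- params@corr > 0
  pred2 <- (extHi & pos) | (extLo & !pos)
  pred0 <- (extHi & !pos) | (extLo & pos)
  terms <- .gnbClassTerms(gnb, E)
  nq <- ncol(Eg); nc <- ncol(Dc)
  sc <- matrix(0, nq, nc)
  extreme <- pred2 | pred0
  for (cls in 0:2) {
    Tm <- terms[[cls + 1L]]
    Tm[extreme] <- 0                                # extreme sites leave GNB
    sc <- sc + crossprod(Tm, Dc == cls)
  }
  # penalty for candidates disagreeing with the predicted homozygote
  for (q in seq_len(nq)) {
    s2 <- which(pred2[, q])
    s0 <- which(pred0[, q])
    if (length(s2))
      sc[q, ] <- sc[q, ] - params@lambda * colSums(Dc[s2, , drop = FALSE] != 2L)
    if (length(s0))
      sc[q, ] <- sc[q, ] - params@lambda * colSums(Dc[s0, , drop = FALSE] != 0L)
  }
  sc
}

#' Extremity-based log match score
#'
#' @inheritParams gnbLogScore
#' @param params an [EBLParams-class].
#' @return scalar log score.
#' @export
eblLogScore <- function(x, e, params) {
  stopifnot(is(x, "GenotypeProfile"), is(params, "EBLParams"))
  E <- .asExpressionMatrix(e)
  Dc <- matrix(dosage(x)[params@gnb@map@siteIndex], ncol = 1)
  as.numeric(.eblScoreMatrix(params, E, Dc))
}

#' @describeIn eblLogScore generic pairwise score method for EBL parameters.
#' @export
setMethod("logScore", signature(params = "EBLParams"),
          function(x, e, params, ...) eblLogScore(x, e, params))

#' Grid search for the extremity-based linker
#'
#' Fits [eblFit()] across a grid of extremity quantiles and correlation
#' thresholds and keeps the setting with the highest linking accuracy
#' (fraction of training expression profiles whose top-scoring candidate is
#' their own genotype).
#'
#' @inheritParams eblFit
#' @param extremityGrid,corrGrid candidate thresholds.
#' @return the best [EBLParams-class]; the searched grid and accuracies are in
#'   `attr(, "grid")`.
#' @export
tuneEBL <- function(genotypes, expressions, eqtlMap,
                    extremityGrid = c(0.8, 0.9, 0.95, 0.99),
                    corrGrid = c(0.1, 0.3, 0.5), lambda = 5) {
  grid <- expand.grid(extremityQ = extremityGrid, corrMin = corrGrid)
  grid$accuracy <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- eblFit(genotypes, expressions, eqtlMap,
                  extremityQ = grid$extremityQ[i], corrMin = grid$corrMin[i],
                  lambda = lambda)
    sc <- scoreAll(expressions, genotypes, fit)
    acc <- mean(apply(sc@.Data, 1, which.max) == seq_along(genotypes))
    grid$accuracy[i] <- acc
    if (is.null(best) || acc > attr(best, "accuracy")) {
      attr(fit, "accuracy") <- acc
      best <- fit
    }
  }
  attr(best, "grid") <- grid
  best
}
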