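# Linking attacks: pairwise score matrices, forward/reverse argmax linking,
# Gaussian null models with model-based P-values, and thresholded linking
# under unknown membership (ROC / precision-recall).

.profileIds <- function(profiles) {
  ids <- vapply(profiles, sampleId, "")
  if (anyDuplicated(ids)) .stopf("sample identifiers must be unique")
  ids
}

.asProfileList <- function(x, cls) {
  if (is(x, cls)) list(x) else x
}

.checkTrained <- function(params) {
  if (is(params, "DSMParams") && length(params@history) == 0L &&
      all(params@qtl@alpha == 0) &&
      all(vapply(params@qtl@beta, function(b) all(b == 0), TRUE)))
    .warnf("DSM factors are all zero (untrained?): every candidate ties")
  invisible(TRUE)
}

.newScoreMatrix <- function(sc, qIds, cIds, scorer) {
  dimnames(sc) <- list(qIds, cIds)
  new("ScoreMatrix", sc, scorer = scorer)
}

#' @describeIn scoreAll score with a trained DSM: log match scores
#'   `log M(x, e)` from [dsmLogScore()], computed in one matrix pass.
#' @export
setMethod("scoreAll", signature(params = "DSMParams"),
  function(queries, candidates, params, ...) {
    queries <- .asProfileList(queries, "ExpressionProfile")
    candidates <- .asProfileList(candidates, "GenotypeProfile")
    stopifnot(length(queries) > 0, length(candidates) > 0)
    .checkTrained(params)
    E <- expressionMatrix(queries)
    L <- .dsmLogits(params, E)
    p1 <- .clipProb(.sigmoid(L))
    Dc <- dosageMatrix(candidates)[params@map@siteIndex, , drop = FALSE]
    sc <- crossprod(log(p1), Dc) + crossprod(log(1 - p1), 2 - Dc)
    .newScoreMatrix(sc, .profileIds(queries), .profileIds(candidates), "dsm")
  })

#' @describeIn scoreAll score with a list of window-wise DSM models (the sum
#'   of per-window scores).
#' @export
setMethod("scoreAll", signature(params = "list"),
  function(queries, candidates, params, ...) {
    stopifnot(all(vapply(params, is, TRUE, "DSMParams")))
    queries <- .asProfileList(queries, "ExpressionProfile")
    candidates <- .asProfileList(candidates, "GenotypeProfile")
    Dfull <- dosageMatrix(candidates)
    E <- expressionMatrix(queries)
    sc <- 0
    for (m in params) {
      rng <- attr(m, "siteRange")
      if (is.null(rng)) .stopf("window models must carry a siteRange attribute")
      Lw <- .dsmLogits(m, E)
      p1 <- .clipProb(.sigmoid(Lw))
      Dc <- Dfull[m@map@siteIndex + rng[1] - 1L, , drop = FALSE]
      sc <- sc + crossprod(log(p1), Dc) + crossprod(log(1 - p1), 2 - Dc)
    }
    .newScoreMatrix(sc, .profileIds(queries), .profileIds(candidates), "dsm")
  })

#' @describeIn scoreAll score with the Gaussian naive Bayes baseline.
#' @export
setMethod("scoreAll", signature(params = "GNBParams"),
  function(queries, candidates, params, ...) {
    queries <- .asProfileList(queries, "ExpressionProfile")
    candidates <- .asProfileList(candidates, "GenotypeProfile")
    E <- expressionMatrix(queries)
    Dc <- dosageMatrix(candidates)[params@map@siteIndex, , drop = FALSE]
    sc <- .gnbScoreMatrix(params, E, Dc)
    .newScoreMatrix(sc, .profileIds(queries), .profileIds(candidates), "gnb")
  })

#' @describeIn scoreAll score with the extremity-based baseline.
#' @export
setMethod("scoreAll", signature(params = "EBLParams"),
  function(queries, candidates, params, ...) {
    queries <- .asProfileList(queries, "ExpressionProfile")
    candidates <- .asProfileList(candidates, "GenotypeProfile")
    E <- expressionMatrix(queries)
    Dc <- dosageMatrix(candidates)[params@gnb@map@siteIndex, , drop = FALSE]
    sc <- .eblScoreMatrix(params, E, Dc)
    .newScoreMatrix(sc, .profileIds(queries), .profileIds(candidates), "ebl")
  })

#' Forward linking by per-query argmax
#'
#' Independently assigns to each query expression profile the best-matching
#' candidate genotype (row argmax; not a bipartite matching). Ties are broken
#' deterministically towards the lexicographically smallest candidate
#' identifier and flagged, since ties indicate zero signal.
#'
#' @param scores a [ScoreMatrix-class].
#' @param null optional [NullModel-class]; adds model-based P-values.
#' @param threshold optional log-score call threshold; queries whose best
#'   score falls below it are left uncalled.
#' @return a `data.frame` with columns `query_id`, `best_candidate`,
#'   `log_score`, `pvalue`, `called`, `tie`.
#' @export
linkForward <- function(scores, null = NULL, threshold = -Inf) {
  stopifnot(is(scores, "ScoreMatrix"))
  sc <- scores@.Data
  cand <- colnames(sc)
  ord <- order(cand)
  best <- apply(sc[, ord, drop = FALSE], 1, function(r) {
    m <- max(r)
    hits <- which(r == m)
    c(idx = ord[hits[1]], score = m, tie = as.numeric(length(hits) > 1))
  })
  res <- data.frame(query_id = rownames(sc),
                    best_candidate = cand[best["idx", ]],
                    log_score = unname(best["score", ]),
                    pvalue = NA_real_,
                    called = unname(best["score", ] >= threshold),
                    tie = unname(best["tie", ] > 0),
                    stringsAsFactors = FALSE)
  if (!is.null(null)) res$pvalue <- matchPValue(res$log_score, null, res$query_id)
  if (any(res$tie)) .warnf("%d quer(ies) had tied best scores", sum(res$tie))
  res
}

#' Reverse linking of one genotype against candidate expression profiles
#'
#' Scores the same pairwise log match score as forward linking, but takes the
#' argmax over expression candidates for a fixed genotype profile: reading the
#' transposed score matrix.
#'
#' @param query a [GenotypeProfile-class].
#' @param candidates list of [ExpressionProfile-class].
#' @param params trained scorer parameters (any class accepted by
#'   [scoreAll()]).
#' @return one-row `data.frame` as in [linkForward()], with `query_id` the
#'   genotype sample and `best_candidate` the selected expression profile.
#' @export
linkReverse <- function(query, candidates, params) {
  stopifnot(is(query, "GenotypeProfile"))
  candidates <- .asProfileList(candidates, "ExpressionProfile")
  sc <- scoreAll(candidates, list(query), params)
  tr <- .newScoreMatrix(t(sc@.Data), colnames(sc@.Data), rownames(sc@.Data),
                        sc@scorer)
  linkForward(tr)
}

#' Fit per-query Gaussian nulls to mismatching scores
#'
#' Models, separately for each query, the distribution of log match scores of
#' mismatching candidates as a Gaussian, excluding the query's true candidate
#' when a pairing is supplied. These nulls convert match scores into
#' upper-tail P-values measuring the strength of the identifying signal.
#'
#' @param scores a [ScoreMatrix-class].
#' @param trueMap optional named character vector mapping query identifiers to
#'   their true candidate identifier (entries may be NA).
#' @param minMismatch refuse to fit with fewer mismatching candidates.
#' @return a [NullModel-class].
#' @export
fitNull <- function(scores, trueMap = NULL, minMismatch = 30) {
  stopifnot(is(scores, "ScoreMatrix"))
  sc <- scores@.Data
  qIds <- rownames(sc)
  mu <- sd <- numeric(nrow(sc))
  nn <- integer(nrow(sc))
  for (j in seq_len(nrow(sc))) {
    row <- sc[j, ]
    if (!is.null(trueMap) && !is.na(trueMap[qIds[j]])) {
      keep <- colnames(sc) != trueMap[qIds[j]]
      row <- row[keep]
    }
    if (length(row) < minMismatch)
      .stopf("query '%s' has only %d mismatching candidates (need >= %d)",
             qIds[j], length(row), minMismatch)
    mu[j] <- mean(row)
    sd[j] <- stats::sd(row)
    nn[j] <- length(row)
    if (sd[j] == 0)
      .stopf("query '%s': mismatching scores are constant; null sd undefined", qIds[j])
  }
  new("NullModel", queryIds = qIds, mean = mu, sd = sd, n = nn)
}

#' Model-based match P-value
#'
#' Upper-tail Gaussian P-value of a match score under a query's null model:
#' small values mean the score separates strongly from mismatching pairs.
#'
#' @param score numeric score(s).
#' @param null a [NullModel-class].
#' @param query query identifier(s) aligning `score` with the null (defaults
#'   to the null's query order).
#' @return P-values in (0, 1].
#' @export
matchPValue <- function(score, null, query = NULL) {
  stopifnot(is(null, "NullModel"))
  if (is.null(query)) {
    if (length(score) != length(null@queryIds))
      .stopf("provide query ids or one score per null query")
    idx <- seq_along(score)
  } else {
    idx <- match(query, null@queryIds)
    if (anyNA(idx)) .stopf("unknown query identifier(s)")
  }
  p <- stats::pnorm(score, mean = null@mean[idx], sd = null@sd[idx],
                    lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Linking accuracy of a score matrix
#'
#' Fraction (or count) of queries whose row argmax is their true candidate.
#'
#' @param scores a [ScoreMatrix-class].
#' @param trueMap named character vector query id -> true candidate id.
#' @param count return the number of correctly linked queries rather than the
#'   fraction.
#' @return accuracy in `[0, 1]` (or a count).
#' @export
linkAccuracy <- function(scores, trueMap, count = FALSE) {
  links <- suppressWarnings(linkForward(scores))
  truth <- trueMap[links$query_id]
  hit <- !is.na(truth) & links$best_candidate == truth & !links$tie
  if (count) sum(hit) else mean(hit[!is.na(truth)])
}

#' Thresholded linking under unknown membership
#'
#' When the attacker does not know whether the query's individual is in the
#' candidate set, links are called only when the best match score clears a
#' threshold. Sweeping the threshold yields, in the linking adaptation of the
#' standard binary metrics: TPR = fraction of queries with a present match
#' that are called and correctly linked; FPR = fraction of queries without any
#' matching candidate that are (necessarily incorrectly) called; precision =
#' correctly linked calls over all calls; recall = TPR. AUROC and AUPRC are
#' trapezoid areas over the sweep.
#'
#' @param scores a [ScoreMatrix-class].
#' @param truth named character vector query id -> true candidate id, with NA
#'   for queries whose individual is absent from the candidate set. At least
#'   one absent query is required, otherwise the FPR is undefined.
#' @param thresholds optional threshold grid; defaults to the observed best
#'   scores padded with +/-Inf.
#' @return list with `curve` (a `data.frame` over thresholds), `auroc` and
#'   `auprc`.
#' @export
thresholdedLinking <- function(scores, truth, thresholds = NULL) {
  stopifnot(is(scores, "ScoreMatrix"))
  sc <- scores@.Data
  truth <- truth[rownames(sc)]
  present <- !is.na(truth)
  if (!any(!present))
    .stopf("FPR undefined: no query lacks a matching candidate")
  links <- suppressWarnings(linkForward(scores))
  best <- links$log_score
  correct <- present & links$best_candidate == ifelse(present, truth, "") & !links$tie
  if (is.null(thresholds)) thresholds <- c(Inf, sort(unique(best), decreasing = TRUE), -Inf)
  tpr <- fpr <- prec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    called <- best >= thresholds[i]
    tpr[i] <- if (any(present)) sum(called & correct) / sum(present) else NA_real_
    fpr[i] <- sum(called & !present) / sum(!present)
    prec[i] <- if (any(called)) sum(called & correct) / sum(called) else 1
  }
  curve <- data.frame(threshold = thresholds, tpr = tpr, fpr = fpr,
                      precision = prec, recall = tpr)
  ordR <- order(fpr, tpr)
  auroc <- sum(diff(fpr[ordR]) * (tpr[ordR][-1] + tpr[ordR][-length(tpr)]) / 2)
  ordP <- order(tpr, -prec)
  auprc <- sum(diff(tpr[ordP]) * (prec[ordP][-1] + prec[ordP][-length(prec)]) / 2)
  list(curve = curve, auroc = auroc, auprc = auprc)
}

#' Repeated half-holdout membership experiment
#'
#' Repeats [thresholdedLinking()] over seeded random holdouts: in each trial
#' the true candidates of a random fraction of the queries are removed from
#' the candidate set before linking, so those queries have no present match.
#' Curves and areas are computed per trial and averaged.
#'
#' @param scores a [ScoreMatrix-class] over the full candidate set.
#' @param trueMap named character vector query id -> true candidate id.
#' @param nTrials number of holdout trials (default 100).
#' @param fraction fraction of queries whose true candidate is held out.
#' @param seed integer seed controlling the holdout draws.
#' @return list with `auroc`/`auprc` (per-trial vectors), `meanAuroc`,
#'   `meanAuprc`, and `trials` (list of per-trial curve data frames).
#' @export
holdoutLinking <- function(scores, trueMap, nTrials = 100, fraction = 0.5,
                           seed = 1) {
  stopifnot(is(scores, "ScoreMatrix"))
  sc <- scores@.Data
  qIds <- rownames(sc)
  trueMap <- trueMap[qIds]
  withMatch <- which(!is.na(trueMap) & trueMap %in% colnames(sc))
  if (length(withMatch) < 2L) .stopf("need at least two queries with a true candidate")
  set.seed(seed)
  auroc <- auprc <- numeric(nTrials)
  trials <- vector("list", nTrials)
  nHold <- max(1L, round(fraction * length(withMatch)))
  for (t in seq_len(nTrials)) {
    hold <- sample(withMatch, nHold)
    drop <- unique(trueMap[hold])
    keep <- !(colnames(sc) %in% drop)
    sub <- .newScoreMatrix(sc[, keep, drop = FALSE], qIds,
                           colnames(sc)[keep], scores@scorer)
    truth <- trueMap
    truth[hold] <- NA
    truth[!is.na(truth) & !(truth %in% colnames(sc)[keep])] <- NA
    res <- thresholdedLinking(sub, truth)
    auroc[t] <- res$auroc
    auprc[t] <- res$auprc
    trials[[t]] <- res$curve
  }
  list(auroc = auroc, auprc = auprc, meanAuroc = mean(auroc),
       meanAuprc = mean(auprc), trials = trials)
}
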