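## Nearest-profile and weighted-profile baselines.  Both operate per side
## (drug rows or target columns): the query entity's score row is built
## from the interaction profiles of *training* entities on the same side,
## weighted by similarity.  Drug-side and target-side predictions are then
## averaged for the final full-matrix estimate.

## Training entities given a fold mask: an entity is available for
## similarity-based borrowing iff at least one of its pairs is unmasked.
.trainIdx <- function(Wv, side) {
    s <- if (side == "drug") rowSums(Wv) else colSums(Wv)
    which(s > 0)
}

#' Nearest-profile prediction for one entity
#'
#' Scores the query's interactions as
#' \eqn{\hat Y(d_i) = S(d_i, d_{nearest}) \, Y(d_{nearest})}: the profile
#' of the single most similar training entity, scaled by its similarity to
#' the query.  Ties are broken by the lowest index; the query itself never
#' counts as its own neighbour.
#'
#' @param Y an [InteractionMatrix-class] (training labels; held-out entries
#'   already zeroed).
#' @param S the [SimilarityMatrix-class] for the chosen side.
#' @param queryIndex index of the query entity on that side.
#' @param side "drug" (score a row) or "target" (score a column).
#' @param trainIdx indices of entities usable as neighbours; defaults to
#'   all entities except the query.
#' @return numeric score vector (length m for drugs, n for targets).
#' @export
nearestProfile <- function(Y, S, queryIndex, side = c("drug", "target"),
                           trainIdx = NULL) {
    side <- .asSide(side)
    prof <- .sideRows(values(Y), side)
    Sv <- values(S)
    queryIndex <- .asCount(queryIndex, "queryIndex")
    trainIdx <- .profileTrainIdx(trainIdx, queryIndex, nrow(prof))
    sims <- Sv[queryIndex, trainIdx]
    nearest <- trainIdx[which.max(sims)]   # which.max: lowest index on ties
    unname(Sv[queryIndex, nearest] * prof[nearest, ])
}

#' Weighted-profile prediction for one entity
#'
#' The similarity-weighted mean of all training profiles,
#' \eqn{\hat Y(d_i) = \sum_j S(d_i,d_j) Y(d_j) / \sum_j S(d_i,d_j)}, with
#' the sum over training entities excluding the query itself (self-exclusion
#' avoids label leakage under pair cross-validation).
#'
#' @inheritParams nearestProfile
#' @return numeric score vector.
#' @export
weightedProfile <- function(Y, S, queryIndex, side = c("drug", "target"),
                            trainIdx = NULL) {
    side <- .asSide(side)
    prof <- .sideRows(values(Y), side)
    Sv <- values(S)
    queryIndex <- .asCount(queryIndex, "queryIndex")
    trainIdx <- .profileTrainIdx(trainIdx, queryIndex, nrow(prof))
    sims <- Sv[queryIndex, trainIdx]
    denom <- sum(sims)
    if (denom <= 0)
        stop("all similarities to training entities are zero: ",
             "weighted profile undefined", call. = FALSE)
    as.numeric(crossprod(prof[trainIdx, , drop = FALSE], sims)) / denom
}

.profileTrainIdx <- function(trainIdx, queryIndex, nEntities) {
    if (is.null(trainIdx)) trainIdx <- seq_len(nEntities)
    trainIdx <- setdiff(as.integer(trainIdx), queryIndex)
    if (!length(trainIdx))
        stop("no training entity available for this query (cold start)",
             call. = FALSE)
    trainIdx
}

#' Average drug-side and target-side predictions
#'
#' @param drugSide,targetSide [ScoreMatrix-class] objects with identical
#'   shape and labels.
#' @return their elementwise arithmetic mean as a [ScoreMatrix-class].
#' @export
combineSides <- function(drugSide, targetSide) {
    stopifnot(is(drugSide, "ScoreMatrix"), is(targetSide, "ScoreMatrix"))
    a <- values(drugSide); b <- values(targetSide)
    .sameShape(a, b, "side predictions")
    ScoreMatrix((a + b) / 2)
}

## Full-matrix driver shared by the two baselines: predict every drug row
## from the drug side and every target column from the target side, then
## average.  `fun` is nearestProfile or weightedProfile; queries whose
## prediction is undefined (no training entity, zero similarity mass)
## receive a zero vector -- the honest "no information" score.
.profilePredict <- function(fun, Y, Sd, St, W = NULL) {
    tri <- validateTriple(Y, Sd, St)
    Yv <- values(tri$Y)
    Wv <- .asMask(W, Yv)
    Ytrain <- InteractionMatrix(Yv * Wv)
    n <- nrow(Yv); m <- ncol(Yv)
    drugTrain <- .trainIdx(Wv, "drug")
    targetTrain <- .trainIdx(Wv, "target")
    ds <- matrix(0, n, m, dimnames = dimnames(Yv))
    for (i in seq_len(n)) {
        idx <- setdiff(drugTrain, i)
        if (!length(idx)) next
        ds[i, ] <- tryCatch(
            fun(Ytrain, tri$Sd, i, "drug", trainIdx = idx),
            error = function(e) rep(0, m))
    }
    ts <- matrix(0, n, m, dimnames = dimnames(Yv))
    for (l in seq_len(m)) {
        idx <- setdiff(targetTrain, l)
        if (!length(idx)) next
        ts[, l] <- tryCatch(
            fun(Ytrain, tri$St, l, "target", trainIdx = idx),
            error = function(e) rep(0, n))
    }
    combineSides(ScoreMatrix(ds), ScoreMatrix(ts))
}

#' Full-matrix baseline predictors
#'
#' Apply [nearestProfile()] (`predictNearestProfile`) or
#' [weightedProfile()] (`predictWeightedProfile`) to every drug row and
#' every target column, then average the two side predictions.  Entities
#' fully masked out by `W` are excluded from the training pool; a query
#' with no usable neighbours scores zero.
#'
#' @param Y an [InteractionMatrix-class] (training labels).
#' @param Sd,St drug and target [SimilarityMatrix-class] objects.
#' @param W optional [WeightMask-class] or binary matrix marking training
#'   pairs (1) vs held-out pairs (0).
#' @return a [ScoreMatrix-class].
#' @export
predictNearestProfile <- function(Y, Sd, St, W = NULL)
    .profilePredict(nearestProfile, Y, Sd, St, W)

#' @rdname predictNearestProfile
#' @export
predictWeightedProfile <- function(Y, Sd, St, W = NULL)
    .profilePredict(weightedProfile, Y, Sd, St, W)
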