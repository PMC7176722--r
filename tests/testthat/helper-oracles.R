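## Independent brute-force oracles used to pin down the fast
## implementations, plus small fixture builders.  Oracles deliberately use
## the most literal O(n^2)-style formulations.

## AUC as the literal Mann-Whitney probability: loop over every
## positive-negative pair, wins count 1, ties 1/2.
oracleAuc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (q in neg)
        total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
}

## AUPR by explicit step integration over score thresholds: at each unique
## score (descending) classify everything >= threshold as positive, build
## the confusion counts from scratch, and accumulate precision x recall
## increments.
oracleAupr <- function(labels, scores) {
    thresholds <- sort(unique(scores), decreasing = TRUE)
    P <- sum(labels == 1)
    prevRecall <- 0
    area <- 0
    for (th in thresholds) {
        called <- scores >= th
        tp <- sum(labels == 1 & called)
        precision <- tp / sum(called)
        recall <- tp / P
        area <- area + (recall - prevRecall) * precision
        prevRecall <- recall
    }
    area
}

## Kronecker kernel ridge oracle: explicitly form the nm x nm pairwise
## kernel K = Kt (x) Kd and solve the ridge system on vec(Y).
oracleKronRidge <- function(Yv, Kd, Kt, sigma) {
    K <- kronecker(Kt, Kd)
    yhat <- K %*% solve(K + sigma * diag(nrow(K)), as.numeric(Yv))
    matrix(yhat, nrow(Yv), ncol(Yv), dimnames = dimnames(Yv))
}

## Central finite differences of a scalar function of a matrix.
fdGradient <- function(f, X, h = 1e-6) {
    G <- X * 0
    for (i in seq_along(X)) {
        Xp <- X; Xp[i] <- Xp[i] + h
        Xm <- X; Xm[i] <- Xm[i] - h
        G[i] <- (f(Xp) - f(Xm)) / (2 * h)
    }
    G
}

relErr <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

## Random binary interaction matrix with guaranteed non-empty margins
## avoided on purpose: degenerate rows/columns are part of what the
## methods must tolerate.
randomY <- function(n, m, density = 0.3, seed = 1) {
    set.seed(seed)
    v <- matrix(rbinom(n * m, 1, density), n, m)
    InteractionMatrix(v)
}

## A small aligned triple with informative similarities.
smallTriple <- function(seed = 1, n = 12, m = 9, rank = 3,
                        density = 0.25, noise = 0) {
    generateDTI(simSpec(n, m, rank = rank, density = density,
                        similarityNoise = noise, seed = seed))
}

labelledMatrix <- function(v, drugs = NULL, targets = NULL) {
    if (is.null(drugs)) drugs <- sprintf("d%d", seq_len(nrow(v)))
    if (is.null(targets)) targets <- sprintf("t%d", seq_len(ncol(v)))
    dimnames(v) <- list(drugs, targets)
    v
}
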