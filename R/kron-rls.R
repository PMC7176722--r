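## RLS-WNN: weighted-nearest-neighbour profile inference for cold-start
## entities, Gaussian interaction profile (GIP) kernels as network
## similarity, and Kronecker kernel ridge regression over the pairwise
## kernel K_t (x) K_d, solved in closed form by per-side eigendecomposition
## (the nm x nm Kronecker system is never materialized).

#' Weighted nearest-neighbour profile inference
#'
#' Infers an interaction profile for a cold-start entity as
#' \eqn{\sum_j \omega_j Y(d_j)} where training entities are ranked by
#' descending similarity to the query and \eqn{\omega_j = \eta^{j-1}} with
#' decay \eqn{0 < \eta \le 1}.  No weight normalization is applied: the
#' output is a ranking score profile, not a probability vector.  Ranking
#' ties are broken by the lower entity index.
#'
#' @inheritParams nearestProfile
#' @param eta decay term in (0, 1]; `eta = 1` gives the plain sum of all
#'   training profiles.
#' @return numeric score vector.
#' @export
wnnProfile <- function(Y, S, queryIndex, eta = 0.9,
                       side = c("drug", "target"), trainIdx = NULL) {
    side <- .asSide(side)
    eta <- .asScalar(eta, "eta", lower = 0, upper = 1, strictLower = TRUE)
    prof <- .sideRows(values(Y), side)
    Sv <- values(S)
    queryIndex <- .asCount(queryIndex, "queryIndex")
    trainIdx <- .profileTrainIdx(trainIdx, queryIndex, nrow(prof))
    sims <- Sv[queryIndex, trainIdx]
    ord <- trainIdx[order(-sims, trainIdx)]
    w <- eta^(seq_along(ord) - 1)
    as.numeric(crossprod(prof[ord, , drop = FALSE], w))
}

#' Gaussian interaction profile (GIP) kernel
#'
#' The network similarity between two entities on one side of the
#' bipartite graph: \eqn{K(i,j) = \exp(-\gamma \|y_i - y_j\|^2)} over the
#' entities' interaction profiles, with bandwidth
#' \eqn{\gamma = \gamma' / (\frac1n \sum_i \|y_i\|^2)} normalized by the
#' mean squared profile norm so that the kernel scale is insensitive to
#' the overall interaction density.
#'
#' @param Y an [InteractionMatrix-class] (or [ScoreMatrix-class] holding a
#'   WNN-filled profile matrix).
#' @param side "drug" (kernel over rows) or "target" (over columns).
#' @param gammaPrime positive bandwidth multiplier \eqn{\gamma'}; default 1.
#' @return a [SimilarityMatrix-class] holding the kernel (symmetric, unit
#'   diagonal, entries in (0, 1], positive semidefinite).
#' @export
gipKernel <- function(Y, side = c("drug", "target"), gammaPrime = 1) {
    side <- .asSide(side)
    gammaPrime <- .asScalar(gammaPrime, "gammaPrime", lower = 0,
                            strictLower = TRUE)
    prof <- .sideRows(values(Y), side)
    sq <- rowSums(prof^2)
    msn <- mean(sq)
    if (msn <= 0)
        stop("all interaction profiles are zero: GIP kernel degenerate",
             call. = FALSE)
    gamma <- gammaPrime / msn
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(prof)
    d2[d2 < 0] <- 0                        # numeric round-off
    K <- exp(-gamma * d2)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    dimnames(K) <- list(rownames(prof), rownames(prof))
    new("SimilarityMatrix", values = K)
}

#' Blend a GIP kernel with a given similarity matrix
#'
#' Convex combination `alpha * S + (1 - alpha) * K`, the usual way the
#' chemical/genomic similarity and the interaction-network similarity are
#' merged before kernel ridge regression.
#'
#' @param K a [SimilarityMatrix-class] (typically a [gipKernel()] output).
#' @param S a [SimilarityMatrix-class] over the same entities.
#' @param alpha mixing weight in [0, 1] on `S`; default 0.5.
#' @return a [SimilarityMatrix-class].
#' @export
blendKernels <- function(K, S, alpha = 0.5) {
    stopifnot(is(K, "SimilarityMatrix"), is(S, "SimilarityMatrix"))
    alpha <- .asScalar(alpha, "alpha", lower = 0, upper = 1)
    Kv <- values(K); Sv <- values(S)
    .sameShape(Kv, Sv, "kernel blend")
    new("SimilarityMatrix", values = alpha * Sv + (1 - alpha) * Kv)
}

## Project a symmetric matrix onto the PSD cone by zeroing negative
## eigenvalues.  Measured similarity matrices (noisy, clipped) are not
## kernels in general; this is the standard repair before using them in
## kernel ridge regression.
.psdProject <- function(K) {
    K <- (K + t(K)) / 2
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) >= 0) return(K)
    lam <- pmax(e$values, 0)
    out <- e$vectors %*% (lam * t(e$vectors))
    out <- (out + t(out)) / 2
    dimnames(out) <- dimnames(K)
    out
}

## Eigendecompose a symmetric kernel, enforcing PSD up to tolerance:
## eigenvalues in (-1e-8, 0) are clipped to 0; anything more negative is a
## genuine PSD violation and errors out.
.psdEigen <- function(K, what) {
    K <- (K + t(K)) / 2
    e <- eigen(K, symmetric = TRUE)
    lam <- e$values
    if (min(lam) < -1e-8)
        stop(sprintf("%s kernel is not positive semidefinite (min eigenvalue %g)",
                     what, min(lam)), call. = FALSE)
    lam[lam < 0] <- 0
    list(vectors = e$vectors, values = lam)
}

#' Kronecker kernel ridge regression (RLS-Kron)
#'
#' Solves the kernel ridge problem over the pairwise kernel
#' \eqn{K_t \otimes K_d} with regularizer \eqn{\sigma} in closed form:
#' with eigendecompositions \eqn{K_d = V_d \Lambda_d V_d^\top} and
#' \eqn{K_t = V_t \Lambda_t V_t^\top},
#' \deqn{\hat Y = V_d \left[ \frac{\Lambda_d \Lambda_t^\top}
#'   {\Lambda_d \Lambda_t^\top + \sigma} \circ
#'   (V_d^\top Y V_t) \right] V_t^\top,}
#' the spectral filter \eqn{\lambda/(\lambda+\sigma)} applied per
#' eigenpair.  The nm x nm Kronecker system is never formed.
#'
#' @param Yfilled a [ScoreMatrix-class] or [InteractionMatrix-class]; the
#'   (possibly WNN-filled) training matrix.
#' @param Kd,Kt symmetric positive semidefinite kernels
#'   ([SimilarityMatrix-class] or plain matrices) over drugs and targets.
#' @param sigma positive ridge regularizer; larger values shrink the
#'   prediction (identity kernels give \eqn{\hat Y = Y/(1+\sigma)}).
#' @return a [ScoreMatrix-class].
#' @export
kronRlsPredict <- function(Yfilled, Kd, Kt, sigma = 1) {
    sigma <- .asScalar(sigma, "sigma", lower = 0, strictLower = TRUE)
    Yv <- if (is(Yfilled, "ScoreMatrix") || is(Yfilled, "InteractionMatrix"))
        values(Yfilled) else as.matrix(Yfilled)
    Kdv <- if (is(Kd, "SimilarityMatrix")) values(Kd) else as.matrix(Kd)
    Ktv <- if (is(Kt, "SimilarityMatrix")) values(Kt) else as.matrix(Kt)
    stopifnot(nrow(Kdv) == nrow(Yv), nrow(Ktv) == ncol(Yv))
    ed <- .psdEigen(Kdv, "drug")
    et <- .psdEigen(Ktv, "target")
    lamProd <- outer(ed$values, et$values)
    filt <- lamProd / (lamProd + sigma)
    Z <- crossprod(ed$vectors, Yv) %*% et$vectors
    out <- ed$vectors %*% (filt * Z) %*% t(et$vectors)
    dimnames(out) <- dimnames(Yv)
    ScoreMatrix(out)
}

#' RLS-WNN: the full cold-start-aware Kronecker RLS pipeline
#'
#' The pipeline: (1) infer temporary profiles via [wnnProfile()] for every
#' cold-start drug row and target column (entities whose whole profile is
#' unknown in the current fold -- observed profiles are never altered);
#' (2) build GIP kernels from the filled matrix on both sides; (3) blend
#' each with the corresponding given similarity matrix; (4) run
#' [kronRlsPredict()].  Filling temporary profiles before computing the
#' network similarity is what lets the GIP kernels say something useful
#' about otherwise-empty entities.
#'
#' @inheritParams predictNearestProfile
#' @param eta WNN decay term in (0, 1].
#' @param sigma positive ridge regularizer of the Kronecker RLS step.
#' @param alpha blend weight in [0, 1] on the given similarities (1 - alpha
#'   on the GIP kernels).
#' @param gammaPrime GIP bandwidth multiplier.
#' @return a [ScoreMatrix-class].
#' @export
predictRlsWnn <- function(Y, Sd, St, W = NULL, eta = 0.9, sigma = 1,
                          alpha = 0.5, gammaPrime = 1) {
    tri <- validateTriple(Y, Sd, St)
    Yv <- values(tri$Y)
    Wv <- .asMask(W, Yv)
    Ytrain <- Yv * Wv
    n <- nrow(Yv); m <- ncol(Yv)
    ## cold-start entities: whole profile masked out, or observed but empty
    coldDrug <- which(rowSums(Wv) == 0 | rowSums(Ytrain) == 0)
    coldTarget <- which(colSums(Wv) == 0 | colSums(Ytrain) == 0)
    trainDrugs <- setdiff(seq_len(n), coldDrug)
    trainTargets <- setdiff(seq_len(m), coldTarget)
    Yfill <- Ytrain
    Yobj <- InteractionMatrix(Ytrain)
    if (length(trainDrugs))
        for (i in coldDrug)
            Yfill[i, ] <- wnnProfile(Yobj, tri$Sd, i, eta, "drug",
                                     trainIdx = trainDrugs)
    if (length(trainTargets))
        for (l in coldTarget)
            Yfill[, l] <- wnnProfile(Yobj, tri$St, l, eta, "target",
                                     trainIdx = trainTargets)
    Kd <- blendKernels(gipKernel(ScoreMatrix(Yfill), "drug", gammaPrime),
                       tri$Sd, alpha)
    Kt <- blendKernels(gipKernel(ScoreMatrix(Yfill), "target", gammaPrime),
                       tri$St, alpha)
    ## measured similarities need not be PSD; project the blends onto the
    ## PSD cone so the ridge solve is well posed
    kronRlsPredict(ScoreMatrix(Yfill), .psdProject(values(Kd)),
                   .psdProject(values(Kt)), sigma)
}
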