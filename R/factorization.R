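## The collaborative matrix factorization family.  All three objectives
## share the masked low-rank fit term ||W o (Y - A B^T)||_F^2 and the
## Tikhonov term lambdaL (||A||^2 + ||B||^2); they differ in how side
## information couples to the factors:
##   CMF    adds lambdaD ||Sd - A A^T||^2 + lambdaT ||St - B B^T||^2,
##   MSCMF  replaces Sd/St by simplex-weighted combinations of several
##          similarity matrices, with a Tikhonov term on the weights,
##   WGRMF  adds graph-regularization traces lambdaD Tr(A^T Ld A) +
##          lambdaT Tr(B^T Lt B) over sparsified normalized Laplacians.
## The optimizer is alternating row-wise regularized least squares with
## the quartic similarity coupling linearized at the previous iterate
## (CMF/MSCMF) or the Laplacian term majorized via lambda_max(L) <= 2
## (WGRMF); every accepted iterate is required not to increase the exact
## objective, enforced by step halving.

#' Parameters of the matrix factorization methods
#'
#' @param k latent dimension (capped at min(n, m) - 1 during fitting).
#' @param lambdaL Tikhonov weight on the latent factors.
#' @param lambdaD,lambdaT coupling weights for the drug/target side
#'   information (similarity reconstruction for CMF/MSCMF, graph
#'   regularization for WGRMF).
#' @param lambdaW MSCMF-only Tikhonov weight on the similarity-combination
#'   weight vectors.
#' @param pNeighbors WGRMF-only neighbour count used to sparsify the
#'   similarity graphs before forming Laplacians.
#' @return a named list of validated parameters.
#' @export
cmfParams <- function(k = 50, lambdaL = 0.25, lambdaD = 0.125,
                      lambdaT = 0.125, lambdaW = 0.1, pNeighbors = 5) {
    list(k = .asCount(k, "k"),
         lambdaL = .asScalar(lambdaL, "lambdaL", lower = 0),
         lambdaD = .asScalar(lambdaD, "lambdaD", lower = 0),
         lambdaT = .asScalar(lambdaT, "lambdaT", lower = 0),
         lambdaW = .asScalar(lambdaW, "lambdaW", lower = 0),
         pNeighbors = .asCount(pNeighbors, "pNeighbors"))
}

.factorInputs <- function(Y, W, factors) {
    Yv <- if (is(Y, "InteractionMatrix") || is(Y, "ScoreMatrix"))
        values(Y) else as.matrix(Y)
    Wv <- .asMask(W, Yv)
    stopifnot(is(factors, "LatentFactors"))
    A <- factors@A; B <- factors@B
    stopifnot(nrow(A) == nrow(Yv), nrow(B) == ncol(Yv))
    list(Y = Yv, W = Wv, A = A, B = B)
}

.simValues <- function(S) {
    if (is(S, "SimilarityMatrix")) values(S) else as.matrix(S)
}

#' CMF objective function
#'
#' \deqn{\|W \circ (Y - AB^\top)\|_F^2
#'   + \lambda_l(\|A\|_F^2 + \|B\|_F^2)
#'   + \lambda_d\|S_d - AA^\top\|_F^2 + \lambda_t\|S_t - BB^\top\|_F^2}
#'
#' @param Y interaction matrix (object or plain matrix).
#' @param W [WeightMask-class], binary matrix, or NULL for all-ones.
#' @param factors a [LatentFactors-class].
#' @param Sd,St similarity matrices (objects or plain matrices).
#' @param params a [cmfParams()] list.
#' @return the non-negative objective value.
#' @export
cmfObjective <- function(Y, W, factors, Sd, St, params = cmfParams()) {
    x <- .factorInputs(Y, W, factors)
    Sdv <- .simValues(Sd); Stv <- .simValues(St)
    R <- x$W * (x$Y - tcrossprod(x$A, x$B))
    sum(R^2) +
        params$lambdaL * (sum(x$A^2) + sum(x$B^2)) +
        params$lambdaD * sum((Sdv - tcrossprod(x$A))^2) +
        params$lambdaT * sum((Stv - tcrossprod(x$B))^2)
}

#' Analytic gradient of the CMF objective
#'
#' @inheritParams cmfObjective
#' @return list with matrices `A` and `B`, the partial derivatives.
#' @export
cmfGradient <- function(Y, W, factors, Sd, St, params = cmfParams()) {
    x <- .factorInputs(Y, W, factors)
    Sdv <- .simValues(Sd); Stv <- .simValues(St)
    R <- x$W * (x$Y - tcrossprod(x$A, x$B))
    list(A = -2 * R %*% x$B + 2 * params$lambdaL * x$A -
             4 * params$lambdaD * (Sdv - tcrossprod(x$A)) %*% x$A,
         B = -2 * crossprod(R, x$A) + 2 * params$lambdaL * x$B -
             4 * params$lambdaT * (Stv - tcrossprod(x$B)) %*% x$B)
}

#' MSCMF objective function
#'
#' The CMF objective with each similarity matrix replaced by a convex
#' combination \eqn{\sum_k \omega^k S^k} of several similarity matrices,
#' plus \eqn{\lambda_\omega(\|\omega_d\|^2 + \|\omega_t\|^2)}; both weight
#' vectors live on the probability simplex.
#'
#' @inheritParams cmfObjective
#' @param SdList,StList lists of drug / target similarity matrices.
#' @param omegaD,omegaT non-negative weight vectors summing to 1.
#' @return the objective value.
#' @export
mscmfObjective <- function(Y, W, factors, SdList, StList, omegaD, omegaT,
                           params = cmfParams()) {
    .checkSimplex(omegaD, length(SdList), "omegaD")
    .checkSimplex(omegaT, length(StList), "omegaT")
    Sd <- .combineSims(SdList, omegaD)
    St <- .combineSims(StList, omegaT)
    cmfObjective(Y, W, factors, Sd, St, params) +
        params$lambdaW * (sum(omegaD^2) + sum(omegaT^2))
}

#' @describeIn mscmfObjective analytic gradient with respect to A, B and
#'   both weight vectors.
#' @export
mscmfGradient <- function(Y, W, factors, SdList, StList, omegaD, omegaT,
                          params = cmfParams()) {
    .checkSimplex(omegaD, length(SdList), "omegaD")
    .checkSimplex(omegaT, length(StList), "omegaT")
    Sd <- .combineSims(SdList, omegaD)
    St <- .combineSims(StList, omegaT)
    g <- cmfGradient(Y, W, factors, Sd, St, params)
    x <- .factorInputs(Y, W, factors)
    Rd <- Sd - tcrossprod(x$A)
    Rt <- St - tcrossprod(x$B)
    g$omegaD <- vapply(SdList, function(S)
        2 * params$lambdaD * sum(.simValues(S) * Rd), numeric(1)) +
        2 * params$lambdaW * omegaD
    g$omegaT <- vapply(StList, function(S)
        2 * params$lambdaT * sum(.simValues(S) * Rt), numeric(1)) +
        2 * params$lambdaW * omegaT
    g
}

.checkSimplex <- function(w, len, what) {
    if (length(w) != len || any(w < -1e-12) || abs(sum(w) - 1) > 1e-9)
        stop(sprintf("'%s' must be a length-%d non-negative vector summing to 1",
                     what, len), call. = FALSE)
    invisible(TRUE)
}

.combineSims <- function(SList, w) {
    out <- w[1L] * .simValues(SList[[1L]])
    for (i in seq_along(SList)[-1L]) out <- out + w[i] * .simValues(SList[[i]])
    out
}

#' Sparsified normalized graph Laplacian
#'
#' Zeroes the diagonal of `S`, keeps entry (i, j) iff j is among i's
#' `pNeighbors` most similar entities or i is among j's (symmetric OR
#' rule), and returns \eqn{\tilde L = I - D^{-1/2} S^* D^{-1/2}} with D the
#' diagonal of row sums of the sparsified \eqn{S^*}.  Isolated nodes keep
#' an identity row.  Eigenvalues of the result lie in [0, 2].
#'
#' @param S a [SimilarityMatrix-class] or square symmetric matrix.
#' @param pNeighbors positive neighbour count, less than the entity count.
#' @return symmetric PSD matrix (plain, labelled).
#' @export
buildLaplacian <- function(S, pNeighbors = 5) {
    Sv <- .simValues(S)
    n <- nrow(Sv)
    pNeighbors <- .asCount(pNeighbors, "pNeighbors")
    if (pNeighbors >= n)
        stop("pNeighbors must be smaller than the entity count",
             call. = FALSE)
    A <- Sv
    diag(A) <- 0
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        nb <- order(-A[i, ], seq_len(n))[seq_len(pNeighbors)]
        keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)
    A[!keep] <- 0
    d <- rowSums(A)
    inv <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(n) - (inv * A) * rep(inv, each = n)
    L <- (L + t(L)) / 2
    dimnames(L) <- dimnames(Sv)
    L
}

#' WGRMF objective function
#'
#' \deqn{\|W \circ (Y - AB^\top)\|_F^2
#'   + \lambda_l(\|A\|_F^2 + \|B\|_F^2)
#'   + \lambda_d \mathrm{Tr}(A^\top \tilde L_d A)
#'   + \lambda_t \mathrm{Tr}(B^\top \tilde L_t B)}
#'
#' @inheritParams cmfObjective
#' @param Ld,Lt normalized graph Laplacians from [buildLaplacian()].
#' @return the objective value (non-negative for PSD Laplacians).
#' @export
wgrmfObjective <- function(Y, W, factors, Ld, Lt, params = cmfParams()) {
    x <- .factorInputs(Y, W, factors)
    R <- x$W * (x$Y - tcrossprod(x$A, x$B))
    sum(R^2) +
        params$lambdaL * (sum(x$A^2) + sum(x$B^2)) +
        params$lambdaD * sum(x$A * (Ld %*% x$A)) +
        params$lambdaT * sum(x$B * (Lt %*% x$B))
}

#' @describeIn wgrmfObjective analytic gradient with respect to A and B.
#' @export
wgrmfGradient <- function(Y, W, factors, Ld, Lt, params = cmfParams()) {
    x <- .factorInputs(Y, W, factors)
    R <- x$W * (x$Y - tcrossprod(x$A, x$B))
    list(A = -2 * R %*% x$B + 2 * params$lambdaL * x$A +
             2 * params$lambdaD * (Ld %*% x$A),
         B = -2 * crossprod(R, x$A) + 2 * params$lambdaL * x$B +
             2 * params$lambdaT * (Lt %*% x$B))
}

#' Reconstruct interaction scores from latent factors
#'
#' @param factors a [LatentFactors-class].
#' @param drugIds,targetIds optional labels for the score matrix.
#' @return \eqn{\hat Y = AB^\top} as a [ScoreMatrix-class].
#' @export
predictFactors <- function(factors, drugIds = NULL, targetIds = NULL) {
    stopifnot(is(factors, "LatentFactors"))
    out <- tcrossprod(factors@A, factors@B)
    if (!is.null(drugIds)) rownames(out) <- drugIds
    if (!is.null(targetIds)) colnames(out) <- targetIds
    ScoreMatrix(out)
}

## ---- alternating optimizer -------------------------------------------

## Row-block proposal: solve, for every row i of `A`,
##   (Bt D_i B + ridge) a_i = B^T (w_i o y_i) + rhsExtra_i
## where D_i = diag(w_i).  BtB is corrected per row by subtracting the
## crossproduct over that row's masked columns, which is cheap when masks
## are dense in 1s (the usual CV case).
.rowSolve <- function(Yv, Wv, B, ridge, rhsExtra = NULL) {
    n <- nrow(Yv); k <- ncol(B)
    BtB <- crossprod(B)
    R <- (Wv * Yv) %*% B
    if (!is.null(rhsExtra)) R <- R + rhsExtra
    allOnes <- all(Wv == 1)
    out <- matrix(0, n, k)
    if (allOnes) {
        M <- BtB + ridge
        out <- t(solve(M, t(R)))
    } else {
        for (i in seq_len(n)) {
            z <- which(Wv[i, ] == 0)
            Ci <- if (length(z))
                BtB - crossprod(B[z, , drop = FALSE]) else BtB
            out[i, ] <- solve(Ci + ridge, R[i, ])
        }
    }
    out
}

## Accept a proposed block update only if the exact objective does not
## increase; otherwise damp the step by halving, up to `maxHalve` times.
## Returns list(value, obj, accepted).
.dampedAccept <- function(cur, prop, objFun, objCur, maxHalve = 20L) {
    t <- 1
    for (h in seq_len(maxHalve + 1L)) {
        cand <- cur + t * (prop - cur)
        objCand <- objFun(cand)
        if (is.finite(objCand) && objCand <= objCur)
            return(list(value = cand, obj = objCand, accepted = TRUE))
        t <- t / 2
    }
    list(value = cur, obj = objCur, accepted = FALSE)
}

## Euclidean projection onto the probability simplex.
.projectSimplex <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
}

#' Fit a matrix factorization model
#'
#' Alternating minimization of the chosen objective over the factor pair
#' (A, B) (and, for MSCMF, the similarity-combination weights).  Each
#' block update solves a regularized least-squares subproblem -- with the
#' similarity coupling linearized at the previous iterate (CMF/MSCMF) or
#' the Laplacian term majorized (WGRMF) -- and is accepted only if the
#' exact objective does not increase, enforced by step halving (up to 20
#' halvings, after which the fit stops).  The recorded objective trace is
#' therefore non-increasing by construction.
#'
#' @param method "cmf", "mscmf" or "wgrmf".
#' @param Y an [InteractionMatrix-class] (training labels).
#' @param W optional [WeightMask-class]/binary matrix; 0 marks held-out or
#'   unknown pairs, excluded from the fit term.
#' @param Sd,St similarity input: single matrices for cmf/wgrmf, lists of
#'   matrices for mscmf.
#' @param params a [cmfParams()] list.
#' @param seed integer seed for the random factor initialization
#'   (i.i.d. normal entries scaled by \eqn{1/\sqrt k}).
#' @param maxIter,tol stopping rule: stop when the relative objective
#'   decrease falls below `tol` or after `maxIter` outer iterations.
#' @return a list with `factors` ([LatentFactors-class]), `trace` (the
#'   per-iteration exact objective values, starting at the initial point),
#'   `omegaD`/`omegaT` (MSCMF weight vectors, NULL otherwise), and
#'   `iterations`.
#' @export
fitFactorization <- function(method = c("cmf", "mscmf", "wgrmf"), Y,
                             W = NULL, Sd, St, params = cmfParams(),
                             seed = 1, maxIter = 200, tol = 1e-6) {
    method <- match.arg(method)
    maxIter <- .asCount(maxIter, "maxIter")
    tol <- .asScalar(tol, "tol", lower = 0)
    Yv <- if (is(Y, "InteractionMatrix") || is(Y, "ScoreMatrix"))
        values(Y) else as.matrix(Y)
    Wv <- .asMask(W, Yv)
    n <- nrow(Yv); m <- ncol(Yv)
    k <- min(params$k, min(n, m) - 1L)
    if (k < 1L) stop("matrix too small for any latent dimension",
                     call. = FALSE)
    lamL <- params$lambdaL; lamD <- params$lambdaD; lamT <- params$lambdaT

    if (method == "mscmf") {
        if (!is.list(Sd) || !is.list(St))
            stop("mscmf needs lists of similarity matrices", call. = FALSE)
        SdList <- lapply(Sd, .simValues)
        StList <- lapply(St, .simValues)
        omegaD <- rep(1 / length(SdList), length(SdList))
        omegaT <- rep(1 / length(StList), length(StList))
        Sdv <- .combineSims(SdList, omegaD)
        Stv <- .combineSims(StList, omegaT)
    } else if (method == "cmf") {
        Sdv <- .simValues(Sd); Stv <- .simValues(St)
        omegaD <- omegaT <- NULL
    } else {
        Ld <- buildLaplacian(Sd, min(params$pNeighbors, n - 1L))
        Lt <- buildLaplacian(St, min(params$pNeighbors, m - 1L))
        omegaD <- omegaT <- NULL
    }

    init <- withSeed(seed, list(
        A = matrix(stats::rnorm(n * k), n, k) / sqrt(k),
        B = matrix(stats::rnorm(m * k), m, k) / sqrt(k)))
    A <- init$A; B <- init$B

    objective <- switch(method,
        cmf = function(A, B, oD, oT)
            cmfObjective(Yv, Wv, LatentFactors(A, B), Sdv, Stv, params),
        mscmf = function(A, B, oD, oT)
            mscmfObjective(Yv, Wv, LatentFactors(A, B), SdList, StList,
                           oD, oT, params),
        wgrmf = function(A, B, oD, oT)
            wgrmfObjective(Yv, Wv, LatentFactors(A, B), Ld, Lt, params))

    obj <- objective(A, B, omegaD, omegaT)
    if (!is.finite(obj))
        stop("objective not finite at initialization", call. = FALSE)
    trace <- obj
    iters <- 0L
    for (it in seq_len(maxIter)) {
        stalled <- TRUE
        ## A-step
        if (method == "wgrmf") {
            ridge <- diag(lamL + 2 * lamD, k)
            extra <- if (lamD > 0) -lamD * (Ld %*% A) + 2 * lamD * A
                     else NULL
        } else {
            ridge <- diag(lamL, k) + lamD * crossprod(A)
            extra <- if (lamD > 0) lamD * (Sdv %*% A) else NULL
        }
        Aprop <- .rowSolve(Yv, Wv, B, ridge, extra)
        st <- .dampedAccept(A, Aprop,
                            function(Ax) objective(Ax, B, omegaD, omegaT),
                            obj)
        if (st$accepted) { A <- st$value; obj <- st$obj; stalled <- FALSE }
        ## B-step (rows of B index targets; transpose the fit problem)
        if (method == "wgrmf") {
            ridge <- diag(lamL + 2 * lamT, k)
            extra <- if (lamT > 0) -lamT * (Lt %*% B) + 2 * lamT * B
                     else NULL
        } else {
            ridge <- diag(lamL, k) + lamT * crossprod(B)
            extra <- if (lamT > 0) Stv %*% B * lamT else NULL
        }
        Bprop <- .rowSolve(t(Yv), t(Wv), A, ridge, extra)
        st <- .dampedAccept(B, Bprop,
                            function(Bx) objective(A, Bx, omegaD, omegaT),
                            obj)
        if (st$accepted) { B <- st$value; obj <- st$obj; stalled <- FALSE }
        ## MSCMF weight update: exact equality-constrained quadratic
        ## minimization, then Euclidean projection onto the simplex.
        if (method == "mscmf") {
            upd <- .omegaUpdate(SdList, tcrossprod(A), lamD, params$lambdaW)
            st <- .dampedAccept(omegaD, upd,
                                function(o) objective(A, B, o, omegaT), obj)
            if (st$accepted) { omegaD <- st$value; obj <- st$obj
                               stalled <- FALSE }
            upd <- .omegaUpdate(StList, tcrossprod(B), lamT, params$lambdaW)
            st <- .dampedAccept(omegaT, upd,
                                function(o) objective(A, B, omegaD, o), obj)
            if (st$accepted) { omegaT <- st$value; obj <- st$obj
                               stalled <- FALSE }
            Sdv <- .combineSims(SdList, omegaD)
            Stv <- .combineSims(StList, omegaT)
        }
        if (!is.finite(obj))
            stop("objective became non-finite at iteration ", it,
                 call. = FALSE)
        trace <- c(trace, obj)
        iters <- it
        prev <- trace[length(trace) - 1L]
        if (stalled ||
            (prev - obj) / max(abs(prev), .Machine$double.eps) < tol)
            break
    }
    list(factors = LatentFactors(A, B), trace = trace,
         omegaD = omegaD, omegaT = omegaT, iterations = iters)
}

.omegaUpdate <- function(SList, G, lamSide, lamW) {
    M <- length(SList)
    if (M == 1L) return(1)
    Q <- matrix(0, M, M)
    cvec <- numeric(M)
    for (a in seq_len(M)) {
        cvec[a] <- lamSide * sum(SList[[a]] * G)
        for (b in a:M) {
            Q[a, b] <- Q[b, a] <- lamSide * sum(SList[[a]] * SList[[b]])
        }
    }
    diag(Q) <- diag(Q) + lamW
    Qi <- solve(Q)
    one <- rep(1, M)
    mu <- (sum(one * (Qi %*% cvec)) - 1) / sum(one * (Qi %*% one))
    .projectSimplex(as.numeric(Qi %*% (cvec - mu * one)))
}

#' Evaluator-facing factorization predictors
#'
#' Fit the named factorization on the masked training data and return the
#' reconstructed score matrix \eqn{AB^\top}.  `predictMSCMF` accepts lists
#' of similarity matrices; when handed single matrices it wraps them in
#' one-element lists.
#'
#' @inheritParams predictNearestProfile
#' @param params a [cmfParams()] list.
#' @param seed,maxIter,tol passed to [fitFactorization()].
#' @return a [ScoreMatrix-class].
#' @export
predictCMF <- function(Y, Sd, St, W = NULL, params = cmfParams(),
                       seed = 1, maxIter = 200, tol = 1e-6) {
    tri <- validateTriple(Y, Sd, St)
    fit <- fitFactorization("cmf", tri$Y, W, values(tri$Sd),
                            values(tri$St), params, seed, maxIter, tol)
    predictFactors(fit$factors, drugNames(Y), targetNames(Y))
}

#' @rdname predictCMF
#' @export
predictWGRMF <- function(Y, Sd, St, W = NULL, params = cmfParams(),
                         seed = 1, maxIter = 200, tol = 1e-6) {
    tri <- validateTriple(Y, Sd, St)
    fit <- fitFactorization("wgrmf", tri$Y, W, values(tri$Sd),
                            values(tri$St), params, seed, maxIter, tol)
    predictFactors(fit$factors, drugNames(Y), targetNames(Y))
}

#' @rdname predictCMF
#' @param SdList,StList lists of similarity matrices for MSCMF.
#' @export
predictMSCMF <- function(Y, SdList, StList, W = NULL, params = cmfParams(),
                         seed = 1, maxIter = 200, tol = 1e-6) {
    if (!is.list(SdList)) SdList <- list(SdList)
    if (!is.list(StList)) StList <- list(StList)
    fit <- fitFactorization("mscmf", Y, W, lapply(SdList, .simValues),
                            lapply(StList, .simValues), params, seed,
                            maxIter, tol)
    predictFactors(fit$factors, drugNames(Y), targetNames(Y))
}
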