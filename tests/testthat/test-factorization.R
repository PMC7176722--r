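## Small random problem shared by the gradient and fit tests.
factorProblem <- function(seed, n = 10, m = 8, k = 3) {
    set.seed(seed)
    Yv <- labelledMatrix(matrix(rbinom(n * m, 1, 0.3), n, m))
    Wv <- matrix(rbinom(n * m, 1, 0.8), n, m)
    Sd <- crossprod(matrix(runif(n * n), n)) / n
    Sd <- Sd / max(Sd); diag(Sd) <- 1
    St <- crossprod(matrix(runif(m * m), m)) / m
    St <- St / max(St); diag(St) <- 1
    fac <- LatentFactors(matrix(rnorm(n * k), n, k),
                         matrix(rnorm(m * k), m, k))
    list(Y = Yv, W = Wv, Sd = Sd, St = St, fac = fac,
         params = cmfParams(k = k, lambdaL = 0.2, lambdaD = 0.15,
                            lambdaT = 0.1, lambdaW = 0.05,
                            pNeighbors = 3))
}

test_that("CMF objective matches hand-evaluated cases", {
    ## zero factors, all-ones mask, three interactions, no regularization
    Y <- labelledMatrix(rbind(c(1, 1, 0), c(0, 1, 0)))
    zero <- LatentFactors(matrix(0, 2, 1), matrix(0, 3, 1))
    p0 <- cmfParams(k = 1, lambdaL = 0, lambdaD = 0, lambdaT = 0)
    expect_equal(cmfObjective(Y, NULL, zero, diag(2), diag(3), p0), 3)
    ## all-zero mask: only the Tikhonov term survives
    fac <- LatentFactors(matrix(1:2, 2, 1), matrix(1:3, 3, 1))
    pL <- cmfParams(k = 1, lambdaL = 0.5, lambdaD = 0, lambdaT = 0)
    expect_equal(cmfObjective(Y, matrix(0, 2, 3), fac, diag(2), diag(3),
                              pL), 0.5 * (5 + 14))
    ## 1x1 scalar case
    p1 <- cmfParams(k = 1, lambdaL = 0.1, lambdaD = 1, lambdaT = 1)
    expect_equal(cmfObjective(matrix(1), NULL,
                              LatentFactors(matrix(1), matrix(1)),
                              matrix(1), matrix(1), p1), 0.2)
})

test_that("MSCMF reduces to CMF for single similarity matrices", {
    fx <- factorProblem(21)
    base <- cmfObjective(fx$Y, fx$W, fx$fac, fx$Sd, fx$St, fx$params)
    expect_equal(mscmfObjective(fx$Y, fx$W, fx$fac, list(fx$Sd),
                                list(fx$St), 1, 1, fx$params),
                 base + fx$params$lambdaW * 2)
    pNoW <- fx$params; pNoW$lambdaW <- 0
    expect_equal(mscmfObjective(fx$Y, fx$W, fx$fac, list(fx$Sd),
                                list(fx$St), 1, 1, pNoW),
                 cmfObjective(fx$Y, fx$W, fx$fac, fx$Sd, fx$St, pNoW))
    ## duplicated similarity matrices: any simplex weight is equivalent
    expect_equal(
        mscmfObjective(fx$Y, fx$W, fx$fac, list(fx$Sd, fx$Sd),
                       list(fx$St), c(0.3, 0.7), 1, pNoW),
        mscmfObjective(fx$Y, fx$W, fx$fac, list(fx$Sd, fx$Sd),
                       list(fx$St), c(0.5, 0.5), 1, pNoW))
    expect_error(mscmfObjective(fx$Y, fx$W, fx$fac, list(fx$Sd),
                                list(fx$St), 2, 1, fx$params), "omegaD")
})

test_that("normalized Laplacians have the expected structure", {
    ## two entities joined by a unit edge
    S2 <- matrix(c(1, 1, 1, 1), 2, 2)
    L <- buildLaplacian(S2, 1)
    expect_equal(unname(L), rbind(c(1, -1), c(-1, 1)))
    ## constant vectors are in the null space of a connected graph
    expect_equal(as.numeric(t(c(1, 1)) %*% L %*% c(1, 1)), 0)
    for (seed in 1:10) {
        set.seed(seed)
        n <- sample(4:12, 1)
        S <- crossprod(matrix(runif(n * n), n)); S <- S / max(S)
        diag(S) <- 1
        L <- buildLaplacian(S, 3)
        ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
        expect_gte(min(ev), -1e-8)
        expect_lte(max(ev), 2 + 1e-8)
    }
    expect_error(buildLaplacian(S2, 0), "pNeighbors")
    expect_error(buildLaplacian(S2, 2), "smaller")
})

test_that("WGRMF objective shares terms with CMF when uncoupled", {
    for (seed in 1:10) {
        fx <- factorProblem(seed)
        p0 <- fx$params; p0$lambdaD <- 0; p0$lambdaT <- 0
        Ld <- buildLaplacian(fx$Sd, 3); Lt <- buildLaplacian(fx$St, 3)
        expect_identical(wgrmfObjective(fx$Y, fx$W, fx$fac, Ld, Lt, p0),
                         cmfObjective(fx$Y, fx$W, fx$fac, fx$Sd, fx$St,
                                      p0))
        expect_gte(wgrmfObjective(fx$Y, fx$W, fx$fac, Ld, Lt,
                                  fx$params), 0)
    }
    ## identical factor rows on a connected 2-node graph add nothing
    L <- buildLaplacian(matrix(c(1, 1, 1, 1), 2, 2), 1)
    facEq <- LatentFactors(rbind(c(1, 2), c(1, 2)), matrix(0, 3, 2))
    p <- cmfParams(k = 2, lambdaL = 0, lambdaD = 5, lambdaT = 0)
    expect_equal(wgrmfObjective(matrix(0, 2, 3), matrix(0, 2, 3), facEq,
                                L, buildLaplacian(diag(3) + 0.5, 1), p),
                 0)
})

test_that("analytic gradients agree with finite differences", {
    fx <- factorProblem(31, n = 7, m = 6, k = 2)
    Ld <- buildLaplacian(fx$Sd, 3); Lt <- buildLaplacian(fx$St, 3)
    A <- fx$fac@A; B <- fx$fac@B
    ## cmf
    g <- cmfGradient(fx$Y, fx$W, fx$fac, fx$Sd, fx$St, fx$params)
    fdA <- fdGradient(function(X) cmfObjective(
        fx$Y, fx$W, LatentFactors(X, B), fx$Sd, fx$St, fx$params), A)
    fdB <- fdGradient(function(X) cmfObjective(
        fx$Y, fx$W, LatentFactors(A, X), fx$Sd, fx$St, fx$params), B)
    expect_lt(relErr(fdA, g$A), 1e-5)
    expect_lt(relErr(fdB, g$B), 1e-5)
    ## wgrmf
    g <- wgrmfGradient(fx$Y, fx$W, fx$fac, Ld, Lt, fx$params)
    fdA <- fdGradient(function(X) wgrmfObjective(
        fx$Y, fx$W, LatentFactors(X, B), Ld, Lt, fx$params), A)
    expect_lt(relErr(fdA, g$A), 1e-5)
    ## mscmf, including the weight-vector gradient
    SdL <- list(fx$Sd, diag(nrow(fx$Y))); StL <- list(fx$St)
    oD <- c(0.4, 0.6); oT <- 1
    g <- mscmfGradient(fx$Y, fx$W, fx$fac, SdL, StL, oD, oT, fx$params)
    fdA <- fdGradient(function(X) mscmfObjective(
        fx$Y, fx$W, LatentFactors(X, B), SdL, StL, oD, oT, fx$params), A)
    expect_lt(relErr(fdA, g$A), 1e-5)
    ## omega gradient checked against the unconstrained objective surface
    fdO <- vapply(1:2, function(i) {
        h <- 1e-6; up <- oD; up[i] <- up[i] + h
        dn <- oD; dn[i] <- dn[i] - h
        obj <- function(o) {
            S <- o[1] * SdL[[1]] + o[2] * SdL[[2]]
            cmfObjective(fx$Y, fx$W, fx$fac, S, fx$St, fx$params) +
                fx$params$lambdaW * (sum(o^2) + sum(oT^2))
        }
        (obj(up) - obj(dn)) / (2 * h)
    }, numeric(1))
    expect_lt(relErr(fdO, g$omegaD), 1e-5)
})

test_that("alternating fits decrease the objective monotonically", {
    for (seed in 1:3) {
        fx <- factorProblem(seed + 40, n = 12, m = 9, k = 3)
        for (method in c("cmf", "wgrmf")) {
            fit <- fitFactorization(method, fx$Y, fx$W, fx$Sd, fx$St,
                                    fx$params, seed = seed,
                                    maxIter = 40, tol = 1e-9)
            expect_true(all(diff(fit$trace) <= 1e-12))
            ## final trace entry equals an independent objective call
            final <- if (method == "cmf")
                cmfObjective(fx$Y, fx$W, fit$factors, fx$Sd, fx$St,
                             fx$params)
            else wgrmfObjective(fx$Y, fx$W, fit$factors,
                                buildLaplacian(fx$Sd, 3),
                                buildLaplacian(fx$St, 3), fx$params)
            expect_equal(final, fit$trace[length(fit$trace)],
                         tolerance = 1e-9)
        }
        fitM <- fitFactorization("mscmf", fx$Y, fx$W,
                                 list(fx$Sd, diag(nrow(fx$Y))),
                                 list(fx$St), fx$params, seed = seed,
                                 maxIter = 30, tol = 1e-9)
        expect_true(all(diff(fitM$trace) <= 1e-12))
        expect_equal(sum(fitM$omegaD), 1, tolerance = 1e-12)
        expect_true(all(fitM$omegaD >= 0))
    }
})

test_that("fits are deterministic given the seed", {
    fx <- factorProblem(55)
    f1 <- fitFactorization("cmf", fx$Y, fx$W, fx$Sd, fx$St, fx$params,
                           seed = 9, maxIter = 25, tol = 1e-9)
    f2 <- fitFactorization("cmf", fx$Y, fx$W, fx$Sd, fx$St, fx$params,
                           seed = 9, maxIter = 25, tol = 1e-9)
    expect_equal(f1$factors@A, f2$factors@A, tolerance = 1e-12)
    expect_equal(f1$factors@B, f2$factors@B, tolerance = 1e-12)
    expect_identical(f1$trace, f2$trace)
})

test_that("a noise-free low-rank matrix is recovered", {
    set.seed(42)
    n <- 30; m <- 20; r <- 3
    A0 <- matrix(rnorm(n * r), n, r); B0 <- matrix(rnorm(m * r), m, r)
    Yr <- tcrossprod(A0, B0)
    Sd <- exp(-as.matrix(dist(A0))^2 / (2 * r)); diag(Sd) <- 1
    St <- exp(-as.matrix(dist(B0))^2 / (2 * r)); diag(St) <- 1
    p <- cmfParams(k = r, lambdaL = 1e-6, lambdaD = 1e-6, lambdaT = 1e-6)
    fit <- fitFactorization("cmf", Yr, NULL, Sd, St, p, seed = 1,
                            maxIter = 500, tol = 1e-12)
    fitTerm <- sum((Yr - tcrossprod(fit$factors@A, fit$factors@B))^2)
    expect_lt(fitTerm, 1e-3)
})

test_that("factor prediction is the plain matrix product", {
    expect_equal(unname(values(predictFactors(
        LatentFactors(rbind(c(1, 0)), rbind(c(0, 1)))))), matrix(0, 1, 1))
    I3 <- LatentFactors(diag(3), diag(3))
    expect_equal(unname(values(predictFactors(I3))), diag(3))
    set.seed(8)
    A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(12), 4, 3)
    byHand <- matrix(0, 5, 4)
    for (i in 1:5) for (j in 1:4) byHand[i, j] <- sum(A[i, ] * B[j, ])
    expect_equal(unname(values(predictFactors(LatentFactors(A, B)))),
                 byHand)
})
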