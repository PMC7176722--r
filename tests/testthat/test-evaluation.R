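test_that("fold plans partition the unit set evenly and reproducibly", {
    Y <- randomY(4, 3, 0.5, 1)
    p1 <- makeFolds(Y, "S1", nFolds = 4, nRepeats = 2, seed = 3)
    expect_true(all(vapply(p1@folds, function(r)
        all(lengths(r) == 3), logical(1))))
    p2 <- makeFolds(Y, "S2", nFolds = 4, nRepeats = 1, seed = 3)
    expect_true(all(lengths(p2@folds[[1]]) == 1))
    expect_identical(makeFolds(Y, "S1", 4, 2, seed = 3)@folds, p1@folds)
    expect_error(makeFolds(Y, "S2", nFolds = 5, nRepeats = 1, seed = 1),
                 "exceeds")
    expect_error(makeFolds(Y, "S3", nFolds = 1, nRepeats = 1, seed = 1),
                 "nFolds")
})

test_that("fold masking removes exactly the held-out units", {
    Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
    plan <- makeFolds(Y, "S2", nFolds = 2, nRepeats = 1, seed = 1)
    f <- which(vapply(plan@folds[[1]], function(u) 1 %in% u, logical(1)))
    msk <- maskForFold(Y, plan, 1, f)
    expect_equal(unname(values(msk$trainY)[1, ]), c(0, 0))
    expect_equal(unname(values(msk$W)[1, ]), c(0, 0))
    expect_setequal(paste(msk$heldOut$drug, msk$heldOut$target),
                    c("1 1", "1 2"))
    expect_equal(msk$heldOut$label,
                 values(Y)[cbind(msk$heldOut$drug, msk$heldOut$target)])
    ## S1: a single pair is zeroed; held-out sizes tile the whole matrix
    plan1 <- makeFolds(Y, "S1", nFolds = 4, nRepeats = 1, seed = 2)
    tot <- 0
    for (k in 1:4) {
        m1 <- maskForFold(Y, plan1, 1, k)
        expect_equal(sum(values(m1$W) == 0), nrow(m1$heldOut))
        tot <- tot + nrow(m1$heldOut)
    }
    expect_equal(tot, 4)
})

test_that("AUC matches the pairwise oracle, including ties", {
    expect_equal(aucScore(c(1, 0), c(0.9, 0.1)), 1)
    expect_equal(aucScore(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
    expect_equal(aucScore(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 0.75)
    expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "positive and one negative")
    for (seed in 1:200) {
        set.seed(seed)
        n <- sample(2:50, 1)
        labels <- c(0, 1, rbinom(n, 1, 0.4))
        scores <- sample(seq(0, 1, by = 0.1), n + 2, replace = TRUE)
        expect_equal(aucScore(labels, scores), oracleAuc(labels, scores),
                     tolerance = 1e-12)
    }
    ## rank-based, hence invariant under strictly monotone transforms
    set.seed(99)
    labels <- rbinom(30, 1, 0.3); labels[1:2] <- c(0, 1)
    scores <- rnorm(30)
    expect_equal(aucScore(labels, exp(3 * scores)),
                 aucScore(labels, scores))
})

test_that("AUPR matches the step-integration oracle, including ties", {
    expect_equal(auprScore(c(1, 0), c(0.9, 0.1)), 1)
    expect_equal(auprScore(c(0, 1), c(0.9, 0.1)), 0.5)
    expect_error(auprScore(c(0, 0), c(0.1, 0.2)), "no positive")
    for (seed in 1:200) {
        set.seed(seed)
        n <- sample(2:50, 1)
        labels <- c(1, rbinom(n, 1, 0.3))
        scores <- sample(seq(0, 1, by = 0.1), n + 1, replace = TRUE)
        expect_equal(auprScore(labels, scores),
                     oracleAupr(labels, scores), tolerance = 1e-12)
    }
})

test_that("the evaluator grades oracle, antioracle and constant scorers", {
    dat <- smallTriple(seed = 10, n = 10, m = 8, density = 0.3)
    plan <- makeFolds(dat$Y, "S1", nFolds = 5, nRepeats = 2, seed = 4)
    rep <- evaluateMethod("oracle", dat$Y, dat$Sd, dat$St, plan)
    s <- metricSummary(rep)
    expect_equal(s$mean, c(1, 1))
    expect_equal(s$sd, c(0, 0))
    anti <- function(Y, Sd, St, W = NULL, ...)
        ScoreMatrix(-values(dtiMethod("oracle", fullY = dat$Y)(Y)))
    expect_equal(metricSummary(evaluateMethod(
        anti, dat$Y, dat$Sd, dat$St, plan))$mean[1], 0)
    const <- function(Y, Sd, St, W = NULL, ...)
        ScoreMatrix(values(Y) * 0 + 1)
    expect_equal(metricSummary(evaluateMethod(
        const, dat$Y, dat$Sd, dat$St, plan))$mean[1], 0.5)
})

test_that("aggregates are recomputable from the per-fold table", {
    dat <- smallTriple(seed = 12, n = 12, m = 9, density = 0.3)
    plan <- makeFolds(dat$Y, "S1", nFolds = 4, nRepeats = 2, seed = 5)
    rep <- evaluateMethod("wp", dat$Y, dat$Sd, dat$St, plan)
    s <- metricSummary(rep)
    f <- rep@folds[!rep@folds$skipped, ]
    expect_equal(s$mean, c(mean(f$auc), mean(f$aupr)), tolerance = 1e-12)
    expect_equal(s$sd, c(sd(f$auc), sd(f$aupr)), tolerance = 1e-12)
})

test_that("single-class folds are recorded as skipped, not dropped", {
    ## drug 1 has no interactions: holding it out yields all-zero labels
    Yv <- labelledMatrix(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1),
                               c(0, 1, 1)))
    Y <- InteractionMatrix(Yv)
    Sv <- matrix(0.5, 4, 4); diag(Sv) <- 1
    Tv <- matrix(0.5, 3, 3); diag(Tv) <- 1
    plan <- makeFolds(Y, "S2", nFolds = 4, nRepeats = 1, seed = 2)
    rep <- evaluateMethod("wp", Y, SimilarityMatrix(labelledMatrix(
        Sv, sprintf("d%d", 1:4), sprintf("d%d", 1:4))),
        SimilarityMatrix(labelledMatrix(Tv, sprintf("t%d", 1:3),
                                        sprintf("t%d", 1:3))), plan)
    expect_equal(sum(rep@folds$skipped), 1)
    expect_match(rep@folds$reason[rep@folds$skipped], "single-class")
    expect_equal(metricSummary(rep)$n_folds, c(3, 3))
})

test_that("target cold start (S3) masks whole columns and evaluates", {
    dat <- smallTriple(seed = 16, n = 10, m = 8, density = 0.3)
    plan <- makeFolds(dat$Y, "S3", nFolds = 4, nRepeats = 1, seed = 3)
    msk <- maskForFold(dat$Y, plan, 1, 1)
    held <- unique(msk$heldOut$target)
    expect_identical(sort(held), sort(plan@folds[[1]][[1]]))
    expect_true(all(values(msk$trainY)[, held] == 0))
    expect_true(all(values(msk$W)[, held] == 0))
    expect_true(all(values(msk$W)[, -held] == 1))
    rep <- evaluateMethod("wp", dat$Y, dat$Sd, dat$St, plan)
    s <- metricSummary(rep)
    expect_true(all(is.finite(s$mean)))
    expect_gte(min(rep@folds$auc, na.rm = TRUE), 0)
})

test_that("held-out labels cannot leak into cold-start predictions", {
    dat <- smallTriple(seed = 14, n = 10, m = 8, density = 0.3)
    plan <- makeFolds(dat$Y, "S2", nFolds = 5, nRepeats = 1, seed = 6)
    held <- plan@folds[[1]][[2]]
    msk <- maskForFold(dat$Y, plan, 1, 2)
    Yv <- values(dat$Y)
    Yv[held, ] <- sample(c(0, 1), length(held) * ncol(Yv),
                         replace = TRUE)
    msk2 <- maskForFold(InteractionMatrix(Yv), plan, 1, 2)
    for (m in c("wp", "rlswnn", "nbi")) {
        s1 <- dtiMethod(m)(msk$trainY, dat$Sd, dat$St, msk$W)
        s2 <- dtiMethod(m)(msk2$trainY, dat$Sd, dat$St, msk2$W)
        expect_equal(values(s1), values(s2), tolerance = 1e-12)
    }
})
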