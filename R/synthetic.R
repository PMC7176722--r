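## Synthetic bipartite interaction data with the structure chemogenomic
## methods assume: Y is (approximately) low rank, sparse, and similar
## drugs share targets -- because the similarity kernels are built from
## the same latent factors that generate Y.  This is precisely the
## guilt-by-association premise the factorization objectives encode, so
## the generated triples carry a recoverable signal; a permutation
## control is provided to destroy it while preserving marginals.

#' Specify a synthetic DTI data set
#'
#' @param nDrugs,nTargets entity counts.
#' @param rank latent dimension of the generating factors (<= min(n, m)).
#' @param density fraction of positive pairs in (0, 1); realized exactly
#'   by top-quantile thresholding.
#' @param similarityNoise standard deviation of the symmetric Gaussian
#'   perturbation added to the similarity kernels (0 = noise-free).
#' @param bandwidth Gaussian kernel bandwidth on the latent vectors;
#'   defaults to `2 * rank`, the expected squared distance between two
#'   independent standard-normal latent vectors, which centres the
#'   off-diagonal similarities around exp(-1).
#' @param seed integer seed; the whole triple is deterministic given it.
#' @return a validated spec list for [generateDTI()].
#' @export
simSpec <- function(nDrugs, nTargets, rank = 5, density = 0.1,
                    similarityNoise = 0.1, bandwidth = 2 * rank,
                    seed = 1) {
    nDrugs <- .asCount(nDrugs, "nDrugs")
    nTargets <- .asCount(nTargets, "nTargets")
    rank <- .asCount(rank, "rank")
    if (rank > min(nDrugs, nTargets))
        stop("rank must not exceed min(nDrugs, nTargets)", call. = FALSE)
    density <- .asScalar(density, "density", lower = 0, upper = 1,
                         strictLower = TRUE)
    if (density >= 1)
        stop("'density' must be below 1", call. = FALSE)
    if (density * nDrugs * nTargets < 1)
        stop("density too low: no positive pair would be generated",
             call. = FALSE)
    list(nDrugs = nDrugs, nTargets = nTargets, rank = rank,
         density = density,
         similarityNoise = .asScalar(similarityNoise, "similarityNoise",
                                     lower = 0),
         bandwidth = .asScalar(bandwidth, "bandwidth", lower = 0,
                               strictLower = TRUE),
         seed = .asCount(seed, "seed", min = 0L))
}

.latentKernel <- function(Fm, bandwidth, noise, prefix) {
    sq <- rowSums(Fm^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(Fm)
    d2[d2 < 0] <- 0
    S <- exp(-d2 / bandwidth)
    if (noise > 0) {
        E <- matrix(stats::rnorm(nrow(Fm)^2, sd = noise), nrow(Fm))
        S <- S + (E + t(E)) / 2
    }
    S <- pmin(pmax(S, 0), 1)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    labels <- sprintf("%s%03d", prefix, seq_len(nrow(Fm)))
    dimnames(S) <- list(labels, labels)
    new("SimilarityMatrix", values = S)
}

#' Generate a synthetic (Y, Sd, St) triple
#'
#' Draws latent factors A (n x rank) and B (m x rank) with i.i.d.
#' standard-normal entries, sets Z = AB', and places the
#' `ceiling(density * n * m)` largest entries of Z to 1 (ties resolved by
#' index).  Similarities are Gaussian kernels on the latent vectors,
#' `exp(-||a_i - a_j||^2 / bandwidth)`, perturbed by symmetric noise of
#' scale `similarityNoise`, clipped to [0, 1] with the unit diagonal
#' restored.
#'
#' @param spec a [simSpec()] list.
#' @return list with `Y` ([InteractionMatrix-class]), `Sd`, `St`
#'   ([SimilarityMatrix-class]) and the ground-truth `factors`
#'   ([LatentFactors-class]).
#' @export
generateDTI <- function(spec) {
    withSeed(spec$seed, {
        n <- spec$nDrugs; m <- spec$nTargets; r <- spec$rank
        A <- matrix(stats::rnorm(n * r), n, r)
        B <- matrix(stats::rnorm(m * r), m, r)
        Z <- tcrossprod(A, B)
        nPos <- ceiling(spec$density * n * m)
        Yv <- matrix(0, n, m)
        Yv[order(Z, decreasing = TRUE)[seq_len(nPos)]] <- 1
        dimnames(Yv) <- list(sprintf("d%03d", seq_len(n)),
                             sprintf("t%03d", seq_len(m)))
        Sd <- .latentKernel(A, spec$bandwidth, spec$similarityNoise, "d")
        St <- .latentKernel(B, spec$bandwidth, spec$similarityNoise, "t")
        list(Y = InteractionMatrix(Yv), Sd = Sd, St = St,
             factors = LatentFactors(A, B))
    })
}

#' Permutation control for similarity informativeness
#'
#' Applies one random permutation jointly to the rows and columns of each
#' similarity matrix while keeping the original labels in place, so the
#' similarity value distribution is preserved but the correspondence with
#' the interaction matrix is destroyed.  Used as a negative control: any
#' method whose performance survives this permutation is not actually
#' using the similarities.
#'
#' @param Sd,St [SimilarityMatrix-class] objects.
#' @param seed integer seed.
#' @return list with permuted `Sd`, `St` and the permutations used
#'   (`permD`, `permT`).
#' @export
permuteSimilarities <- function(Sd, St, seed = 1) {
    stopifnot(is(Sd, "SimilarityMatrix"), is(St, "SimilarityMatrix"))
    withSeed(seed, {
        pd <- sample.int(nrow(values(Sd)))
        pt <- sample.int(nrow(values(St)))
        list(Sd = .applyPerm(Sd, pd), St = .applyPerm(St, pt),
             permD = pd, permT = pt)
    })
}

.applyPerm <- function(S, p) {
    v <- values(S)
    out <- v[p, p, drop = FALSE]
    dimnames(out) <- dimnames(v)     # labels stay; values move
    new("SimilarityMatrix", values = out)
}
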