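## Network-based inference (NBI): two-step mass diffusion on the DTI
## bipartite graph.  Resource flows target -> drug -> target; the net
## effect on the drug side is the transfer matrix W with
##   W_ij = (1 / k(d_j)) * sum_l Y_il Y_jl / k(t_l),
## and predictions are Yhat = W Y.  Only the interaction matrix enters:
## NBI uses no chemical or genomic similarity, which is exactly why it
## cannot score orphan (cold-start) drugs above zero.

#' Drug-side diffusion weight matrix
#'
#' @param Y an [InteractionMatrix-class].
#' @return the n x n non-negative transfer matrix as a labelled base
#'   matrix; column j sums to 1 whenever drug j has degree > 0, and is
#'   identically zero for orphan drugs (degree-0 columns), by convention.
#' @examples
#' Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
#' nbiWeights(Y)   # [[0.75, 0.5], [0.25, 0.5]]
#' @export
nbiWeights <- function(Y) {
    stopifnot(is(Y, "InteractionMatrix"))
    Yv <- values(Y)
    kd <- rowSums(Yv)
    kt <- colSums(Yv)
    ## Y scaled by target degree: columns with kt = 0 are all-zero anyway
    Yt <- sweep(Yv, 2L, ifelse(kt > 0, kt, 1), "/")
    W <- tcrossprod(Yt, Yv)          # [i,j] = sum_l Y_il Y_jl / k(t_l)
    W <- sweep(W, 2L, ifelse(kd > 0, kd, 1), "/")
    W[, kd == 0] <- 0
    dimnames(W) <- list(drugNames(Y), drugNames(Y))
    W
}

#' Network-based inference prediction
#'
#' One application of the two-step diffusion: \eqn{\hat Y = W Y} with W
#' from [nbiWeights()].
#'
#' @param Y an [InteractionMatrix-class] (training labels; held-out entries
#'   already zeroed).
#' @return a [ScoreMatrix-class].
#' @examples
#' Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
#' values(nbiPredict(Y))   # [[0.75, 1.25], [0.25, 0.75]]
#' @export
nbiPredict <- function(Y) {
    W <- nbiWeights(Y)
    ScoreMatrix(W %*% values(Y))
}

#' @describeIn nbiPredict evaluator-facing wrapper with the common
#'   `(Y, Sd, St, W)` signature; similarities are accepted and ignored and
#'   the fold mask is applied by zeroing held-out entries before diffusion.
#' @param Sd,St ignored (NBI uses only the interaction matrix).
#' @param W optional fold mask; held-out entries of `Y` are zeroed.
#' @export
predictNBI <- function(Y, Sd = NULL, St = NULL, W = NULL) {
    Yv <- values(Y)
    Wv <- .asMask(W, Yv)
    nbiPredict(InteractionMatrix(Yv * Wv))
}
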