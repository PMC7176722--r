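## One place that maps short method names to evaluator-compatible
## prediction functions, shared by evaluateMethod() and the CLI.

#' Look up a prediction method by name
#'
#' Registered methods (all with signature `(Y, Sd, St, W, ...)` returning
#' a [ScoreMatrix-class]):
#' \describe{
#'   \item{np}{nearest profile ([predictNearestProfile()])}
#'   \item{wp}{weighted profile ([predictWeightedProfile()])}
#'   \item{rlswnn}{WNN-filled Kronecker RLS with GIP kernels
#'     ([predictRlsWnn()])}
#'   \item{nbi}{network-based inference ([predictNBI()])}
#'   \item{cmf}{collaborative matrix factorization ([predictCMF()])}
#'   \item{mscmf}{multiple-similarity CMF ([predictMSCMF()]; single
#'     similarity matrices are wrapped in one-element lists)}
#'   \item{wgrmf}{weighted graph regularized matrix factorization
#'     ([predictWGRMF()])}
#'   \item{oracle}{debug scorer that returns the *full* label matrix as
#'     scores, deliberately leaking the held-out labels; it exists to
#'     verify the evaluation harness (AUC = AUPR = 1 on every fold) and
#'     requires `fullY`.}
#' }
#'
#' @param name one of the names above.
#' @param fullY the complete [InteractionMatrix-class]; required by the
#'   `oracle` debug scorer only.
#' @return the prediction function.
#' @export
dtiMethod <- function(name, fullY = NULL) {
    name <- match.arg(name, c("np", "wp", "rlswnn", "nbi", "cmf", "mscmf",
                              "wgrmf", "oracle"))
    if (name == "oracle") {
        if (is.null(fullY))
            stop("the oracle debug scorer needs the full matrix (fullY)",
                 call. = FALSE)
        fullScores <- ScoreMatrix(values(fullY))
        return(function(Y, Sd, St, W = NULL, ...) fullScores)
    }
    switch(name,
           np = predictNearestProfile,
           wp = predictWeightedProfile,
           rlswnn = predictRlsWnn,
           nbi = predictNBI,
           cmf = predictCMF,
           mscmf = function(Y, Sd, St, W = NULL, ...)
               predictMSCMF(Y, list(Sd), list(St), W, ...),
           wgrmf = predictWGRMF)
}
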