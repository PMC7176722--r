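#' Construct an InteractionMatrix
#'
#' @param values numeric matrix with entries in \{0,1\}; drugs as rows.
#'   Missing dimnames are filled in as `d1, d2, ...` / `t1, t2, ...`.
#' @return a validated [InteractionMatrix-class].
#' @examples
#' InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
#' @export
InteractionMatrix <- function(values) {
    values <- .defaultLabels(as.matrix(values))
    storage.mode(values) <- "double"
    new("InteractionMatrix", values = values)
}

#' Construct a SimilarityMatrix
#'
#' @param values numeric square matrix of similarities in [0,1] with unit
#'   diagonal.  Missing labels are filled in as `e1, e2, ...`.
#' @param symmetrize if TRUE, replace `values` by `(values + t(values))/2`
#'   before validation.  Off by default so that asymmetric input surfaces as
#'   a data error rather than being silently repaired.
#' @return a validated [SimilarityMatrix-class].
#' @examples
#' SimilarityMatrix(matrix(c(1, .4, .4, 1), 2, 2))
#' @export
SimilarityMatrix <- function(values, symmetrize = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)) && !is.null(colnames(values)))
        rownames(values) <- colnames(values)
    values <- .defaultLabels(values, "e", "e")
    if (is.null(colnames(values))) colnames(values) <- rownames(values)
    if (isTRUE(symmetrize)) values <- (values + t(values)) / 2
    new("SimilarityMatrix", values = values)
}

#' Construct a ScoreMatrix
#'
#' @param values finite numeric matrix of prediction scores, drugs as rows.
#' @return a validated [ScoreMatrix-class].
#' @export
ScoreMatrix <- function(values) {
    values <- .defaultLabels(as.matrix(values))
    storage.mode(values) <- "double"
    new("ScoreMatrix", values = values)
}

#' Construct a WeightMask aligned to an InteractionMatrix
#'
#' @param values binary matrix (1 = pair participates in fitting).
#' @param Y optional [InteractionMatrix-class]; when given, labels are
#'   copied from it and shapes must agree.
#' @return a validated [WeightMask-class].
#' @export
WeightMask <- function(values, Y = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(Y)) {
        Yv <- values(Y)
        if (!identical(dim(values), dim(Yv)))
            stop("mask shape must match its InteractionMatrix", call. = FALSE)
        dimnames(values) <- dimnames(Yv)
    }
    values <- .defaultLabels(values)
    new("WeightMask", values = values)
}

#' Construct a LatentFactors object
#'
#' @param A numeric n x k matrix of drug factors.
#' @param B numeric m x k matrix of target factors.
#' @return a validated [LatentFactors-class].
#' @export
LatentFactors <- function(A, B) {
    new("LatentFactors", A = as.matrix(A), B = as.matrix(B))
}

#' Align a (Y, Sd, St) triple by entity labels
#'
#' Reorders the drug similarity matrix to the drug order of `Y` and the
#' target similarity matrix to its target order.  Alignment is strict: a
#' label present in `Y` but absent from a similarity matrix (or vice versa)
#' is an error naming the offending labels -- no silent intersection.
#'
#' @param Y an [InteractionMatrix-class].
#' @param Sd drug-drug [SimilarityMatrix-class] over exactly Y's drugs.
#' @param St target-target [SimilarityMatrix-class] over exactly Y's targets.
#' @return a list with elements `Y`, `Sd`, `St`, label-aligned.
#' @examples
#' Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2,
#'     dimnames = list(c("d1", "d2"), c("t1", "t2"))))
#' Sd <- SimilarityMatrix(matrix(c(1, .3, .3, 1), 2, 2,
#'     dimnames = list(c("d2", "d1"), c("d2", "d1"))))
#' St <- SimilarityMatrix(matrix(c(1, .2, .2, 1), 2, 2,
#'     dimnames = list(c("t1", "t2"), c("t1", "t2"))))
#' validateTriple(Y, Sd, St)$Sd
#' @export
validateTriple <- function(Y, Sd, St) {
    stopifnot(is(Y, "InteractionMatrix"), is(Sd, "SimilarityMatrix"),
              is(St, "SimilarityMatrix"))
    validObject(Y); validObject(Sd); validObject(St)
    list(Y = Y,
         Sd = .alignSimilarity(Sd, drugNames(Y), "drug"),
         St = .alignSimilarity(St, targetNames(Y), "target"))
}

.alignSimilarity <- function(S, wanted, what) {
    have <- entityNames(S)
    missing <- setdiff(wanted, have)
    extra <- setdiff(have, wanted)
    if (length(missing) || length(extra))
        stop(sprintf(
            "%s similarity labels do not match the interaction matrix%s%s",
            what,
            if (length(missing)) paste0("; missing: ",
                                        paste(missing, collapse = ", "))
            else "",
            if (length(extra)) paste0("; extra: ",
                                      paste(extra, collapse = ", "))
            else ""), call. = FALSE)
    if (identical(have, wanted)) return(S)
    new("SimilarityMatrix", values = S@values[wanted, wanted, drop = FALSE])
}

#' Interaction degree of drugs or targets
#'
#' The degree of a node in the DTI bipartite graph: row sums of Y for drugs
#' (`k(d_i)`, the size of each drug's interaction profile), column sums for
#' targets (`k(t_l)`).
#'
#' @param Y an [InteractionMatrix-class].
#' @param side "drug" or "target".
#' @return named integer vector of non-negative degrees.
#' @examples
#' Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
#' interactionDegree(Y, "drug")   # 2 1
#' interactionDegree(Y, "target") # 1 2
#' @export
interactionDegree <- function(Y, side = c("drug", "target")) {
    stopifnot(is(Y, "InteractionMatrix"))
    side <- .asSide(side)
    v <- values(Y)
    d <- if (side == "drug") rowSums(v) else colSums(v)
    storage.mode(d) <- "integer"
    d
}
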