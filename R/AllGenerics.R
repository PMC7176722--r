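#' Extract the numeric matrix payload of a chemoDTI object
#'
#' All matrix-like S4 classes in chemoDTI ([InteractionMatrix-class],
#' [SimilarityMatrix-class], [ScoreMatrix-class], [WeightMask-class]) carry
#' their data in a labelled base matrix; `values()` returns it.
#'
#' @param x a chemoDTI matrix-like object.
#' @return the underlying labelled numeric matrix.
#' @examples
#' Y <- InteractionMatrix(matrix(c(1, 0, 1, 1), 2, 2))
#' values(Y)
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "InteractionMatrix", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "SimilarityMatrix", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "ScoreMatrix", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "WeightMask", function(x) x@values)

#' @describeIn values drug labels of a bipartite object.
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))
#' @rdname values
#' @export
setMethod("drugNames", "InteractionMatrix", function(x) rownames(x@values))
#' @rdname values
#' @export
setMethod("drugNames", "ScoreMatrix", function(x) rownames(x@values))

#' @describeIn values target labels of a bipartite object.
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))
#' @rdname values
#' @export
setMethod("targetNames", "InteractionMatrix", function(x) colnames(x@values))
#' @rdname values
#' @export
setMethod("targetNames", "ScoreMatrix", function(x) colnames(x@values))

#' @describeIn values entity labels of a similarity kernel.
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))
#' @rdname values
#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) rownames(x@values))

.showMat <- function(label, v) {
    cat(sprintf("%s: %d x %d [%s ... x %s ...]\n", label, nrow(v), ncol(v),
                rownames(v)[1L], colnames(v)[1L]))
}

setMethod("show", "InteractionMatrix", function(object) {
    v <- object@values
    .showMat("InteractionMatrix", v)
    cat(sprintf("  %d interactions (density %.4f)\n", sum(v),
                mean(v)))
})

setMethod("show", "SimilarityMatrix", function(object) {
    v <- object@values
    cat(sprintf("SimilarityMatrix: %d entities [%s ...]\n", nrow(v),
                rownames(v)[1L]))
    off <- v[upper.tri(v)]
    if (length(off))
        cat(sprintf("  off-diagonal range [%.4f, %.4f]\n", min(off), max(off)))
})

setMethod("show", "ScoreMatrix", function(object) {
    v <- object@values
    .showMat("ScoreMatrix", v)
    cat(sprintf("  score range [%.4f, %.4f]\n", min(v), max(v)))
})

setMethod("show", "WeightMask", function(object) {
    v <- object@values
    .showMat("WeightMask", v)
    cat(sprintf("  %d of %d pairs included\n", sum(v), length(v)))
})

setMethod("show", "LatentFactors", function(object) {
    cat(sprintf("LatentFactors: %d drugs x %d targets, k = %d\n",
                nrow(object@A), nrow(object@B), ncol(object@A)))
})

setMethod("show", "FoldPlan", function(object) {
    cat(sprintf("FoldPlan: setting %s, %d folds x %d repeats (seed %d)\n",
                object@setting, object@nFolds, object@nRepeats, object@seed))
    cat(sprintf("  over %d drugs x %d targets\n",
                object@dims[1L], object@dims[2L]))
})

setMethod("show", "MetricReport", function(object) {
    cat(sprintf("MetricReport: method %s under %s\n",
                object@method, object@setting))
    print(metricSummary(object))
})

#' Drug and target factor accessors
#'
#' @param x a [LatentFactors-class] object.
#' @return `drugFactors()` the n x k matrix A; `targetFactors()` the m x k
#'   matrix B; `latentDim()` the integer k.
#' @export
setGeneric("drugFactors", function(x) standardGeneric("drugFactors"))
#' @rdname drugFactors
#' @export
setMethod("drugFactors", "LatentFactors", function(x) x@A)
#' @rdname drugFactors
#' @export
setGeneric("targetFactors", function(x) standardGeneric("targetFactors"))
#' @rdname drugFactors
#' @export
setMethod("targetFactors", "LatentFactors", function(x) x@B)
#' @rdname drugFactors
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))
#' @rdname drugFactors
#' @export
setMethod("latentDim", "LatentFactors", function(x) ncol(x@A))
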