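#' @import methods
NULL

.checkLabels <- function(lab, what) {
    if (is.null(lab) || length(lab) == 0L)
        return(sprintf("%s labels are missing", what))
    if (anyNA(lab) || any(!nzchar(lab)))
        return(sprintf("%s labels contain NA or empty strings", what))
    if (anyDuplicated(lab))
        return(sprintf("duplicated %s labels: %s", what,
                       paste(unique(lab[duplicated(lab)]), collapse = ", ")))
    NULL
}

#' InteractionMatrix: a binary bipartite drug-target linkage matrix
#'
#' Stores the 0/1 interaction matrix Y with drugs as rows and targets as
#' columns.  Row and column labels are mandatory and unique; every entry is
#' exactly 0 or 1.  A cell value of 1 records a known interaction; 0 is an
#' unobserved pair (which may be an undiscovered interaction -- the usual
#' caveat for chemogenomic gold standards).
#'
#' @slot values numeric matrix with entries in \{0, 1\} and complete,
#'   unique dimnames.
#' @seealso [InteractionMatrix()] for the constructor,
#'   [interactionDegree()], [validateTriple()]
#' @exportClass InteractionMatrix
setClass("InteractionMatrix", representation(values = "matrix"))

setValidity("InteractionMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("interaction values must be numeric")
    if (nrow(v) < 1L || ncol(v) < 1L)
        return("interaction matrix needs at least one drug and one target")
    msg <- c(.checkLabels(rownames(v), "drug"),
             .checkLabels(colnames(v), "target"))
    if (length(msg)) return(msg)
    if (anyNA(v) || !all(v == 0 | v == 1))
        return("interaction values must all be exactly 0 or 1")
    TRUE
})

#' SimilarityMatrix: a symmetric similarity kernel over one entity set
#'
#' A square matrix of pairwise similarities among drugs or among targets,
#' with values in [0, 1], unit diagonal and symmetry enforced to within
#' 1e-9.  Entity labels are mandatory and unique.
#'
#' @slot values numeric square matrix with matching row/column labels.
#' @seealso [SimilarityMatrix()] for the constructor
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("similarity values must be numeric")
    if (nrow(v) != ncol(v)) return("similarity matrix must be square")
    if (nrow(v) < 1L) return("similarity matrix must be non-empty")
    msg <- .checkLabels(rownames(v), "entity")
    if (length(msg)) return(msg)
    if (!identical(rownames(v), colnames(v)))
        return("similarity row and column labels must match")
    if (anyNA(v)) return("similarity values must not contain NA")
    if (max(abs(v - t(v))) > 1e-9)
        return("similarity matrix is asymmetric beyond tolerance 1e-9")
    if (any(abs(diag(v) - 1) > 1e-9))
        return("similarity diagonal entries must equal 1")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
        return("similarity values must lie in [0, 1]")
    TRUE
})

#' ScoreMatrix: real-valued predicted interaction scores
#'
#' Same shape and labels as the [InteractionMatrix-class] it was predicted
#' for; entries are finite ranking scores (not probabilities).
#'
#' @slot values finite numeric matrix with complete unique dimnames.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(values = "matrix"))

setValidity("ScoreMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("scores must be numeric")
    if (nrow(v) < 1L || ncol(v) < 1L) return("score matrix must be non-empty")
    msg <- c(.checkLabels(rownames(v), "drug"),
             .checkLabels(colnames(v), "target"))
    if (length(msg)) return(msg)
    if (!all(is.finite(v))) return("scores must all be finite")
    TRUE
})

#' WeightMask: binary inclusion mask aligned to an InteractionMatrix
#'
#' Entries equal to 1 mark drug-target pairs that participate in model
#' fitting; 0 marks unknown/held-out pairs, which contribute nothing to the
#' loss.  This is the factorization mask W, distinct from the network
#' diffusion weight matrix of [nbiWeights()].
#'
#' @slot values numeric 0/1 matrix with complete unique dimnames.
#' @exportClass WeightMask
setClass("WeightMask", representation(values = "matrix"))

setValidity("WeightMask", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("mask values must be numeric")
    msg <- c(.checkLabels(rownames(v), "drug"),
             .checkLabels(colnames(v), "target"))
    if (length(msg)) return(msg)
    if (anyNA(v) || !all(v == 0 | v == 1))
        return("mask values must all be exactly 0 or 1")
    TRUE
})

#' LatentFactors: low-rank factor pair (A, B) from matrix factorization
#'
#' Drug factors A (n x k) and target factors B (m x k) such that
#' \eqn{\hat Y = A B^\top} reconstructs the interaction matrix.
#'
#' @slot A numeric matrix of drug factors, one row per drug.
#' @slot B numeric matrix of target factors, one row per target.
#' @exportClass LatentFactors
setClass("LatentFactors", representation(A = "matrix", B = "matrix"))

setValidity("LatentFactors", function(object) {
    if (ncol(object@A) < 1L) return("latent dimension k must be >= 1")
    if (ncol(object@A) != ncol(object@B))
        return("A and B must share the latent dimension k")
    if (!all(is.finite(object@A)) || !all(is.finite(object@B)))
        return("latent factors must be finite")
    TRUE
})

#' FoldPlan: a cross-validation design over interaction data
#'
#' Holds the partition of evaluation units for one of the three settings:
#' \describe{
#'   \item{S1}{held-out drug-target pairs (units are matrix cells),}
#'   \item{S2}{held-out drugs (whole rows; the drug cold-start case),}
#'   \item{S3}{held-out targets (whole columns; the target cold-start case).}
#' }
#' Units are stored as integer indices: linear cell indices for S1 (column
#' major, as R matrices), row indices for S2, column indices for S3.
#'
#' @slot setting one of "S1", "S2", "S3".
#' @slot nFolds,nRepeats integers; number of folds per repeat and repeats.
#' @slot seed integer seed the plan was drawn from.
#' @slot dims integer c(n drugs, m targets) the plan applies to.
#' @slot folds list of length nRepeats; each element a list of nFolds
#'   disjoint integer vectors covering the unit set.
#' @exportClass FoldPlan
setClass("FoldPlan",
         representation(setting = "character", nFolds = "integer",
                        nRepeats = "integer", seed = "integer",
                        dims = "integer", folds = "list"))

setValidity("FoldPlan", function(object) {
    if (!object@setting %in% c("S1", "S2", "S3"))
        return("setting must be one of S1, S2, S3")
    if (object@nFolds < 2L) return("need at least 2 folds")
    if (object@nRepeats < 1L) return("need at least 1 repeat")
    if (length(object@folds) != object@nRepeats)
        return("folds list length must equal nRepeats")
    nUnits <- switch(object@setting,
                     S1 = prod(object@dims),
                     S2 = object@dims[1L],
                     S3 = object@dims[2L])
    for (rep in object@folds) {
        if (length(rep) != object@nFolds)
            return("each repeat must hold nFolds folds")
        if (any(lengths(rep) == 0L)) return("folds must be non-empty")
        all_idx <- sort(unlist(rep, use.names = FALSE))
        if (!identical(all_idx, seq_len(nUnits)))
            return("folds within a repeat must partition the unit set")
    }
    TRUE
})

#' MetricReport: per-fold and aggregated AUC/AUPR
#'
#' One row per (repeat, fold) with the fold's AUC and AUPR over its held-out
#' pairs, plus skip bookkeeping for degenerate single-class folds.
#' Aggregates (mean and standard deviation across all evaluated folds) are
#' recomputed on demand by [metricSummary()].
#'
#' @slot setting the cross-validation setting evaluated.
#' @slot method label of the evaluated method.
#' @slot folds data.frame with columns repeat_, fold, n_heldout, n_pos,
#'   n_neg, auc, aupr, skipped, reason.
#' @exportClass MetricReport
setClass("MetricReport",
         representation(setting = "character", method = "character",
                        folds = "data.frame"))

setValidity("MetricReport", function(object) {
    need <- c("repeat_", "fold", "n_heldout", "n_pos", "n_neg",
              "auc", "aupr", "skipped", "reason")
    if (!all(need %in% names(object@folds)))
        return(paste("folds table must have columns:",
                     paste(need, collapse = ", ")))
    ok <- !object@folds$skipped
    if (any(ok)) {
        a <- object@folds$auc[ok]; p <- object@folds$aupr[ok]
        if (any(a < 0 | a > 1) || any(p < 0 | p > 1))
            return("AUC and AUPR must lie in [0, 1]")
    }
    TRUE
})
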