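## Cross-validation regimes and ranking metrics.  Setting S1 partitions
## drug-target pairs (the classical case), S2 partitions drugs (drug
## cold start), S3 partitions targets (target cold start).  Held-out
## entries are zeroed in the training matrix AND excluded from the fit by
## the weight mask; labels for scoring come from the original matrix only
## at held-out positions, so a method can never see what it is graded on.

#' Build a cross-validation fold plan
#'
#' Draws `nRepeats` independent uniformly random partitions of the unit
#' set into `nFolds` near-equal folds.  Deterministic given the seed.
#'
#' @param Y an [InteractionMatrix-class].
#' @param setting "S1" (pairs), "S2" (drugs) or "S3" (targets).
#' @param nFolds number of folds (>= 2; for S2/S3 at most the entity
#'   count on that axis).
#' @param nRepeats number of repeated partitions.
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @export
makeFolds <- function(Y, setting = c("S1", "S2", "S3"), nFolds = 10,
                      nRepeats = 5, seed = 1) {
    stopifnot(is(Y, "InteractionMatrix"))
    setting <- match.arg(setting)
    nFolds <- .asCount(nFolds, "nFolds", min = 2L)
    nRepeats <- .asCount(nRepeats, "nRepeats")
    dims <- dim(values(Y))
    nUnits <- switch(setting, S1 = prod(dims), S2 = dims[1L],
                     S3 = dims[2L])
    if (nFolds > nUnits)
        stop(sprintf("nFolds = %d exceeds the %d available units for %s",
                     nFolds, nUnits, setting), call. = FALSE)
    folds <- withSeed(seed, lapply(seq_len(nRepeats), function(r) {
        perm <- sample.int(nUnits)
        sizes <- rep(nUnits %/% nFolds, nFolds)
        extra <- nUnits %% nFolds
        if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
        split(perm, rep(seq_len(nFolds), times = sizes))
    }))
    new("FoldPlan", setting = setting, nFolds = nFolds,
        nRepeats = nRepeats, seed = .asCount(seed, "seed", min = 0L),
        dims = as.integer(dims), folds = folds)
}

#' Mask one fold out of the interaction matrix
#'
#' Produces the training view for a given (repeat, fold): held-out units
#' are zeroed in the interaction matrix and zeroed in the weight mask
#' (whole rows for S2, whole columns for S3, single cells for S1), and the
#' held-out pairs are listed with their true labels.
#'
#' @param Y the full [InteractionMatrix-class].
#' @param plan a [FoldPlan-class] built on Y.
#' @param repeatIdx,foldIdx which repeat and fold to hold out.
#' @return list with `trainY` ([InteractionMatrix-class]), `W`
#'   ([WeightMask-class]) and `heldOut` (data.frame drug, target, label).
#' @export
maskForFold <- function(Y, plan, repeatIdx = 1, foldIdx = 1) {
    stopifnot(is(Y, "InteractionMatrix"), is(plan, "FoldPlan"))
    Yv <- values(Y)
    if (!identical(as.integer(dim(Yv)), plan@dims))
        stop("fold plan was built for a different matrix shape",
             call. = FALSE)
    repeatIdx <- .asCount(repeatIdx, "repeatIdx")
    foldIdx <- .asCount(foldIdx, "foldIdx")
    units <- plan@folds[[repeatIdx]][[foldIdx]]
    Wv <- matrix(1, nrow(Yv), ncol(Yv), dimnames = dimnames(Yv))
    if (plan@setting == "S1") {
        Wv[units] <- 0
        cells <- arrayInd(units, dim(Yv))
    } else if (plan@setting == "S2") {
        Wv[units, ] <- 0
        cells <- cbind(rep(units, each = ncol(Yv)),
                       rep(seq_len(ncol(Yv)), length(units)))
    } else {
        Wv[, units] <- 0
        cells <- cbind(rep(seq_len(nrow(Yv)), length(units)),
                       rep(units, each = nrow(Yv)))
    }
    heldOut <- data.frame(drug = cells[, 1L], target = cells[, 2L],
                          label = Yv[cells])
    list(trainY = InteractionMatrix(Yv * Wv),
         W = new("WeightMask", values = Wv),
         heldOut = heldOut)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with tied scores counted 1/2 -- computed from average
#' ranks, so it is exact under ties and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
    .checkMetricInput(labels, scores)
    P <- sum(labels == 1); N <- sum(labels == 0)
    if (P == 0 || N == 0)
        stop("AUC undefined: need at least one positive and one negative",
             call. = FALSE)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with tied scores treated as one group: walking the
#' unique score values in decreasing order, each group contributes its
#' recall increment times the precision after the whole group is
#' included.  For tie-free scores this is the usual "precision at each
#' positive's rank" sum.
#'
#' @inheritParams aucScore
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(labels, scores) {
    .checkMetricInput(labels, scores)
    P <- sum(labels == 1)
    if (P == 0)
        stop("AUPR undefined: no positive labels", call. = FALSE)
    ord <- order(-scores)
    s <- scores[ord]; y <- labels[ord]
    n <- length(s)
    grpEnd <- c(which(s[-n] != s[-1L]), n)  # last index of each tie group
    cumTP <- cumsum(y)[grpEnd]
    prec <- cumTP / grpEnd
    dTP <- diff(c(0, cumTP))
    sum(dTP / P * prec)
}

.checkMetricInput <- function(labels, scores) {
    if (length(labels) != length(scores) || !length(labels))
        stop("labels and scores must be non-empty and equal length",
             call. = FALSE)
    if (anyNA(labels) || !all(labels == 0 | labels == 1))
        stop("labels must be binary 0/1", call. = FALSE)
    if (anyNA(scores) || !all(is.finite(scores)))
        stop("scores must be finite", call. = FALSE)
    invisible(TRUE)
}

#' Cross-validated evaluation of a prediction method
#'
#' For every (repeat, fold): zero and mask the held-out units, call the
#' method on the training view, collect its scores at the held-out pairs,
#' and grade them against the true labels with [aucScore()] and
#' [auprScore()].  Folds whose held-out labels are single-class are
#' recorded as skipped (with the reason) and excluded from aggregates,
#' never silently dropped.
#'
#' @param method a prediction function with signature
#'   `(Y, Sd, St, W, ...)` returning a [ScoreMatrix-class], or one of the
#'   registered method names of [dtiMethod()].
#' @param Y,Sd,St the full data triple (label-aligned or alignable).
#' @param plan a [FoldPlan-class].
#' @param ... extra arguments passed to the method on every fold.
#' @param methodLabel label stored in the report; defaults to the method
#'   name or "custom".
#' @return a [MetricReport-class].
#' @export
evaluateMethod <- function(method, Y, Sd, St, plan, ...,
                           methodLabel = NULL) {
    tri <- validateTriple(Y, Sd, St)
    if (is.character(method)) {
        if (is.null(methodLabel)) methodLabel <- method
        method <- dtiMethod(method, fullY = tri$Y)
    } else if (is.null(methodLabel)) methodLabel <- "custom"
    stopifnot(is.function(method), is(plan, "FoldPlan"))
    rows <- vector("list", plan@nRepeats * plan@nFolds)
    idx <- 0L
    for (r in seq_len(plan@nRepeats)) {
        for (f in seq_len(plan@nFolds)) {
            idx <- idx + 1L
            msk <- maskForFold(tri$Y, plan, r, f)
            lab <- msk$heldOut$label
            if (all(lab == 1) || all(lab == 0)) {
                rows[[idx]] <- data.frame(
                    repeat_ = r, fold = f, n_heldout = length(lab),
                    n_pos = sum(lab), n_neg = sum(lab == 0),
                    auc = NA_real_, aupr = NA_real_, skipped = TRUE,
                    reason = "single-class held-out set")
                next
            }
            scores <- method(msk$trainY, tri$Sd, tri$St, msk$W, ...)
            sv <- values(scores)[cbind(msk$heldOut$drug,
                                       msk$heldOut$target)]
            rows[[idx]] <- data.frame(
                repeat_ = r, fold = f, n_heldout = length(lab),
                n_pos = sum(lab), n_neg = sum(lab == 0),
                auc = aucScore(lab, sv), aupr = auprScore(lab, sv),
                skipped = FALSE, reason = "")
        }
    }
    new("MetricReport", setting = plan@setting, method = methodLabel,
        folds = do.call(rbind, rows))
}

#' Aggregate a MetricReport
#'
#' @param report a [MetricReport-class].
#' @return data.frame with one row per metric (auc, aupr): mean, sd (over
#'   all evaluated folds x repeats), and the evaluated/skipped fold
#'   counts.
#' @export
metricSummary <- function(report) {
    stopifnot(is(report, "MetricReport"))
    f <- report@folds[!report@folds$skipped, , drop = FALSE]
    data.frame(
        metric = c("auc", "aupr"),
        mean = c(mean(f$auc), mean(f$aupr)),
        sd = c(stats::sd(f$auc), stats::sd(f$aupr)),
        n_folds = nrow(f),
        n_skipped = sum(report@folds$skipped))
}
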