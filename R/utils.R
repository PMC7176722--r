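## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded from `seed`, then restores the
#' caller's RNG state, so that package functions taking an explicit seed are
#' deterministic without clobbering the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
    seed <- .asCount(seed, "seed", min = 0L)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

.asCount <- function(x, what, min = 1L) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x))
        stop(sprintf("'%s' must be a single integer", what), call. = FALSE)
    x <- as.integer(x)
    if (x < min)
        stop(sprintf("'%s' must be >= %d", what, min), call. = FALSE)
    x
}

.asScalar <- function(x, what, lower = -Inf, upper = Inf,
                      strictLower = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", what),
             call. = FALSE)
    bad <- if (strictLower) x <= lower else x < lower
    if (bad || x > upper)
        stop(sprintf("'%s' = %g is outside its admissible range", what, x),
             call. = FALSE)
    as.numeric(x)
}

.defaultLabels <- function(v, rowPrefix = "d", colPrefix = "t") {
    if (is.null(rownames(v)))
        rownames(v) <- sprintf("%s%d", rowPrefix, seq_len(nrow(v)))
    if (is.null(colnames(v)))
        colnames(v) <- sprintf("%s%d", colPrefix, seq_len(ncol(v)))
    v
}

.asSide <- function(side) match.arg(side, c("drug", "target"))

## Orient a bipartite matrix so the requested side is on rows.
.sideRows <- function(v, side) if (side == "drug") v else t(v)

.sameShape <- function(a, b, what) {
    if (!identical(dim(a), dim(b)))
        stop(sprintf("%s: shapes differ (%d x %d vs %d x %d)", what,
                     nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
    if (!is.null(dimnames(a)) && !is.null(dimnames(b)) &&
        !identical(dimnames(a), dimnames(b)))
        stop(sprintf("%s: labels differ", what), call. = FALSE)
    invisible(TRUE)
}

## Coerce a WeightMask | matrix | NULL to a plain 0/1 matrix aligned to Y.
.asMask <- function(W, Yv) {
    if (is.null(W))
        return(matrix(1, nrow(Yv), ncol(Yv), dimnames = dimnames(Yv)))
    if (is(W, "WeightMask")) W <- W@values
    if (!is.matrix(W) || !all(W == 0 | W == 1))
        stop("mask must be a binary matrix or WeightMask", call. = FALSE)
    .sameShape(W, Yv, "mask vs interaction matrix")
    W
}
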