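## Readers/writers for the labelled tab-delimited formats DTI gold
## standards ship in (e.g. the public "admat" matrices), plus result
## serialization.  Canonical in-memory orientation is drugs-as-rows; the
## on-disk orientation is declared explicitly, never guessed, because the
## widely used exports are targets-as-rows.

.readTsvMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("empty or header-only table: ", path, call. = FALSE)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    ## tolerate both a leading corner cell and a bare column-label header
    body <- cells[-1L]
    ncolBody <- lengths(body)
    if (length(unique(ncolBody)) != 1L)
        stop("ragged rows in ", path, call. = FALSE)
    colLabels <- if (length(header) == ncolBody[1L]) header[-1L]
                 else if (length(header) == ncolBody[1L] - 1L) header
                 else stop("header width does not match rows in ", path,
                           call. = FALSE)
    rowLabels <- vapply(body, `[`, character(1), 1L)
    raw <- t(vapply(body, function(r) r[-1L],
                    character(length(colLabels))))
    if (length(colLabels) == 1L) raw <- matrix(raw, ncol = 1L)
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                     raw[bad[1L], bad[2L]], rowLabels[bad[1L]],
                     colLabels[bad[2L]], path), call. = FALSE)
    }
    dimnames(num) <- list(rowLabels, colLabels)
    num
}

.writeTsvMatrix <- function(v, path, corner = "") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(c(corner, colnames(v)), collapse = "\t"),
                 vapply(seq_len(nrow(v)), function(i)
                     paste(c(rownames(v)[i],
                             format(v[i, ], digits = 17, trim = TRUE,
                                    scientific = FALSE)),
                           collapse = "\t"), character(1))),
               con, sep = "\n")
    invisible(path)
}

#' Read a labelled interaction matrix from a TSV file
#'
#' @param path path to a tab-delimited table with row labels in the first
#'   column and column labels in the first row.
#' @param orientation which entity set is on the file's rows:
#'   `"drugs-as-rows"` or `"targets-as-rows"`.  Mandatory, because public
#'   DTI adjacency exports use both conventions; the returned object always
#'   has drugs as rows (a transpose is applied for targets-as-rows files).
#' @return an [InteractionMatrix-class].
#' @export
readInteractionMatrix <- function(path,
                                  orientation = c("drugs-as-rows",
                                                  "targets-as-rows")) {
    orientation <- match.arg(orientation)
    v <- .readTsvMatrix(path)
    if (!all(v == 0 | v == 1)) {
        bad <- which(!(v == 0 | v == 1), arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "non-binary cell %g at row '%s', column '%s' in %s",
            v[bad[1L], bad[2L]], rownames(v)[bad[1L]],
            colnames(v)[bad[2L]], path), call. = FALSE)
    }
    if (orientation == "targets-as-rows") v <- t(v)
    InteractionMatrix(v)
}

#' Read an interaction edge list
#'
#' Accepts two or three tab-separated columns: drug, target, and an
#' optional indicator that must equal 1.  The result covers the union of
#' observed labels (sorted lexicographically), with 1 at listed pairs.
#'
#' @param path path to the edge-list file.
#' @return an [InteractionMatrix-class].
#' @export
readEdgeList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty edge list: ", path, call. = FALSE)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(cells)
    if (any(nc < 2L | nc > 3L))
        stop(sprintf("edge list rows must have 2 or 3 columns (row %d has %d)",
                     which(nc < 2L | nc > 3L)[1L],
                     nc[which(nc < 2L | nc > 3L)[1L]]), call. = FALSE)
    drugs <- vapply(cells, `[`, character(1), 1L)
    targets <- vapply(cells, `[`, character(1), 2L)
    flag <- vapply(cells, function(r) if (length(r) == 3L) r[3L] else "1",
                   character(1))
    if (!all(flag == "1"))
        stop("third edge-list column must be 1 when present", call. = FALSE)
    if (anyDuplicated(paste(drugs, targets, sep = "\r")))
        stop("duplicate edge rows in ", path, call. = FALSE)
    dl <- sort(unique(drugs)); tl <- sort(unique(targets))
    v <- matrix(0, length(dl), length(tl), dimnames = list(dl, tl))
    v[cbind(match(drugs, dl), match(targets, tl))] <- 1
    InteractionMatrix(v)
}

#' Read a labelled similarity matrix from a TSV file
#'
#' @param path path to a square tab-delimited table.
#' @param symmetrize passed to [SimilarityMatrix()]; default FALSE so
#'   asymmetric data errors out rather than being repaired silently.
#' @return a [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, symmetrize = FALSE) {
    v <- .readTsvMatrix(path)
    if (nrow(v) != ncol(v))
        stop(sprintf("similarity table must be square (%d x %d) in %s",
                     nrow(v), ncol(v), path), call. = FALSE)
    SimilarityMatrix(v, symmetrize = symmetrize)
}

#' Write chemoDTI matrices as labelled TSV
#'
#' `writeScores()` writes a [ScoreMatrix-class] (drugs as rows);
#' `writeInteractionMatrix()` and `writeSimilarityMatrix()` the analogous
#' tables.  Values are written with 17 significant digits so a read-back
#' reproduces the object to better than 1e-12.
#'
#' @param x the object to write.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeScores <- function(x, path) {
    stopifnot(is(x, "ScoreMatrix"))
    validObject(x)
    .writeTsvMatrix(values(x), path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) ScoreMatrix(.readTsvMatrix(path))

#' @rdname writeScores
#' @export
writeInteractionMatrix <- function(x, path) {
    stopifnot(is(x, "InteractionMatrix"))
    .writeTsvMatrix(values(x), path)
}

#' @rdname writeScores
#' @export
writeSimilarityMatrix <- function(x, path) {
    stopifnot(is(x, "SimilarityMatrix"))
    .writeTsvMatrix(values(x), path)
}

#' Serialize a MetricReport
#'
#' Writes the per-fold table as TSV (one row per fold plus a trailing
#' aggregate row) and, alongside it, a JSON document with the fold table
#' and the mean/SD aggregates.  `readMetricReport()` restores the object
#' from the JSON file.
#'
#' @param report a [MetricReport-class].
#' @param path destination TSV path; the JSON twin replaces the extension
#'   with `.json` (or appends it).
#' @return named character vector with the `tsv` and `json` paths,
#'   invisibly.
#' @export
writeMetricReport <- function(report, path) {
    stopifnot(is(report, "MetricReport"))
    validObject(report)
    f <- report@folds
    if (!nrow(f)) stop("empty MetricReport", call. = FALSE)
    s <- metricSummary(report)
    agg <- data.frame(repeat_ = NA_integer_, fold = NA_integer_,
                      n_heldout = sum(f$n_heldout), n_pos = sum(f$n_pos),
                      n_neg = sum(f$n_neg),
                      auc = s$mean[s$metric == "auc"],
                      aupr = s$mean[s$metric == "aupr"],
                      skipped = NA, reason = "aggregate-mean")
    out <- rbind(f, agg)
    con <- file(path, open = "wb")
    writeLines(c(paste(names(out), collapse = "\t"),
                 vapply(seq_len(nrow(out)), function(i)
                     paste(vapply(out[i, ], function(x)
                         if (is.numeric(x)) format(x, digits = 17,
                                                   trim = TRUE)
                         else as.character(x), character(1)),
                         collapse = "\t"), character(1))),
               con, sep = "\n")
    close(con)
    jsonPath <- sub("\\.[^.]*$", ".json", path)
    if (identical(jsonPath, path)) jsonPath <- paste0(path, ".json")
    jsonlite::write_json(
        list(setting = report@setting, method = report@method,
             folds = f, summary = s),
        jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(c(tsv = path, json = jsonPath))
}

#' @rdname writeMetricReport
#' @param jsonPath path to a JSON file written by [writeMetricReport()].
#' @export
readMetricReport <- function(jsonPath) {
    doc <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    f <- as.data.frame(doc$folds)
    f$reason <- as.character(f$reason)
    f$reason[is.na(f$reason)] <- ""
    f$skipped <- as.logical(f$skipped)
    f$auc <- as.numeric(f$auc)
    f$aupr <- as.numeric(f$aupr)
    new("MetricReport", setting = doc$setting, method = doc$method,
        folds = f)
}
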