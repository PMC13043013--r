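# Protein alignment wrappers around Biostrings::pairwiseAlignment.
# Convention: a gap of length L costs gapOpen + L * gapExt (affine),
# substitution scores from a named Biostrings matrix (default BLOSUM62,
# gap 11/1 — the classic protein-search working point).

.matrixCache <- new.env(parent = emptyenv())

#' Fetch a substitution matrix by name
#'
#' @param name matrix name shipped with Biostrings (e.g. `"BLOSUM62"`,
#'   `"BLOSUM45"`, `"PAM250"`).
#' @return numeric substitution matrix.
#' @export
substitutionMatrix <- function(name = "BLOSUM62") {
    if (!exists(name, envir = .matrixCache)) {
        e <- new.env()
        data(list = name, package = "Biostrings", envir = e)
        assign(name, get(name, envir = e), envir = .matrixCache)
    }
    get(name, envir = .matrixCache)
}

.alignmentResult <- function(score, identity, queryCov, querySpan, targetSpan,
                             alignedQuery, alignedTarget) {
    structure(
        list(score = score, identity = identity, queryCov = queryCov,
             querySpan = querySpan, targetSpan = targetSpan,
             alignedQuery = alignedQuery, alignedTarget = alignedTarget),
        class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
    cat(sprintf("AlignmentResult: score %g, identity %.3f, query_cov %.3f\n",
                x$score, x$identity, x$queryCov))
    cat(" query  ", x$alignedQuery, "\n target ", x$alignedTarget, "\n")
    invisible(x)
}

.emptyAlignment <- function() {
    .alignmentResult(0, 0, 0, c(NA_integer_, NA_integer_),
                     c(NA_integer_, NA_integer_), "", "")
}

.pwaToResult <- function(pwa, queryLen) {
    aq <- as.character(alignedPattern(pwa))
    at <- as.character(alignedSubject(pwa))
    ncol <- nchar(aq)
    ident <- if (ncol > 0) nmatch(pwa) / ncol else 0
    qs <- Biostrings::start(Biostrings::pattern(pwa))
    qe <- Biostrings::end(Biostrings::pattern(pwa))
    ts <- Biostrings::start(Biostrings::subject(pwa))
    te <- Biostrings::end(Biostrings::subject(pwa))
    qcov <- if (!is.na(qs) && qe >= qs) (qe - qs + 1) / queryLen else 0
    .alignmentResult(Biostrings::score(pwa), ident, qcov,
                     c(qs, qe), c(ts, te), aq, at)
}

.align <- function(query, target, type, matrix, gapOpen, gapExt) {
    if (!nzchar(query))
        stop("empty query sequence")
    if (!nzchar(target))
        stop("empty target sequence")
    mat <- substitutionMatrix(matrix)
    pwa <- pairwiseAlignment(Biostrings::AAString(query),
                             Biostrings::AAString(target),
                             type = type, substitutionMatrix = mat,
                             gapOpening = gapOpen, gapExtension = gapExt)
    .pwaToResult(pwa, nchar(query))
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Affine-gap local alignment; a gap of length L costs
#' `gapOpen + L * gapExt`. An alignment whose optimal score is not positive
#' is reported as empty (score 0, identity 0, coverage 0): a local
#' similarity that never rises above chance carries no signal.
#'
#' @param query,target protein strings (query = the reference protein whose
#'   coverage is reported).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExt affine gap penalties (positive costs; default 11/1).
#' @return an `AlignmentResult`: `score`, `identity` (fraction of matching
#'   columns over aligned columns including gaps), `queryCov` (aligned query
#'   span / query length), `querySpan`/`targetSpan` (1-based inclusive),
#'   `alignedQuery`/`alignedTarget` (gapped strings).
#' @examples
#' localAlign("MKWVT", "MKWVT")
#' @export
localAlign <- function(query, target, matrix = "BLOSUM62",
                       gapOpen = 11, gapExt = 1) {
    res <- .align(query, target, "local", matrix, gapOpen, gapExt)
    if (res$score <= 0)
        return(.emptyAlignment())
    res
}

#' Optimal global (Needleman-Wunsch) protein alignment
#'
#' Affine-gap global alignment with end gaps penalized; same scoring
#' convention as [localAlign()].
#'
#' @inheritParams localAlign
#' @return an `AlignmentResult` (see [localAlign()]); spans always cover the
#'   full sequences.
#' @export
globalAlign <- function(query, target, matrix = "BLOSUM62",
                        gapOpen = 11, gapExt = 1) {
    .align(query, target, "global", matrix, gapOpen, gapExt)
}

#' Recompute an alignment score from its gapped strings
#'
#' Independent rescoring of an alignment: substitution scores summed over
#' residue columns plus `-(gapOpen + L * gapExt)` per gap run. Used to
#' assert score consistency of reported alignments.
#'
#' @param alignedQuery,alignedTarget equal-length gapped strings.
#' @inheritParams localAlign
#' @return numeric score.
#' @export
rescoreAlignment <- function(alignedQuery, alignedTarget, matrix = "BLOSUM62",
                             gapOpen = 11, gapExt = 1) {
    if (nchar(alignedQuery) != nchar(alignedTarget))
        stop("gapped strings must have equal length")
    if (!nzchar(alignedQuery))
        return(0)
    mat <- substitutionMatrix(matrix)
    q <- strsplit(alignedQuery, "")[[1]]
    t <- strsplit(alignedTarget, "")[[1]]
    score <- 0
    inGapQ <- FALSE
    inGapT <- FALSE
    for (i in seq_along(q)) {
        if (q[i] == "-") {
            score <- score - gapExt - (if (inGapQ) 0 else gapOpen)
            inGapQ <- TRUE
            inGapT <- FALSE
        } else if (t[i] == "-") {
            score <- score - gapExt - (if (inGapT) 0 else gapOpen)
            inGapT <- TRUE
            inGapQ <- FALSE
        } else {
            score <- score + mat[q[i], t[i]]
            inGapQ <- FALSE
            inGapT <- FALSE
        }
    }
    score
}
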