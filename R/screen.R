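# Translated homology screen of MAG contigs against reference protein
# panels: every stop-to-stop ORF is aligned (Smith-Waterman, affine gaps)
# against every panel member; hits passing identity/coverage/score
# thresholds are dereplicated per gene family and become predicted gene
# features. This is the package's equivalent of a TBLASTN reference screen,
# made exact and deterministic by running full DP on called ORFs.

#' Read a reference protein panel
#'
#' Panel FASTA headers follow `<accession>|<gene_label>`; an optional
#' `subtree=<label>` tag in the description annotates rhodopsin references
#' (see [rhodopsinReferences()]).
#'
#' @param path protein FASTA path.
#' @return `AAStringSet` named by accession with `mcols` columns
#'   `accession`, `label` and (possibly `NA`) `subtree`.
#' @export
readPanel <- function(path) {
    aa <- readFasta(path, "protein")
    ids <- names(aa)
    if (!all(grepl("|", ids, fixed = TRUE)))
        stop("panel headers must follow <accession>|<gene_label>")
    acc <- sub("\\|.*$", "", ids)
    lab <- sub("^[^|]*\\|", "", ids)
    desc <- mcols(aa)$description
    subtree <- ifelse(grepl("subtree=", desc),
                      sub(".*subtree=(\\S+).*", "\\1", desc), NA_character_)
    names(aa) <- acc
    mcols(aa)$accession <- acc
    mcols(aa)$label <- lab
    mcols(aa)$subtree <- subtree
    aa
}

#' Combine reference panels
#'
#' Concatenates panels, dropping duplicate accessions (first occurrence
#' wins).
#'
#' @param ... `AAStringSet` panels from [readPanel()].
#' @return combined panel.
#' @export
combinePanels <- function(...) {
    panels <- list(...)
    out <- do.call(c, panels)
    keep <- !duplicated(mcols(out)$accession)
    out[keep]
}

.emptyHits <- function() {
    data.frame(magId = character(0), contigId = character(0),
               referenceId = character(0), geneLabel = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), score = numeric(0), identity = numeric(0),
               queryCov = numeric(0), orfProtein = character(0),
               stringsAsFactors = FALSE)
}

#' Screen a MAG against a reference protein panel
#'
#' Calls ORFs (>= `minAa` residues) on every contig, aligns each panel
#' protein locally against every ORF, and keeps hits with
#' `identity >= minIdentity` AND `queryCov >= minQueryCov` AND
#' `score >= minScore`. For each ORF only the best reference per gene
#' family is kept; overlapping hits to the same family on a contig are then
#' dereplicated keeping the best score.
#'
#' @param bin a [GenomeBin-class].
#' @param panel an `AAStringSet` from [readPanel()].
#' @param minIdentity minimum identity fraction (default 0.30).
#' @param minQueryCov minimum query (reference) coverage (default 0.50).
#' @param minScore minimum alignment score (default 60).
#' @param minAa minimum ORF length in residues (default 60).
#' @param matrix,gapOpen,gapExt alignment scoring (see [localAlign()]).
#' @return hit data.frame: `magId, contigId, referenceId, geneLabel, start,
#'   end, strand, frame, score, identity, queryCov, orfProtein`.
#'   Coordinates are the ORF's, 0-based half-open on the forward strand.
#' @export
screenGenome <- function(bin, panel, minIdentity = 0.30, minQueryCov = 0.50,
                         minScore = 60, minAa = 60L, matrix = "BLOSUM62",
                         gapOpen = 11, gapExt = 1) {
    if (length(panel) == 0L)
        stop("reference panel is empty")
    if (genomeSize(bin) == 0L) {
        warning("empty MAG: ", magId(bin))
        return(.emptyHits())
    }
    mat <- substitutionMatrix(matrix)
    ctgs <- contigs(bin)
    orfTabs <- lapply(seq_along(ctgs), function(i) {
        o <- callOrfs(as.character(ctgs[[i]]), minAa = minAa)
        if (nrow(o)) o$contigId <- names(ctgs)[i]
        o
    })
    orfs <- do.call(rbind, orfTabs[vapply(orfTabs, nrow, 1L) > 0])
    if (is.null(orfs) || nrow(orfs) == 0L)
        return(.emptyHits())
    orfSet <- AAStringSet(orfs$protein)
    hits <- vector("list", length(panel))
    for (p in seq_along(panel)) {
        ref <- panel[[p]]
        refLen <- length(ref)
        # fast score-only pass over all ORFs, full DP only on candidates
        sc <- pairwiseAlignment(orfSet, ref, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gapOpen, gapExtension = gapExt,
                                scoreOnly = TRUE)
        cand <- which(sc >= minScore)
        if (length(cand) == 0L)
            next
        rows <- lapply(cand, function(j) {
            aln <- localAlign(as.character(ref), orfs$protein[j],
                              matrix = matrix, gapOpen = gapOpen,
                              gapExt = gapExt)
            if (aln$score < minScore || aln$identity < minIdentity ||
                aln$queryCov < minQueryCov)
                return(NULL)
            data.frame(magId = magId(bin), contigId = orfs$contigId[j],
                       referenceId = mcols(panel)$accession[p],
                       geneLabel = mcols(panel)$label[p],
                       start = orfs$start[j], end = orfs$end[j],
                       strand = orfs$strand[j], frame = orfs$frame[j],
                       score = aln$score, identity = aln$identity,
                       queryCov = aln$queryCov,
                       orfProtein = orfs$protein[j],
                       stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows))
            hits[[p]] <- do.call(rbind, rows)
    }
    hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
    if (is.null(hits) || nrow(hits) == 0L)
        return(.emptyHits())
    .dereplicateHits(hits)
}

# keep the best reference per (family x ORF), then drop overlapping
# same-family hits on a contig keeping the best score
.dereplicateHits <- function(hits) {
    key <- paste(hits$geneLabel, hits$contigId, hits$start, hits$end,
                 hits$frame)
    hits <- hits[order(key, -hits$score), , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$geneLabel, hits$contigId, hits$start,
                                   hits$end, hits$frame)), , drop = FALSE]
    out <- list()
    for (grp in split(seq_len(nrow(hits)),
                      paste(hits$geneLabel, hits$contigId))) {
        sub <- hits[grp[order(-hits$score[grp])], , drop = FALSE]
        kept <- sub[0, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            overlaps <- nrow(kept) > 0 &&
                any(sub$start[i] < kept$end & sub$end[i] > kept$start)
            if (!overlaps)
                kept <- rbind(kept, sub[i, , drop = FALSE])
        }
        out[[length(out) + 1L]] <- kept
    }
    res <- do.call(rbind, out)
    res <- res[order(res$contigId, res$start, res$geneLabel), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Screen every MAG of a collection
#'
#' @param collection a [MagCollection-class].
#' @param panel reference panel (see [readPanel()]).
#' @param ... thresholds passed to [screenGenome()].
#' @return combined hit data.frame across MAGs.
#' @export
screenCollection <- function(collection, panel, ...) {
    tabs <- lapply(seq_len(length(collection)), function(i)
        screenGenome(collection[[i]], panel, ...))
    res <- do.call(rbind, tabs)
    if (is.null(res)) .emptyHits() else res
}

#' Convert hits to predicted gene features
#'
#' @param hits hit data.frame from [screenGenome()].
#' @return feature data.frame (`contigId, start, end, strand, label, source`)
#'   with `source = "predicted"` and an extra `magId` column.
#' @export
hitsToFeatures <- function(hits) {
    if (nrow(hits) == 0L) {
        f <- .emptyFeatures()
        f$magId <- character(0)
        return(f)
    }
    data.frame(contigId = hits$contigId, start = hits$start, end = hits$end,
               strand = hits$strand, label = hits$geneLabel,
               source = "predicted", magId = hits$magId,
               stringsAsFactors = FALSE)
}

#' Write hits as TSV
#'
#' @param hits hit data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
    out <- hits[, c("magId", "contigId", "referenceId", "geneLabel", "start",
                    "end", "strand", "frame", "score", "identity",
                    "queryCov")]
    colnames(out) <- c("mag_id", "contig_id", "reference_id", "gene_label",
                       "start", "end", "strand", "frame", "score",
                       "identity", "query_cov")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write hits as GFF3 predicted gene features
#'
#' @param hits hit data.frame.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeHitsGff <- function(hits, path) {
    writeGff(hitsToFeatures(hits), path)
}
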