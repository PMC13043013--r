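# Community metrics: the MAG quality filter, host-calibrated relative
# abundance (coverage as a percentage of the cyanobacterial host MAG's
# coverage in the same metagenome), commonality (in how many of the
# investigated microbiomes a taxon occurs), and rank-wise presence-absence
# matrices for external ordination.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

#' Filter MAGs by completeness and contamination
#'
#' Keeps MAGs with completeness strictly above 80% and contamination
#' strictly below 10% (both thresholds read literally as strict
#' inequalities; relax via the arguments). Removals are logged via
#' `message()`.
#'
#' @param qc QC data.frame from [readQcTable()].
#' @param collection a [MagCollection-class] (every MAG must have a QC row).
#' @param minCompleteness strict lower bound, percent (default 80).
#' @param maxContamination strict upper bound, percent (default 10).
#' @return the retained [MagCollection-class]; removed MAG ids in
#'   `attr(, "removed")`.
#' @export
filterMags <- function(qc, collection, minCompleteness = 80,
                       maxContamination = 10) {
    ids <- magIds(collection)
    miss <- setdiff(ids, qc$magId)
    if (length(miss))
        stop("no QC row for MAG(s): ", paste(miss, collapse = ", "))
    row <- qc[match(ids, qc$magId), ]
    keep <- row$completeness > minCompleteness &
        row$contamination < maxContamination
    removed <- ids[!keep]
    if (length(removed))
        message("filterMags: removed ", length(removed), " MAG(s): ",
                paste(removed, collapse = ", "))
    out <- collection[which(keep)]
    attr(out, "hostIds") <- intersect(hostMap(collection), ids[keep])
    attr(out, "removed") <- removed
    out
}

#' Host-calibrated relative abundance
#'
#' Per metagenome: coverage = mapped bases / genome size (fold), and
#' relative abundance = 100 x coverage / host coverage, so the host MAG is
#' 100% by construction and an associate at seventeen times the host's
#' coverage reports 1700%.
#'
#' @param coverage data.frame from [readCoverageTable()].
#' @param genomeSizes named numeric vector (bp) keyed by MAG id, or a
#'   [MagCollection-class] to derive sizes from.
#' @param hostIds character vector with one host MAG id per metagenome
#'   present in `coverage`.
#' @return `coverage` with added columns `genomeSize, coverage,
#'   relativeAbundance`.
#' @export
computeAbundance <- function(coverage, genomeSizes, hostIds) {
    if (is(genomeSizes, "MagCollection"))
        genomeSizes <- setNames(
            vapply(seq_len(length(genomeSizes)), function(i)
                genomeSize(genomeSizes[[i]]), numeric(1)),
            magIds(genomeSizes))
    gs <- genomeSizes[coverage$magId]
    if (any(is.na(gs)))
        stop("missing genome size for MAG(s): ",
             paste(coverage$magId[is.na(gs)], collapse = ", "))
    if (any(gs <= 0))
        stop("genome size must be positive")
    coverage$genomeSize <- as.numeric(gs)
    coverage$coverage <- coverage$mappedBases / coverage$genomeSize
    coverage$relativeAbundance <- NA_real_
    for (mg in unique(coverage$metagenomeId)) {
        sel <- coverage$metagenomeId == mg
        host <- intersect(hostIds, coverage$magId[sel])
        if (length(host) != 1L)
            stop("metagenome ", mg, " must have exactly one host MAG ",
                 "among its coverage rows")
        hc <- coverage$coverage[sel & coverage$magId == host]
        if (hc == 0)
            stop("host coverage is zero in metagenome ", mg)
        coverage$relativeAbundance[sel] <- 100 * coverage$coverage[sel] / hc
    }
    coverage
}

.lineageRank <- function(lineage, rank) {
    parts <- strsplit(lineage, ";", fixed = TRUE)
    bad <- lengths(parts) != length(.RANKS)
    if (any(bad))
        stop("malformed lineage string: ", lineage[bad][1])
    i <- match(rank, .RANKS)
    vapply(parts, `[[`, character(1), i)
}

#' Join taxonomy onto MAG metadata
#'
#' @param taxonomy data.frame from [readTaxonomyTable()].
#' @param collection a [MagCollection-class].
#' @return data.frame `magId, metagenomeId, lineage`; MAGs without an
#'   assignment get `unclassified_<mag_id>` at every rank.
#' @export
joinTaxonomy <- function(taxonomy, collection) {
    ids <- magIds(collection)
    lin <- taxonomy$lineage[match(ids, taxonomy$magId)]
    miss <- is.na(lin)
    lin[miss] <- vapply(ids[miss], function(m)
        paste(rep(paste0("unclassified_", m), length(.RANKS)),
              collapse = ";"), character(1))
    data.frame(magId = ids, metagenomeId = metagenomeIds(collection),
               lineage = lin, stringsAsFactors = FALSE)
}

#' Commonality of taxa across metagenomes
#'
#' For each taxon at the chosen rank, the number of distinct metagenomes in
#' which it occurs (a taxon counts once per metagenome regardless of how
#' many MAGs carry it). Sorted by count descending, then taxon name.
#'
#' @param assignments data.frame `magId, metagenomeId, lineage` (see
#'   [joinTaxonomy()]).
#' @param rank one of species, genus, family, order, class, phylum.
#' @return data.frame `taxon, count`.
#' @export
commonality <- function(assignments, rank = "species") {
    if (nrow(assignments) == 0L)
        return(data.frame(taxon = character(0), count = integer(0),
                          stringsAsFactors = FALSE))
    taxon <- .lineageRank(assignments$lineage, rank)
    u <- unique(data.frame(taxon = taxon,
                           metagenomeId = assignments$metagenomeId,
                           stringsAsFactors = FALSE))
    counts <- table(u$taxon)
    out <- data.frame(taxon = names(counts), count = as.integer(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$taxon), ]
    rownames(out) <- NULL
    out
}

#' Presence-absence matrix at a taxonomic rank
#'
#' Binary taxa x metagenome matrix; all-zero taxon rows are pruned by
#' construction, rows and columns are sorted for determinism. The matrix is
#' the export surface for external ordination of community composition.
#'
#' @inheritParams commonality
#' @return integer matrix (taxa in rows, metagenomes in columns).
#' @export
presenceMatrix <- function(assignments, rank = "species") {
    if (nrow(assignments) == 0L)
        return(matrix(integer(0), nrow = 0, ncol = 0))
    taxon <- .lineageRank(assignments$lineage, rank)
    taxa <- sort(unique(taxon))
    mgs <- sort(unique(assignments$metagenomeId))
    m <- matrix(0L, nrow = length(taxa), ncol = length(mgs),
                dimnames = list(taxa, mgs))
    m[cbind(match(taxon, taxa), match(assignments$metagenomeId, mgs))] <- 1L
    m
}

#' Write a presence-absence matrix as TSV
#'
#' @param m matrix from [presenceMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePresenceMatrix <- function(m, path) {
    df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
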