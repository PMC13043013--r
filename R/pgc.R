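# Photosynthesis gene cluster (PGC) inventory and synteny. Genes found in
# a MAG are numbered against an ordered reference cluster (D. shibae
# DFL 12-style symbols); completeness, contiguity and a signed gene-order
# vector are derived, and clusters are compared by signed adjacency
# breakpoints — the minimal well-defined rearrangement statistic for the
# inversion-style differences seen between PGCs.

#' The ordered reference PGC
#'
#' Loads the packaged ordered gene list of the reference photosynthesis
#' gene cluster (canonical Roseobacter-type layout keyed to D. shibae
#' DFL 12-style symbols; a constructed stand-in for the published cluster
#' table, user-replaceable). Classes: `bch` (bacteriochlorophyll
#' biosynthesis), `crt` (carotenoid biosynthesis), `puf` (light-harvesting /
#' reaction center), `cycA` (cytochrome c2), `other_conserved`.
#'
#' @param path optional path to a replacement TSV with columns
#'   `symbol  class  ref_index`.
#' @return data.frame `symbol, class, refIndex` in reference order.
#' @export
pgcReference <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "synthetic_pgc_reference.tsv",
                            package = "cyanophot", mustWork = TRUE)
    ref <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("symbol", "class", "ref_index")
    if (!all(need %in% colnames(ref)))
        stop("PGC reference must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(ref$symbol))
        stop("PGC reference symbols must be unique")
    ref <- ref[order(ref$ref_index), ]
    data.frame(symbol = ref$symbol, class = ref$class,
               refIndex = as.integer(ref$ref_index), stringsAsFactors = FALSE)
}

#' Build the PGC inventory of a MAG
#'
#' Restricts hits to reference PGC symbols, computes completeness (distinct
#' reference genes found / reference size), decides presence of a PGC
#' (pufL and pufM both found AND completeness at or above the floor),
#' contiguity (all PGC genes on one contig within the span limit), and the
#' signed order vector (reference indices in genomic order; negative on the
#' minus strand).
#'
#' @param hits hit data.frame (only rows whose `geneLabel` is a reference
#'   symbol are used; dereplicated per family).
#' @param bin the [GenomeBin-class] the hits belong to (identity check and
#'   empty-MAG handling); may be `NULL` when only the table is available.
#' @param reference ordered reference from [pgcReference()].
#' @param minCompleteness completeness floor for the PGC call (default 0.5).
#' @param maxSpanBp maximum genomic span for contiguity (default 80000;
#'   generous versus the ~45 kb canonical cluster size to tolerate island
#'   insertions).
#' @return a [PgcInventory-class].
#' @export
inventoryPgc <- function(hits, bin = NULL, reference = pgcReference(),
                         minCompleteness = 0.5, maxSpanBp = 80000) {
    mid <- if (!is.null(bin)) magId(bin) else unique(hits$magId)[1]
    if (is.na(mid)) mid <- "unknown"
    pg <- hits[hits$geneLabel %in% reference$symbol, , drop = FALSE]
    if (nrow(pg)) {
        # one gene per family: keep the best-scoring occurrence
        pg <- pg[order(-pg$score), , drop = FALSE]
        pg <- pg[!duplicated(pg$geneLabel), , drop = FALSE]
        pg <- pg[order(pg$contigId, pg$start), , drop = FALSE]
    }
    comp <- nrow(pg) / nrow(reference)
    has <- all(c("pufL", "pufM") %in% pg$geneLabel) && comp >= minCompleteness
    contig <- FALSE
    span <- list()
    if (nrow(pg) > 0 && length(unique(pg$contigId)) == 1L) {
        lo <- min(pg$start)
        hi <- max(pg$end)
        if (hi - lo <= maxSpanBp) {
            contig <- TRUE
            span <- list(contigId = pg$contigId[1], start = lo, end = hi)
        }
    }
    idx <- match(pg$geneLabel, reference$symbol)
    ov <- as.integer(ifelse(pg$strand == "+", idx, -idx))
    genes <- data.frame(symbol = pg$geneLabel,
                        class = reference$class[idx],
                        refIndex = reference$refIndex[idx],
                        contigId = pg$contigId, start = pg$start,
                        end = pg$end, strand = pg$strand,
                        stringsAsFactors = FALSE)
    new("PgcInventory", magId = mid, genes = genes, completeness = comp,
        hasPgc = has, contiguous = contig, span = span,
        orderVector = ov)
}

# signed adjacencies of a signed permutation, as a 2-column matrix
.signedAdjacencies <- function(v) {
    if (length(v) < 2L)
        return(matrix(integer(0), ncol = 2))
    cbind(v[-length(v)], v[-1L])
}

.adjacencyConserved <- function(adj, adjSet) {
    # (u,v) conserved if (u,v) or (-v,-u) occurs in adjSet
    any((adjSet[, 1] == adj[1] & adjSet[, 2] == adj[2]) |
        (adjSet[, 1] == -adj[2] & adjSet[, 2] == -adj[1]))
}

#' Compare two PGC inventories by signed synteny
#'
#' Restricts both clusters to their shared reference genes and counts
#' breakpoints: signed adjacencies of one order not conserved (directly or
#' as the reverse complement `(-v,-u)`) in the other. `blocks` is the
#' number of maximal conserved runs. Breakpoints are `NA` when no genes are
#' shared; `breakpoints == 0` iff the shared genes appear in identical
#' signed order (up to whole-cluster reflection).
#'
#' @param a,b [PgcInventory-class] objects.
#' @return list `(magIds, sharedGenes, breakpoints, blocks)`.
#' @export
syntenyCompare <- function(a, b) {
    va <- orderVector(a)
    vb <- orderVector(b)
    shared <- intersect(abs(va), abs(vb))
    va <- va[abs(va) %in% shared]
    vb <- vb[abs(vb) %in% shared]
    if (length(shared) == 0L)
        return(list(magIds = c(magId(a), magId(b)), sharedGenes = 0L,
                    breakpoints = NA_integer_, blocks = NA_integer_))
    adjA <- .signedAdjacencies(va)
    adjB <- .signedAdjacencies(vb)
    conserved <- if (nrow(adjA))
        vapply(seq_len(nrow(adjA)), function(i)
            .adjacencyConserved(adjA[i, ], adjB), logical(1))
    else logical(0)
    bp <- sum(!conserved)
    blocks <- length(shared) - sum(conserved)
    list(magIds = c(magId(a), magId(b)), sharedGenes = length(shared),
         breakpoints = as.integer(bp), blocks = as.integer(blocks))
}

#' Export plot-ready synteny data
#'
#' One row per located PGC gene of each inventory, carrying the class color
#' key and the reference index, ordered deterministically (MAG, contig,
#' start). Genes of a MAG that are not in the reference would be
#' `nonconserved`; inventories only contain reference genes, so the class
#' column takes values from the reference classes.
#'
#' @param inventories list of [PgcInventory-class] objects.
#' @return data.frame
#'   `magId, symbol, class, contigId, start, end, strand, refIndex`.
#' @export
exportSyntenyPlotData <- function(inventories) {
    if (is(inventories, "PgcInventory"))
        inventories <- list(inventories)
    rows <- lapply(inventories, function(inv) {
        g <- pgcGenes(inv)
        if (nrow(g) == 0L)
            return(NULL)
        cbind(data.frame(magId = magId(inv), stringsAsFactors = FALSE), g)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
        return(data.frame(magId = character(0), symbol = character(0),
                          class = character(0), contigId = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), refIndex = integer(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$magId, out$contigId, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a PGC inventory as TSV
#'
#' @param inventories list of [PgcInventory-class] (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePgcTsv <- function(inventories, path) {
    tab <- exportSyntenyPlotData(inventories)
    colnames(tab) <- c("mag_id", "symbol", "class", "contig", "start",
                       "end", "strand", "ref_index")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
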