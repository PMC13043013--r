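#' @rdname GenomeBin
#' @param object,x a `GenomeBin` or `MagCollection`.
#' @export
setGeneric("magId", function(object) standardGeneric("magId"))

#' @rdname GenomeBin
#' @export
setGeneric("metagenomeId", function(object) standardGeneric("metagenomeId"))

#' @rdname GenomeBin
#' @export
setGeneric("contigs", function(object) standardGeneric("contigs"))

#' @rdname GenomeBin
#' @export
setGeneric("genomeSize", function(object) standardGeneric("genomeSize"))

#' @rdname GenomeBin
#' @export
setGeneric("gcContent", function(object) standardGeneric("gcContent"))

#' @rdname MagCollection
#' @param object,x a `MagCollection`.
#' @export
setGeneric("magIds", function(object) standardGeneric("magIds"))

#' @rdname MagCollection
#' @export
setGeneric("metagenomeIds", function(object) standardGeneric("metagenomeIds"))

setMethod("magId", "GenomeBin", function(object) object@magId)
setMethod("metagenomeId", "GenomeBin", function(object) object@metagenomeId)
setMethod("contigs", "GenomeBin", function(object) object@contigs)

setMethod("genomeSize", "GenomeBin", function(object)
    sum(Biostrings::width(object@contigs)))

#' GC content of nucleotide sequences
#'
#' (G + C) / (A + C + G + T); `N` and other ambiguity codes are excluded
#' from the denominator. Returns `NaN` for a sequence with no unambiguous
#' bases.
#'
#' @param object a `GenomeBin` (pooled over contigs), `DNAStringSet`
#'   (per sequence), or character vector.
#' @return numeric fraction in `[0, 1]` (or `NaN`).
#' @export
#' @rdname gcContent
setMethod("gcContent", "GenomeBin", function(object) {
    af <- colSums(alphabetFrequency(object@contigs)[, c("A", "C", "G", "T"),
                                                    drop = FALSE])
    unname((af["G"] + af["C"]) / sum(af))
})

setMethod("gcContent", "DNAStringSet", function(object) {
    af <- alphabetFrequency(object)[, c("A", "C", "G", "T"), drop = FALSE]
    unname((af[, "G"] + af[, "C"]) / rowSums(af))
})

setMethod("gcContent", "character", function(object)
    gcContent(DNAStringSet(object)))

setMethod("show", "GenomeBin", function(object) {
    cat(sprintf("GenomeBin %s (metagenome %s): %d contig(s), %s bp, GC %.3f\n",
                object@magId, object@metagenomeId, length(object@contigs),
                format(genomeSize(object), big.mark = ","),
                gcContent(object)))
})

setMethod("magIds", "MagCollection", function(object)
    vapply(object@bins, magId, character(1)))

setMethod("metagenomeIds", "MagCollection", function(object)
    vapply(object@bins, metagenomeId, character(1)))

setMethod("length", "MagCollection", function(x) length(x@bins))

setMethod("[[", "MagCollection", function(x, i, ...) {
    if (is.character(i)) {
        j <- match(i, magIds(x))
        if (is.na(j))
            stop("no MAG with id '", i, "' in collection")
        i <- j
    }
    x@bins[[i]]
})

setMethod("[", "MagCollection", function(x, i, ...) {
    if (is.character(i))
        i <- match(i, magIds(x))
    MagCollection(x@bins[i])
})

setMethod("show", "MagCollection", function(object) {
    mg <- metagenomeIds(object)
    cat(sprintf("MagCollection: %d MAG(s) from %d metagenome(s)\n",
                length(object), length(unique(mg))))
    if (length(object))
        cat("  metagenomes:", paste(unique(mg), collapse = ", "), "\n")
})

setMethod("show", "PgcInventory", function(object) {
    cat(sprintf(
        "PgcInventory %s: %d gene(s), completeness %.2f, hasPgc=%s, contiguous=%s\n",
        object@magId, nrow(object@genes), object@completeness,
        object@hasPgc, object@contiguous))
})

#' @rdname PgcInventory
#' @param object a `PgcInventory`.
#' @export
setGeneric("completeness", function(object) standardGeneric("completeness"))

#' @rdname PgcInventory
#' @export
setGeneric("hasPgc", function(object) standardGeneric("hasPgc"))

#' @rdname PgcInventory
#' @export
setGeneric("orderVector", function(object) standardGeneric("orderVector"))

#' @rdname PgcInventory
#' @export
setGeneric("pgcGenes", function(object) standardGeneric("pgcGenes"))

setMethod("completeness", "PgcInventory", function(object) object@completeness)
setMethod("hasPgc", "PgcInventory", function(object) object@hasPgc)
setMethod("orderVector", "PgcInventory", function(object) object@orderVector)
setMethod("pgcGenes", "PgcInventory", function(object) object@genes)
setMethod("magId", "PgcInventory", function(object) object@magId)
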