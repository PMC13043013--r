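#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet readBStringSet
#'   writeXStringSet translate reverseComplement pairwiseAlignment
#'   alignedPattern alignedSubject nmatch getGeneticCode alphabetFrequency
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom stats rlnorm runif setNames
#' @importFrom utils read.delim write.table data
NULL

#' GenomeBin: one metagenome-assembled genome
#'
#' Container for a single MAG: its identifier, the metagenome (culture) it
#' was binned from, and its contigs as a [Biostrings::DNAStringSet].
#' Genome size and GC content are derived, not stored: `genomeSize()` is the
#' sum of contig lengths and `gcContent()` is (G+C)/(A+C+G+T) with ambiguous
#' bases excluded from the denominator.
#'
#' @slot magId single MAG identifier, e.g. `"E2-BRE-13"` (treated as opaque).
#' @slot metagenomeId identifier of the source culture/metagenome, e.g. `"BRE"`.
#' @slot contigs a `DNAStringSet` with unique, nonempty names.
#'
#' @aliases GenomeBin-class
#' @exportClass GenomeBin
setClass("GenomeBin",
    representation(
        magId = "character",
        metagenomeId = "character",
        contigs = "DNAStringSet"
    )
)

setValidity("GenomeBin", function(object) {
    msg <- character(0)
    if (length(object@magId) != 1L || !nzchar(object@magId))
        msg <- c(msg, "magId must be a single nonempty string")
    if (length(object@metagenomeId) != 1L || !nzchar(object@metagenomeId))
        msg <- c(msg, "metagenomeId must be a single nonempty string")
    if (length(object@contigs)) {
        nm <- names(object@contigs)
        if (is.null(nm) || any(!nzchar(nm)))
            msg <- c(msg, "every contig must be named")
        else if (anyDuplicated(nm))
            msg <- c(msg, "contig names must be unique")
        if (any(Biostrings::width(object@contigs) == 0L))
            msg <- c(msg, "contigs must have nonzero length")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeBin
#'
#' @param magId MAG identifier (single string).
#' @param metagenomeId metagenome/culture identifier.
#' @param contigs named `DNAStringSet` (or named character vector).
#' @return a [GenomeBin-class] object.
#' @examples
#' bin <- GenomeBin("M1", "CUL1", c(ctg1 = "ACGTACGT"))
#' genomeSize(bin)
#' @export
GenomeBin <- function(magId, metagenomeId, contigs) {
    if (is.character(contigs))
        contigs <- DNAStringSet(contigs)
    new("GenomeBin", magId = as.character(magId),
        metagenomeId = as.character(metagenomeId), contigs = contigs)
}

#' MagCollection: a set of MAGs grouped by metagenome
#'
#' Ordered list of [GenomeBin-class] objects with unique MAG identifiers.
#' Supports `length()`, `[[` (by index or MAG id), and `[` (subset, returning
#' a `MagCollection`).
#'
#' @slot bins list of `GenomeBin` objects.
#' @aliases MagCollection-class
#' @exportClass MagCollection
setClass("MagCollection", representation(bins = "list"))

setValidity("MagCollection", function(object) {
    ok <- vapply(object@bins, is, logical(1), class2 = "GenomeBin")
    if (!all(ok))
        return("all elements must be GenomeBin objects")
    ids <- vapply(object@bins, slot, character(1), name = "magId")
    if (anyDuplicated(ids))
        return(sprintf("duplicate magId: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    TRUE
})

#' Construct a MagCollection
#'
#' @param bins list of [GenomeBin-class] objects.
#' @return a [MagCollection-class].
#' @export
MagCollection <- function(bins = list()) {
    new("MagCollection", bins = unname(bins))
}

#' PgcInventory: photosynthesis-gene-cluster inventory of one MAG
#'
#' Records which reference PGC genes were found in a MAG, the completeness
#' relative to the ordered reference cluster, whether the cluster is
#' contiguous (single contig, bounded span), and the signed gene-order
#' vector used for synteny comparison (reference indices in genomic order,
#' negative on the minus strand).
#'
#' @slot magId MAG identifier.
#' @slot genes data.frame of located PGC genes
#'   (`symbol, class, refIndex, contigId, start, end, strand`).
#' @slot completeness fraction of reference genes found, in `[0, 1]`.
#' @slot hasPgc logical: pufL and pufM present and completeness above floor.
#' @slot contiguous logical: all genes on one contig within the span limit.
#' @slot span list `(contigId, start, end)` or empty when not contiguous.
#' @slot orderVector signed integer vector of reference indices.
#' @aliases PgcInventory-class
#' @exportClass PgcInventory
setClass("PgcInventory",
    representation(
        magId = "character",
        genes = "data.frame",
        completeness = "numeric",
        hasPgc = "logical",
        contiguous = "logical",
        span = "list",
        orderVector = "integer"
    )
)

setValidity("PgcInventory", function(object) {
    msg <- character(0)
    if (object@completeness < 0 || object@completeness > 1)
        msg <- c(msg, "completeness must lie in [0, 1]")
    if (length(object@orderVector) != nrow(object@genes))
        msg <- c(msg, "orderVector length must equal number of genes found")
    if (object@contiguous && nrow(object@genes) > 0 &&
        length(unique(object@genes$contigId)) != 1L)
        msg <- c(msg, "contiguous inventory must lie on a single contig")
    if (length(msg)) msg else TRUE
})
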