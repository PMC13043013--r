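# External formats: FASTA (Biostrings), GFF3 (rtracklayer), TSV tables.
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based inclusive convention happens only at the GFF boundary.

.NUC_ALPHABET <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K",
                   "M", "B", "D", "H", "V")
.AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.PROT_ALPHABET <- c(.AA_ALPHABET20, "X", "*")

#' Read a FASTA file with validation
#'
#' Reads nucleotide or protein FASTA. Sequences are uppercased; for
#' nucleotide input, `U` is mapped to `T`. Sequence ids (the first
#' whitespace-delimited token of the header) must be unique; the remainder
#' of the header is kept as `mcols(x)$description`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; empty
#'   (with a warning) for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fna")
#' writeLines(c(">a some contig", "acgu"), f)
#' readFasta(f, "nucleotide")
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- readBStringSet(path)
    if (length(raw) == 0L) {
        warning("empty FASTA file: ", path)
        return(if (alphabet == "nucleotide") DNAStringSet() else AAStringSet())
    }
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(ids)))
        stop("FASTA header with empty id in ", path)
    if (anyDuplicated(ids))
        stop("duplicate FASTA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    if (any(!nzchar(seqs)))
        stop("empty sequence for id(s): ",
             paste(ids[!nzchar(seqs)], collapse = ", "))
    legal <- if (alphabet == "nucleotide") .NUC_ALPHABET else .PROT_ALPHABET
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[[i]], "")[[1]]
        bad <- which(!ch %in% legal)
        if (length(bad))
            stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                         ch[bad[1]], bad[1], ids[i]))
    }
    if (alphabet == "nucleotide") {
        seqs <- gsub("U", "T", seqs, fixed = TRUE)
        out <- DNAStringSet(seqs)
    } else {
        out <- AAStringSet(seqs)
    }
    names(out) <- ids
    mcols(out)$description <- desc
    out
}

#' Write sequences as FASTA
#'
#' @param x a named `XStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x))
        x <- Biostrings::BStringSet(x)
    writeXStringSet(x, path)
    invisible(path)
}

# canonical empty feature table
.emptyFeatures <- function() {
    data.frame(contigId = character(0), start = integer(0), end = integer(0),
               strand = character(0), label = character(0),
               source = character(0), stringsAsFactors = FALSE)
}

#' Read gene features from GFF3
#'
#' Coordinates are converted from GFF's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. The gene-family symbol is
#' taken from the `geneKey` attribute (default `"gene"`), falling back to
#' `"Name"`, else `"unknown"`.
#'
#' @param path path to a GFF3 file.
#' @param geneKey attribute key holding the gene symbol.
#' @return data.frame with columns
#'   `contigId, start, end, strand, label, source`.
#' @export
readGff <- function(path, geneKey = "gene") {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) == 0L)
        return(.emptyFeatures())
    for (i in keep) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 8L)
            stop(sprintf("malformed GFF row at line %d: fewer than 8 fields", i))
        s <- suppressWarnings(as.integer(f[4]))
        e <- suppressWarnings(as.integer(f[5]))
        if (is.na(s) || is.na(e))
            stop(sprintf("non-numeric coordinates at line %d", i))
        if (e < s)
            stop(sprintf("end < start at line %d", i))
        if (!f[7] %in% c("+", "-"))
            stop(sprintf("strand required at line %d", i))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0L)
        return(.emptyFeatures())
    lab <- rep(NA_character_, length(gr))
    m <- S4Vectors::mcols(gr)
    if (geneKey %in% colnames(m))
        lab <- as.character(m[[geneKey]])
    if ("Name" %in% colnames(m))
        lab <- ifelse(is.na(lab), as.character(m$Name), lab)
    lab[is.na(lab)] <- "unknown"
    data.frame(
        contigId = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        label = lab,
        source = "annotated",
        stringsAsFactors = FALSE)
}

#' Write gene features as GFF3
#'
#' Inverse of [readGff()]: internal 0-based half-open coordinates are
#' written 1-based inclusive. Round-trips coordinates bit-exactly.
#'
#' @param features feature data.frame (see [readGff()]).
#' @param path output path.
#' @param source value for the GFF source column.
#' @return `path`, invisibly.
#' @export
writeGff <- function(features, path, source = "cyanophot") {
    if (nrow(features) == 0L) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = features$contigId,
        ranges = IRanges::IRanges(start = features$start + 1L,
                                  end = features$end),
        strand = features$strand)
    n <- nrow(features)
    S4Vectors::mcols(gr)$source <- rep(source, n)
    S4Vectors::mcols(gr)$type <- rep("gene", n)
    S4Vectors::mcols(gr)$gene <- features$label
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Load a MAG collection from a manifest
#'
#' The manifest is a TSV with header `mag_id  metagenome_id  fasta_path`
#' (one nucleotide FASTA per MAG; relative paths are resolved against the
#' manifest's directory). An optional `is_host` column (0/1 or TRUE/FALSE)
#' flags the cyanobacterial host MAG of each metagenome and is returned as
#' a per-bin attribute via [hostMap()].
#'
#' @param manifestPath path to the manifest TSV.
#' @return a [MagCollection-class]; host flags (if present) in
#'   `metadata`-style attribute `hostIds`.
#' @export
loadCollection <- function(manifestPath) {
    man <- read.delim(manifestPath, stringsAsFactors = FALSE)
    need <- c("mag_id", "metagenome_id", "fasta_path")
    if (!all(need %in% colnames(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    base <- dirname(normalizePath(manifestPath))
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$fasta_path),
                    man$fasta_path, file.path(base, man$fasta_path))
    missing <- !file.exists(paths)
    if (any(missing))
        stop("missing FASTA for MAG(s): ",
             paste(man$mag_id[missing], collapse = ", "))
    bins <- lapply(seq_len(nrow(man)), function(i) {
        GenomeBin(man$mag_id[i], man$metagenome_id[i],
                  readFasta(paths[i], "nucleotide"))
    })
    coll <- MagCollection(bins)
    if ("is_host" %in% colnames(man)) {
        hostIds <- man$mag_id[as.logical(as.integer(man$is_host))]
        attr(coll, "hostIds") <- hostIds
    }
    coll
}

#' Host MAG ids of a collection
#'
#' @param collection a [MagCollection-class] loaded via [loadCollection()].
#' @return character vector of MAG ids flagged as hosts (may be empty).
#' @export
hostMap <- function(collection) {
    h <- attr(collection, "hostIds")
    if (is.null(h)) character(0) else h
}

#' Read the MAG quality-control table
#'
#' TSV with header `mag_id  completeness  contamination` (percent units).
#'
#' @param path path to the QC TSV.
#' @return data.frame `magId, completeness, contamination`.
#' @export
readQcTable <- function(path) {
    qc <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("mag_id", "completeness", "contamination")
    if (!all(need %in% colnames(qc)))
        stop("QC table must have columns: ", paste(need, collapse = ", "))
    if (any(qc$completeness < 0 | qc$completeness > 100))
        stop("completeness must lie in [0, 100]")
    if (any(qc$contamination < 0))
        stop("contamination must be >= 0")
    data.frame(magId = qc$mag_id, completeness = qc$completeness,
               contamination = qc$contamination, stringsAsFactors = FALSE)
}

#' Read the coverage table
#'
#' TSV with header `mag_id  metagenome_id  mapped_bases`.
#'
#' @param path path to the coverage TSV.
#' @return data.frame `magId, metagenomeId, mappedBases`.
#' @export
readCoverageTable <- function(path) {
    cv <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("mag_id", "metagenome_id", "mapped_bases")
    if (!all(need %in% colnames(cv)))
        stop("coverage table must have columns: ", paste(need, collapse = ", "))
    data.frame(magId = cv$mag_id, metagenomeId = cv$metagenome_id,
               mappedBases = as.numeric(cv$mapped_bases),
               stringsAsFactors = FALSE)
}

#' Read the taxonomy table
#'
#' TSV with header `mag_id  lineage`, where `lineage` is a semicolon-
#' separated seven-rank string `domain;phylum;class;order;family;genus;species`.
#'
#' @param path path to the taxonomy TSV.
#' @return data.frame `magId, lineage`.
#' @export
readTaxonomyTable <- function(path) {
    tx <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("mag_id", "lineage")
    if (!all(need %in% colnames(tx)))
        stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
    data.frame(magId = tx$mag_id, lineage = tx$lineage,
               stringsAsFactors = FALSE)
}
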