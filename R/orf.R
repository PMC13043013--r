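# Six-frame translation and stop-to-stop ORF calling: the substrate of the
# translated homology screen. Coordinates are 0-based half-open on the
# forward strand; frames are {1,2,3,-1,-2,-3}, negative frames translating
# the reverse complement.

.GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

.translateFrame <- function(dna, offset) {
    # offset in 0..2; returns AA string of the complete codons of that frame
    n <- nchar(dna)
    usable <- ((n - offset) %/% 3L) * 3L
    if (usable < 3L)
        return("")
    sub <- substr(dna, offset + 1L, offset + usable)
    # the fuzzy-codon path rebuilds an ambiguity code table per call; only
    # take it when ambiguity codes are actually present
    fuzzy <- if (grepl("[^ACGT]", sub)) "X" else "error"
    as.character(translate(DNAStringSet(sub),
                           genetic.code = .GENETIC_CODE_11,
                           no.init.codon = TRUE,      # plain frame, no start-codon M
                           if.fuzzy.codon = fuzzy))
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard bacterial genetic code (translation table 11); stop codons are
#' rendered `*`. Frames `-1..-3` translate the reverse complement. Frames
#' too short for a complete codon yield an empty string.
#'
#' @param seq a nucleotide string, `DNAString`, or length-1 `DNAStringSet`.
#' @return named character vector of six protein strings, names
#'   `"1","2","3","-1","-2","-3"`.
#' @examples
#' sixFrameTranslate("ATGAAA")
#' @export
sixFrameTranslate <- function(seq) {
    seq <- .asDnaString(seq)
    rc <- as.character(reverseComplement(DNAStringSet(seq)))
    fwd <- vapply(0:2, function(o) .translateFrame(seq, o), character(1))
    rev <- vapply(0:2, function(o) .translateFrame(rc, o), character(1))
    setNames(c(fwd, rev), c("1", "2", "3", "-1", "-2", "-3"))
}

.asDnaString <- function(seq) {
    if (is.character(seq))
        return(toupper(seq))
    as.character(seq)
}

.emptyOrfs <- function() {
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), protein = character(0),
               stringsAsFactors = FALSE)
}

#' Call open reading frames in all six frames
#'
#' Maximal stop-to-stop ORFs of at least `minAa` residues. Contig ends are
#' treated as open: a terminal stop codon is not required. Coordinates are
#' reported 0-based half-open on the forward strand and cover exactly the
#' codons of the reported protein, so `(end - start) == 3 * nchar(protein)`.
#' The stop codon itself is never part of the interval or the protein.
#'
#' @param seq nucleotide string.
#' @param minAa minimum protein length in residues (default 60).
#' @return data.frame `start, end, strand, frame, protein`.
#' @examples
#' callOrfs("ATGAAATAA", minAa = 2)
#' @export
callOrfs <- function(seq, minAa = 60L) {
    stopifnot(minAa >= 1L)
    seq <- .asDnaString(seq)
    n <- nchar(seq)
    prots <- sixFrameTranslate(seq)
    out <- vector("list", 6L)
    frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
    for (k in seq_along(frames)) {
        fr <- frames[k]
        aa <- prots[[k]]
        if (!nzchar(aa)) {
            out[[k]] <- .emptyOrfs()
            next
        }
        offset <- abs(fr) - 1L
        # split the frame translation on stops, tracking codon offsets
        pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
        if (length(pieces) == 0L)
            pieces <- ""
        lens <- nchar(pieces)
        codonStart <- cumsum(c(0L, lens + 1L))[seq_along(pieces)]
        keep <- which(lens >= minAa)
        if (length(keep) == 0L) {
            out[[k]] <- .emptyOrfs()
            next
        }
        ntStart <- offset + 3L * codonStart[keep]        # frame-local coords
        ntEnd <- ntStart + 3L * lens[keep]
        if (fr > 0L) {
            s <- ntStart
            e <- ntEnd
        } else {
            # reflect from reverse-complement coordinates to forward strand
            s <- n - ntEnd
            e <- n - ntStart
        }
        out[[k]] <- data.frame(start = as.integer(s), end = as.integer(e),
                               strand = if (fr > 0L) "+" else "-",
                               frame = fr, protein = pieces[keep],
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res[order(res$start, res$end, res$frame), , drop = FALSE] -> res
    rownames(res) <- NULL
    res
}
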