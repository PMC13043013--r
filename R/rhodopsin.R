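# Rhodopsin classification: subtree assignment by nearest labeled
# reference, diagnostic residues read off an anchor-relative numbering
# (D-85/T-89/E-96 proton-transfer triad, G-156 antenna glycine, K-292
# retinal-binding lysine), operon context (brp/blh dioxygenase and crt
# carotenoid genes), and the functional call: bona fide light-driven proton
# pump, candidate pump, Na-pump excluded (NDQ motif), or divergent/unknown.

.DIAGNOSTIC_POSITIONS <- c(res85 = 85L, res89 = 89L, res96 = 96L,
                           res156 = 156L, resK = 292L)

#' Shipped rhodopsin reference set
#'
#' Loads the packaged rhodopsin reference panel: one anchor/reference per
#' phylogenetic subtree (I = proteorhodopsin/Bacteroidota-type,
#' II = proteorhodopsin incl. the E. sibiricum branch,
#' III = xanthorhodopsin), plus the brp/blh dioxygenase and crt carotenoid
#' references used for operon context. The shipped sequences are synthetic
#' stand-ins constructed to carry the canonical diagnostic residues at the
#' anchor positions; substitute real references via `path`.
#'
#' @param path optional path to a replacement panel FASTA
#'   (headers `<accession>|<label>`, rhodopsins tagged `subtree=<I|II|III>`).
#' @return `AAStringSet` panel (see [readPanel()]).
#' @export
rhodopsinReferences <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "synthetic_rhodopsin_panel.faa",
                            package = "cyanophot", mustWork = TRUE)
    readPanel(path)
}

#' Map anchor positions onto a hit protein
#'
#' Globally aligns the hit against the anchor; every 1-based anchor
#' position maps either to a (position, residue) in the hit or to `NA` when
#' the anchor column aligns to a gap. Diagnostic positions are thereby
#' anchor-relative, making the numbering scheme explicit.
#'
#' @param hitProtein protein string of the rhodopsin hit.
#' @param anchor protein string of the anchor reference.
#' @param minIdentity identity floor below which the mapping is refused
#'   (default 0.15).
#' @param ... scoring arguments for [globalAlign()].
#' @return data.frame `anchorPos, hitPos, hitRes` with one row per anchor
#'   position; `hitPos` strictly increasing over non-`NA` rows.
#' @export
anchorMap <- function(hitProtein, anchor, minIdentity = 0.15, ...) {
    if (!nzchar(hitProtein) || !nzchar(anchor))
        stop("empty protein for anchor mapping")
    aln <- globalAlign(hitProtein, anchor, ...)
    if (aln$identity < minIdentity)
        stop("anchor mapping unreliable (identity ",
             sprintf("%.2f", aln$identity), " < ", minIdentity, ")")
    q <- strsplit(aln$alignedQuery, "")[[1]]    # hit
    t <- strsplit(aln$alignedTarget, "")[[1]]   # anchor
    anchorLen <- nchar(anchor)
    hitPos <- rep(NA_integer_, anchorLen)
    hitRes <- rep(NA_character_, anchorLen)
    qi <- 0L
    ti <- 0L
    for (col in seq_along(q)) {
        if (q[col] != "-") qi <- qi + 1L
        if (t[col] != "-") {
            ti <- ti + 1L
            if (q[col] != "-") {
                hitPos[ti] <- qi
                hitRes[ti] <- q[col]
            }
        }
    }
    data.frame(anchorPos = seq_len(anchorLen), hitPos = hitPos,
               hitRes = hitRes, stringsAsFactors = FALSE)
}

#' Extract the diagnostic residue profile
#'
#' Reads residues at the configured anchor positions and derives the
#' diagnostic flags: `hasDTE` (D-85, T-89, E-96), `hasRetinalK` (K-292),
#' `hasG156`, and `naPumpMotif` (N-85, D-89, Q-96, the Na-pump signature).
#' A position mapping to a gap yields `NA` and a `FALSE` flag.
#'
#' @param map residue map from [anchorMap()].
#' @param positions named integer vector of anchor positions
#'   (default `c(res85=85, res89=89, res96=96, res156=156, resK=292)`).
#' @return one-row data.frame `res85, res89, res96, res156, resK, hasDTE,
#'   hasRetinalK, hasG156, naPumpMotif`.
#' @export
extractProfile <- function(map, positions = .DIAGNOSTIC_POSITIONS) {
    getRes <- function(p) {
        if (p > nrow(map)) NA_character_ else map$hitRes[p]
    }
    r <- vapply(positions, getRes, character(1))
    eq <- function(a, b) !is.na(a) & a == b
    data.frame(
        res85 = r[["res85"]], res89 = r[["res89"]], res96 = r[["res96"]],
        res156 = r[["res156"]], resK = r[["resK"]],
        hasDTE = eq(r[["res85"]], "D") && eq(r[["res89"]], "T") &&
                 eq(r[["res96"]], "E"),
        hasRetinalK = eq(r[["resK"]], "K"),
        hasG156 = eq(r[["res156"]], "G"),
        naPumpMotif = eq(r[["res85"]], "N") && eq(r[["res89"]], "D") &&
                      eq(r[["res96"]], "Q"),
        stringsAsFactors = FALSE)
}

#' Assign a rhodopsin to a phylogenetic subtree by nearest reference
#'
#' Globally aligns the hit against every labeled rhodopsin reference and
#' returns the label of the best-scoring one. The margin is the score gap
#' to the best reference of a different label; a margin below 5% of the
#' best score raises a low-confidence flag (guards chimeric or ambiguous
#' sequences). This replaces tree inference with a deterministic
#' nearest-reference rule.
#'
#' @param hitProtein protein string.
#' @param references rhodopsin references with `mcols(references)$subtree`
#'   labels (see [rhodopsinReferences()]); non-rhodopsin panel members
#'   (`NA` subtree) are ignored.
#' @param marginFrac low-confidence threshold as a fraction of the best
#'   score (default 0.05).
#' @param ... scoring arguments for [globalAlign()].
#' @return list `(subtree, margin, lowConfidence, bestReference)`.
#' @export
assignSubtree <- function(hitProtein, references, marginFrac = 0.05, ...) {
    sub <- references[!is.na(mcols(references)$subtree)]
    if (length(sub) == 0L)
        stop("reference panel contains no subtree-labeled rhodopsins")
    labels <- mcols(sub)$subtree
    scores <- vapply(seq_along(sub), function(i)
        globalAlign(hitProtein, as.character(sub[[i]]), ...)$score,
        numeric(1))
    best <- which.max(scores)
    other <- which(labels != labels[best])
    margin <- if (length(other))
        scores[best] - max(scores[other]) else Inf
    lowConf <- is.finite(margin) && margin < marginFrac * abs(scores[best])
    list(subtree = labels[best], margin = margin, lowConfidence = lowConf,
         bestReference = mcols(sub)$accession[best])
}

#' Operon context of a rhodopsin gene
#'
#' Neighbors are all features on the same contig within `windowBp` of the
#' hit (any strand). `brpBlhAdjacent` requires a `brp_blh` neighbor;
#' `brpBlhInGenome` searches the full MAG feature set (any contig) —
#' mirroring the genome-wide retinal-biosynthesis requirement. `crtGenes`
#' collects crtE/crtB/crtI/crtY neighbors.
#'
#' @param hitFeature one-row feature data.frame for the rhodopsin gene.
#' @param features all features of the MAG (must include the hit itself).
#' @param windowBp adjacency window in bp (default 5000).
#' @param profile diagnostic profile of the hit (for the Na-pump motif).
#' @return list `(neighbors, brpBlhAdjacent, brpBlhInGenome, crtGenes,
#'   naPumpMotif)`.
#' @export
operonContext <- function(hitFeature, features, windowBp = 5000,
                          profile = NULL) {
    same <- features$contigId == hitFeature$contigId &
        features$start == hitFeature$start &
        features$end == hitFeature$end
    if (!any(same))
        stop("hit feature not present in the MAG feature set")
    onContig <- features$contigId == hitFeature$contigId
    near <- onContig &
        features$start < hitFeature$end + windowBp &
        features$end > hitFeature$start - windowBp
    neighbors <- features[near & !same, , drop = FALSE]
    crt <- intersect(unique(neighbors$label),
                     c("crtE", "crtB", "crtI", "crtY"))
    list(neighbors = neighbors,
         brpBlhAdjacent = "brp_blh" %in% neighbors$label,
         brpBlhInGenome = "brp_blh" %in% features$label[!same],
         crtGenes = crt,
         naPumpMotif = if (is.null(profile)) FALSE else profile$naPumpMotif)
}

#' Functional call for a rhodopsin
#'
#' Decision rule: the NDQ motif excludes the protein as a Na-pump; a
#' missing retinal-binding lysine marks it divergent/unknown; otherwise a
#' subtree-assigned rhodopsin with a brp/blh gene anywhere in the genome is
#' a bona fide light-driven proton pump, else a candidate pump. Divergence
#' at position 96 alone does not disqualify (the E. sibiricum-type branch
#' pumps protons without E-96). A carotenoid antenna is predicted when
#' G-156 is present and the subtree is I or III.
#'
#' @param subtree subtree label (`"I"`, `"II"`, `"III"`) or `NA`.
#' @param profile one-row profile from [extractProfile()].
#' @param context list from [operonContext()].
#' @return list `(call, antenna)` with
#'   `call` in `{bona_fide_pump, candidate_pump, na_pump_excluded,
#'   divergent_unknown}`.
#' @export
callRhodopsinFunction <- function(subtree, profile, context) {
    call <- if (isTRUE(context$naPumpMotif)) {
        "na_pump_excluded"
    } else if (!isTRUE(profile$hasRetinalK)) {
        "divergent_unknown"
    } else if (!is.na(subtree) && isTRUE(context$brpBlhInGenome)) {
        "bona_fide_pump"
    } else {
        "candidate_pump"
    }
    antenna <- isTRUE(profile$hasG156) && !is.na(subtree) &&
        subtree %in% c("I", "III")
    list(call = call, antenna = antenna)
}

.emptyRhodopsinRecords <- function() {
    data.frame(magId = character(0), contigId = character(0),
               referenceId = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               subtree = character(0), margin = numeric(0),
               lowConfidence = logical(0), res85 = character(0),
               res89 = character(0), res96 = character(0),
               res156 = character(0), resK = character(0),
               hasDTE = logical(0), hasG156 = logical(0),
               hasRetinalK = logical(0), naPumpMotif = logical(0),
               brpBlhAdjacent = logical(0), brpBlhInGenome = logical(0),
               crtGenes = character(0), call = character(0),
               antenna = logical(0), stringsAsFactors = FALSE)
}

#' Classify all rhodopsin hits of a MAG collection
#'
#' Drives [assignSubtree()], [anchorMap()]/[extractProfile()] (against the
#' assigned subtree's own anchor), [operonContext()] and
#' [callRhodopsinFunction()] for every hit labeled `rhodopsin`.
#'
#' @param hits hit data.frame from [screenCollection()] (any labels; only
#'   `rhodopsin` rows are classified, all rows provide operon context).
#' @param references rhodopsin reference panel ([rhodopsinReferences()]).
#' @param windowBp operon adjacency window (default 5000).
#' @param positions diagnostic anchor positions (see [extractProfile()]).
#' @param ... scoring arguments passed to the alignment steps.
#' @return one row per rhodopsin hit: identity of the hit, subtree +
#'   margin, observed diagnostic residues and flags, operon context, the
#'   functional call and the antenna prediction.
#' @export
classifyRhodopsins <- function(hits, references = rhodopsinReferences(),
                               windowBp = 5000,
                               positions = .DIAGNOSTIC_POSITIONS, ...) {
    rh <- which(hits$geneLabel == "rhodopsin")
    if (length(rh) == 0L)
        return(.emptyRhodopsinRecords())
    feats <- hitsToFeatures(hits)
    out <- vector("list", length(rh))
    for (k in seq_along(rh)) {
        i <- rh[k]
        prot <- hits$orfProtein[i]
        st <- assignSubtree(prot, references, ...)
        anchorSeq <- as.character(
            references[!is.na(mcols(references)$subtree) &
                       mcols(references)$subtree == st$subtree][[1]])
        profile <- tryCatch({
            m <- anchorMap(prot, anchorSeq, ...)
            extractProfile(m, positions)
        }, error = function(e) {
            p <- extractProfile(data.frame(anchorPos = integer(0),
                                           hitPos = integer(0),
                                           hitRes = character(0)), positions)
            p
        })
        magFeats <- feats[feats$magId == hits$magId[i], , drop = FALSE]
        hitFeat <- data.frame(contigId = hits$contigId[i],
                              start = hits$start[i], end = hits$end[i],
                              strand = hits$strand[i],
                              label = "rhodopsin", source = "predicted",
                              stringsAsFactors = FALSE)
        ctx <- operonContext(hitFeat, magFeats, windowBp, profile)
        fc <- callRhodopsinFunction(st$subtree, profile, ctx)
        out[[k]] <- data.frame(
            magId = hits$magId[i], contigId = hits$contigId[i],
            referenceId = hits$referenceId[i], start = hits$start[i],
            end = hits$end[i], strand = hits$strand[i],
            subtree = st$subtree, margin = st$margin,
            lowConfidence = st$lowConfidence,
            res85 = profile$res85, res89 = profile$res89,
            res96 = profile$res96, res156 = profile$res156,
            resK = profile$resK, hasDTE = profile$hasDTE,
            hasG156 = profile$hasG156, hasRetinalK = profile$hasRetinalK,
            naPumpMotif = profile$naPumpMotif,
            brpBlhAdjacent = ctx$brpBlhAdjacent,
            brpBlhInGenome = ctx$brpBlhInGenome,
            crtGenes = paste(ctx$crtGenes, collapse = ","),
            call = fc$call, antenna = fc$antenna,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write rhodopsin records as TSV
#'
#' @param records data.frame from [classifyRhodopsins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRhodopsinTsv <- function(records, path) {
    out <- records[, c("magId", "contigId", "referenceId", "subtree",
                       "res85", "res89", "res96", "res156", "resK", "call",
                       "antenna", "brpBlhAdjacent", "brpBlhInGenome",
                       "crtGenes")]
    colnames(out) <- c("mag_id", "contig_id", "reference_id", "subtree",
                       "res85", "res89", "res96", "res156", "resK", "call",
                       "antenna", "brp_blh_adjacent", "brp_blh_in_genome",
                       "crt_genes")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
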