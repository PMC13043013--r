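# Aggregation of PGC and rhodopsin evidence into one phototrophy call per
# MAG, plus the collection-level Venn summary (how many MAGs carry a PGC,
# a proton-pumping rhodopsin, or both — dual phototrophy).

#' Phototrophy call for one MAG
#'
#' Modes: `cyano_oxygenic` (reserved for MAGs flagged as the cyanobacterial
#' host), `dual` (PGC plus a bona fide pump or a xanthorhodopsin operon),
#' `pgc_only`, `rhodopsin_only` (at least one bona fide or candidate pump,
#' no PGC), `none`. The xanthorhodopsin-operon flag (`xrOperon`) records a
#' subtree-III rhodopsin with an adjacent brp/blh gene and is kept separate
#' because observed dual phototrophs are xanthorhodopsin-bearing.
#'
#' @param magId MAG identifier.
#' @param pgcInventory a [PgcInventory-class] for the MAG (or `NULL`).
#' @param rhodopsinRecords rhodopsin records of the MAG (possibly 0 rows).
#' @param isHost logical: is this the flagged host MAG.
#' @return one-row data.frame
#'   `magId, mode, hasPgc, pumpRhodopsins, candidateRhodopsins, xrOperon`.
#' @export
callPhototrophy <- function(magId, pgcInventory = NULL,
                            rhodopsinRecords = NULL, isHost = FALSE) {
    hp <- !is.null(pgcInventory) && hasPgc(pgcInventory)
    rr <- rhodopsinRecords
    if (is.null(rr))
        rr <- .emptyRhodopsinRecords()
    pumps <- sum(rr$call == "bona_fide_pump")
    cands <- sum(rr$call == "candidate_pump")
    xr <- any(rr$subtree == "III" & rr$brpBlhAdjacent &
              rr$call %in% c("bona_fide_pump", "candidate_pump"))
    mode <- if (isHost) {
        "cyano_oxygenic"
    } else if (hp && (pumps > 0 || xr)) {
        "dual"
    } else if (hp) {
        "pgc_only"
    } else if (pumps + cands > 0) {
        "rhodopsin_only"
    } else {
        "none"
    }
    data.frame(magId = magId, mode = mode, hasPgc = hp,
               pumpRhodopsins = pumps, candidateRhodopsins = cands,
               xrOperon = xr, stringsAsFactors = FALSE)
}

#' Phototrophy calls for a whole collection
#'
#' @param collection a [MagCollection-class].
#' @param inventories named list of [PgcInventory-class] keyed by MAG id.
#' @param rhodopsins combined rhodopsin record data.frame.
#' @param hostIds character vector of host MAG ids (see [hostMap()]).
#' @return calls data.frame, one row per MAG.
#' @export
callPhototrophyCollection <- function(collection, inventories, rhodopsins,
                                      hostIds = hostMap(collection)) {
    rows <- lapply(magIds(collection), function(m) {
        callPhototrophy(m, inventories[[m]],
                        rhodopsins[rhodopsins$magId == m, , drop = FALSE],
                        isHost = m %in% hostIds)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}

#' Venn summary of phototrophy across a collection
#'
#' Counts, over non-host MAGs: `pgc_total` (MAGs with a PGC),
#' `rhodopsin_total` (MAGs with at least one bona fide or candidate pump),
#' `rhodopsin_bona_fide` (MAGs with at least one bona fide pump), `dual`,
#' `none`; plus `cyano` (host MAGs). Both rhodopsin tallies are reported
#' because "rhodopsin-positive" can reasonably include or exclude
#' candidate pumps.
#'
#' @param calls calls data.frame from [callPhototrophyCollection()].
#' @return named list of counts.
#' @export
summarizeVenn <- function(calls) {
    if (anyDuplicated(calls$magId))
        stop("duplicate magId in phototrophy calls: ",
             paste(unique(calls$magId[duplicated(calls$magId)]),
                   collapse = ", "))
    nonHost <- calls[calls$mode != "cyano_oxygenic", , drop = FALSE]
    list(
        pgc_total = sum(nonHost$hasPgc),
        rhodopsin_total = sum(nonHost$pumpRhodopsins +
                              nonHost$candidateRhodopsins > 0),
        rhodopsin_bona_fide = sum(nonHost$pumpRhodopsins > 0),
        dual = sum(nonHost$mode == "dual"),
        none = sum(nonHost$mode == "none"),
        cyano = sum(calls$mode == "cyano_oxygenic"))
}

#' Write phototrophy calls as TSV
#'
#' @param calls calls data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallsTsv <- function(calls, path) {
    out <- calls
    colnames(out) <- c("mag_id", "mode", "has_pgc", "pump_rhodopsins",
                       "candidate_rhodopsins", "xr_operon")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
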