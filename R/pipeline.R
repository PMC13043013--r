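# Pipeline orchestration: filter -> screen -> rhodopsin -> pgc -> calls ->
# metrics, with a shared resolved configuration, timestamped key=value
# logging, and outputs written per stage so partial results survive a
# failing stage.

.log <- function(stage, ...) {
    kv <- c(...)
    msg <- paste(names(kv), unname(kv), sep = "=", collapse = " ")
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage,
            " ", msg)
}

#' Default pipeline configuration
#'
#' All threshold knobs with their documented defaults. Override any entry
#' via [loadConfig()] or by modifying the returned list.
#'
#' @return named list of configuration entries.
#' @export
defaultConfig <- function() {
    list(
        manifest = NULL,          # path to the MAG manifest TSV
        qc = NULL,                # QC table path (optional)
        coverage = NULL,          # coverage table path (optional)
        taxonomy = NULL,          # taxonomy table path (optional)
        pgc_panel = NULL,         # protein FASTA; NULL = shipped panel
        rhodopsin_panel = NULL,   # protein FASTA; NULL = shipped panel
        pgc_reference = NULL,     # ordered gene list TSV; NULL = shipped
        out = "cyanophot-out",
        min_identity = 0.30,
        min_query_cov = 0.50,
        min_score = 60,
        min_aa = 60,
        matrix = "BLOSUM62",
        gap_open = 11,
        gap_extend = 1,
        window_bp = 5000,
        rhodopsin_positions = c(res85 = 85, res89 = 89, res96 = 96,
                                res156 = 156, resK = 292),
        pgc_min_completeness = 0.5,
        pgc_max_span_bp = 80000,
        qc_min_completeness = 80,
        qc_max_contamination = 10,
        commonality_rank = "species")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' resolved configuration is echoed to the log once.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
loadConfig <- function(path) {
    user <- yaml::read_yaml(path)
    cfg <- defaultConfig()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
    cfg
}

#' Run the full phototrophy-annotation pipeline
#'
#' Stages, in order: QC filter, translated homology screen, rhodopsin
#' classification, PGC inventory, phototrophy calls + Venn summary, and
#' community metrics (abundance, commonality, presence-absence matrices).
#' Each stage writes its outputs before the next starts; a missing
#' coverage/taxonomy table skips the metrics stage with a warning.
#'
#' @param config configuration list ([defaultConfig()] / [loadConfig()]).
#' @return result bundle: `collection`, `hits`, `rhodopsins`,
#'   `inventories`, `calls`, `venn`, `abundance`, `commonality`,
#'   `summaryPath`, invisibly.
#' @export
runPipeline <- function(config = defaultConfig()) {
    cfg <- config
    if (is.null(cfg$manifest))
        stop("config$manifest is required")
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    for (k in names(cfg))
        .log("config", setNames(paste(cfg[[k]] %||% "NULL", collapse = ","),
                                k))

    coll <- loadCollection(cfg$manifest)
    .log("load", n_mags = length(coll))

    if (!is.null(cfg$qc)) {
        qc <- readQcTable(cfg$qc)
        coll <- filterMags(qc, coll, cfg$qc_min_completeness,
                           cfg$qc_max_contamination)
        .log("filter", retained = length(coll),
             removed = length(attr(coll, "removed")))
    }

    pgcP <- pgcPanel(cfg$pgc_panel)
    rhoP <- rhodopsinReferences(cfg$rhodopsin_panel)
    panel <- combinePanels(pgcP, rhoP)
    hits <- screenCollection(coll, panel,
                             minIdentity = cfg$min_identity,
                             minQueryCov = cfg$min_query_cov,
                             minScore = cfg$min_score, minAa = cfg$min_aa,
                             matrix = cfg$matrix, gapOpen = cfg$gap_open,
                             gapExt = cfg$gap_extend)
    writeHitsTsv(hits, file.path(cfg$out, "hits.tsv"))
    writeHitsGff(hits, file.path(cfg$out, "hits.gff3"))
    .log("screen", n_hits = nrow(hits))

    pos <- unlist(cfg$rhodopsin_positions)
    rhodopsins <- classifyRhodopsins(hits, rhoP, windowBp = cfg$window_bp,
                                     positions = pos,
                                     matrix = cfg$matrix,
                                     gapOpen = cfg$gap_open,
                                     gapExt = cfg$gap_extend)
    writeRhodopsinTsv(rhodopsins, file.path(cfg$out, "rhodopsins.tsv"))
    .log("rhodopsin", n_records = nrow(rhodopsins))

    ref <- pgcReference(cfg$pgc_reference)
    inventories <- lapply(magIds(coll), function(m)
        inventoryPgc(hits[hits$magId == m, , drop = FALSE], coll[[m]],
                     reference = ref,
                     minCompleteness = cfg$pgc_min_completeness,
                     maxSpanBp = cfg$pgc_max_span_bp))
    names(inventories) <- magIds(coll)
    writePgcTsv(inventories, file.path(cfg$out, "pgc_inventory.tsv"))
    .log("pgc", n_with_pgc = sum(vapply(inventories, hasPgc, logical(1))))

    calls <- callPhototrophyCollection(coll, inventories, rhodopsins)
    venn <- summarizeVenn(calls)
    writeCallsTsv(calls, file.path(cfg$out, "phototrophy_calls.tsv"))
    .log("calls", dual = venn$dual, pgc_total = venn$pgc_total,
         rhodopsin_total = venn$rhodopsin_total)

    abundance <- NULL
    common <- NULL
    if (!is.null(cfg$coverage)) {
        cv <- readCoverageTable(cfg$coverage)
        abundance <- computeAbundance(cv, coll, hostMap(coll))
        write.table(abundance, file.path(cfg$out, "abundance.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        .log("metrics", abundance_rows = nrow(abundance))
    } else {
        warning("no coverage table configured; abundance stage skipped")
    }
    if (!is.null(cfg$taxonomy)) {
        assignments <- joinTaxonomy(readTaxonomyTable(cfg$taxonomy), coll)
        common <- commonality(assignments, cfg$commonality_rank)
        write.table(common, file.path(cfg$out, "commonality.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        for (rk in c("species", "genus", "family", "order", "class",
                     "phylum"))
            writePresenceMatrix(presenceMatrix(assignments, rk),
                file.path(cfg$out, paste0("presence_", rk, ".tsv")))
        .log("metrics", commonality_taxa = nrow(common))
    } else {
        warning("no taxonomy table configured; commonality stage skipped")
    }

    summaryPath <- file.path(cfg$out, "summary.json")
    jsonlite::write_json(list(venn = venn, n_mags = length(coll),
                              n_hits = nrow(hits),
                              n_rhodopsins = nrow(rhodopsins)),
                         summaryPath, auto_unbox = TRUE, digits = NA)
    invisible(list(collection = coll, hits = hits, rhodopsins = rhodopsins,
                   inventories = inventories, calls = calls, venn = venn,
                   abundance = abundance, commonality = common,
                   summaryPath = summaryPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a pipeline result bundle against a truth manifest
#'
#' Planted rhodopsin features are matched to classified records by MAG and
#' interval overlap; planted PGCs to inventories by MAG. Agreement
#' fractions are reported for subtree, functional call, antenna and
#' per-MAG phototrophy mode, plus rhodopsin recall/precision (a record is
#' a true positive when it overlaps a planted rhodopsin-bearing feature).
#'
#' @param bundle result of [runPipeline()].
#' @param truth truth feature table from [generateCollection()].
#' @param modes per-MAG expected-mode table from [generateCollection()].
#' @return list of agreement fractions and counts.
#' @export
compareToTruth <- function(bundle, truth, modes) {
    rh <- truth[grepl("rhodopsin:", truth$genes), , drop = FALSE]
    rec <- bundle$rhodopsins
    matchedRec <- logical(nrow(rec))
    subtreeOk <- callOk <- antennaOk <- logical(nrow(rh))
    found <- logical(nrow(rh))
    for (i in seq_len(nrow(rh))) {
        sel <- which(rec$magId == rh$magId[i] &
                     rec$contigId == rh$contigId[i] &
                     rec$start < rh$end[i] & rec$end > rh$start[i])
        if (length(sel) == 0L)
            next
        found[i] <- TRUE
        matchedRec[sel] <- TRUE
        r <- rec[sel[1], ]
        subtreeOk[i] <- identical(r$subtree, rh$expectedSubtree[i])
        callOk[i] <- identical(r$call, rh$expectedCall[i])
        antennaOk[i] <- identical(r$antenna, rh$expectedAntenna[i])
    }
    pgcTruthMags <- unique(truth$magId[truth$kind == "pgc"])
    invMags <- names(bundle$inventories)[vapply(bundle$inventories, hasPgc,
                                                logical(1))]
    modeCmp <- merge(modes, bundle$calls, by = "magId")
    list(
        n_planted_rhodopsins = nrow(rh),
        rhodopsin_recall = if (nrow(rh)) mean(found) else NA_real_,
        rhodopsin_precision = if (nrow(rec))
            mean(matchedRec) else NA_real_,
        subtree_agreement = if (nrow(rh)) mean(subtreeOk) else NA_real_,
        call_agreement = if (nrow(rh)) mean(callOk) else NA_real_,
        antenna_agreement = if (nrow(rh)) mean(antennaOk) else NA_real_,
        pgc_recall = if (length(pgcTruthMags))
            mean(pgcTruthMags %in% invMags) else NA_real_,
        pgc_precision = if (length(invMags))
            mean(invMags %in% pgcTruthMags) else NA_real_,
        mode_agreement = mean(modeCmp$expectedMode == modeCmp$mode))
}

#' One-command demo: generate a collection and run the pipeline on it
#'
#' @param outDir working directory for generated inputs and outputs.
#' @param seed RNG seed for the generator.
#' @param ... arguments passed to [generateCollection()].
#' @return list `(generated, bundle, evaluation, venn)`.
#' @export
demoRun <- function(outDir = tempfile("cyanophot-demo"), seed = 1, ...) {
    gen <- generateCollection(file.path(outDir, "input"), seed = seed, ...)
    cfg <- defaultConfig()
    cfg$manifest <- gen$paths$manifest
    cfg$qc <- gen$paths$qc
    cfg$coverage <- gen$paths$coverage
    cfg$taxonomy <- gen$paths$taxonomy
    cfg$out <- file.path(outDir, "out")
    bundle <- runPipeline(cfg)
    ev <- compareToTruth(bundle, gen$truth, gen$modes)
    list(generated = gen, bundle = bundle, evaluation = ev,
         venn = bundle$venn)
}
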