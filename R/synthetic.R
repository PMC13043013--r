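# Synthetic MAG collections with planted, manifest-recorded phototrophy
# features. The generator emulates a per-culture MAG set: one high-coverage
# cyanobacterial "host" genome (GC ~0.69) plus associated genomes, some
# carrying planted PGCs (complete, rearranged, or split), rhodopsin operons
# (with/without brp/blh, with residue overrides such as E96Q, K292A or the
# NDQ Na-pump motif), so that every pipeline stage can be validated against
# ground truth without any external data.

.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Generate an i.i.d. background nucleotide sequence
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2.
#'
#' @param lengthBp sequence length (> 0).
#' @param gc target GC fraction, strictly inside (0, 1).
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return a nucleotide string.
#' @export
generateBackground <- function(lengthBp, gc = 0.5, seed = NULL) {
    stopifnot(lengthBp > 0)
    if (gc <= 0 || gc >= 1)
        stop("gc must lie strictly inside (0, 1)")
    .withSeed(seed, {
        p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        paste(sample(names(p), lengthBp, replace = TRUE, prob = p),
              collapse = "")
    })
}

.codonTable <- function() {
    code <- .GENETIC_CODE_11
    split(names(code), code)
}

#' Reverse-translate a protein with uniform synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly among its synonymous
#' codons (translation table 11, stop codons excluded).
#'
#' @param protein protein string (standard 20 residues).
#' @param seed optional RNG seed.
#' @return a nucleotide string of length `3 * nchar(protein)`.
#' @export
reverseTranslate <- function(protein, seed = NULL) {
    tab <- .codonTable()
    aa <- strsplit(protein, "")[[1]]
    if (any(!aa %in% setdiff(names(tab), "*")))
        stop("protein contains non-standard residues")
    .withSeed(seed, {
        codons <- vapply(aa, function(a) {
            opts <- tab[[a]]
            opts[sample.int(length(opts), 1L)]
        }, character(1))
        paste(codons, collapse = "")
    })
}

#' Mutate a protein by random substitutions
#'
#' Each position is substituted (to a uniformly chosen different residue)
#' with probability `rate`; `protect` positions are never touched.
#'
#' @param protein protein string.
#' @param rate substitution probability per residue, in `[0, 0.7]`.
#' @param protect integer positions left untouched.
#' @param seed optional RNG seed.
#' @return mutated protein string.
#' @export
mutateProtein <- function(protein, rate, protect = integer(0), seed = NULL) {
    if (rate < 0 || rate > 0.7)
        stop("mutation rate must lie in [0, 0.7]")
    if (rate == 0)
        return(protein)
    aa <- strsplit(protein, "")[[1]]
    .withSeed(seed, {
        hit <- runif(length(aa)) < rate
        hit[protect[protect <= length(aa)]] <- FALSE
        for (i in which(hit))
            aa[i] <- sample(setdiff(.AA_ALPHABET20, aa[i]), 1L)
        paste(aa, collapse = "")
    })
}

#' Specify a feature to plant
#'
#' @param kind one of `pgc`, `rhodopsin_operon`, `solitary_rhodopsin`,
#'   `na_pump`, `brp_blh_only`.
#' @param genes gene tokens in operon order. Rhodopsin genes select their
#'   source subtree as `rhodopsin:I`, `rhodopsin:II` or `rhodopsin:III`;
#'   all other tokens are panel gene labels (e.g. `crtY`, `brp_blh`,
#'   `pufM`). For `kind = "pgc"` with `genes = NULL` the full ordered
#'   reference cluster is used.
#' @param mutationRate per-residue substitution probability in `[0, 0.7]`
#'   (anchor positions are protected unless overridden).
#' @param overrides named character vector of residue overrides at anchor
#'   positions, e.g. `c("96" = "Q")` for E96Q, `c("292" = "A")` for K292A,
#'   or `c("85" = "N", "89" = "D", "96" = "Q")` for the NDQ Na-pump motif.
#' @param strand `"+"` or `"-"` (per-gene strand of the planted genes).
#' @param splitAcrossContigs plant the gene list across two contigs.
#' @param rearrangement signed permutation of the gene list (negative =
#'   flipped strand), e.g. `c(1, -3, -2, 4)`; `NULL` for the given order.
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(kind = c("pgc", "rhodopsin_operon",
                               "solitary_rhodopsin", "na_pump",
                               "brp_blh_only"),
                      genes = NULL, mutationRate = 0, overrides = NULL,
                      strand = "+", splitAcrossContigs = FALSE,
                      rearrangement = NULL) {
    kind <- match.arg(kind)
    if (mutationRate < 0 || mutationRate > 0.7)
        stop("mutation rate must lie in [0, 0.7]")
    if (!is.null(overrides)) {
        pos <- as.integer(names(overrides))
        if (any(is.na(pos)) || any(!pos %in% .DIAGNOSTIC_POSITIONS))
            stop("overrides must be named by valid anchor positions (",
                 paste(.DIAGNOSTIC_POSITIONS, collapse = ", "), ")")
    }
    structure(list(kind = kind, genes = genes, mutationRate = mutationRate,
                   overrides = overrides, strand = strand,
                   splitAcrossContigs = splitAcrossContigs,
                   rearrangement = rearrangement),
              class = "PlantSpec")
}

# protein for one gene token, with mutation/overrides applied to rhodopsins
.plantProtein <- function(token, panel, spec) {
    if (grepl("^rhodopsin:", token)) {
        st <- sub("^rhodopsin:", "", token)
        sel <- which(!is.na(mcols(panel)$subtree) &
                     mcols(panel)$subtree == st)
        if (length(sel) == 0L)
            stop("panel has no rhodopsin reference for subtree ", st)
        prot <- as.character(panel[[sel[1]]])
        if (spec$mutationRate > 0)
            prot <- mutateProtein(prot, spec$mutationRate,
                                  protect = .DIAGNOSTIC_POSITIONS)
        if (!is.null(spec$overrides)) {
            aa <- strsplit(prot, "")[[1]]
            aa[as.integer(names(spec$overrides))] <- unname(spec$overrides)
            prot <- paste(aa, collapse = "")
        }
        prot
    } else {
        sel <- which(mcols(panel)$label == token)
        if (length(sel) == 0L)
            stop("panel has no reference labeled ", token)
        prot <- as.character(panel[[sel[1]]])
        if (spec$mutationRate > 0)
            prot <- mutateProtein(prot, spec$mutationRate)
        prot
    }
}

.REVCOMP <- function(x)
    as.character(reverseComplement(DNAStringSet(x)))

# lay out gene blocks (stop-flanked, spacer-separated); returns the
# cassette string and per-gene labels in genomic order
.buildCassette <- function(tokens, strands, panel, spec, spacerGc = 0.45) {
    blocks <- character(length(tokens))
    for (i in seq_along(tokens)) {
        dna <- paste0("TAA", reverseTranslate(.plantProtein(tokens[i],
                                                            panel, spec)),
                      "TAA")
        if (strands[i] == "-")
            dna <- .REVCOMP(dna)
        blocks[i] <- dna
    }
    spacers <- vapply(seq_along(tokens),
                      function(i) generateBackground(60L, spacerGc),
                      character(1))
    paste0(paste0(blocks, spacers[seq_along(blocks)], collapse = ""))
}

.expectedFromSpec <- function(spec, blhInGenome) {
    tokens <- spec$genes
    rhTok <- tokens[grepl("^rhodopsin:", tokens)]
    if (length(rhTok) == 0L)
        return(list(subtree = NA_character_, call = NA_character_,
                    antenna = NA))
    subtree <- sub("^rhodopsin:", "", rhTok[1])
    ov <- spec$overrides
    res <- c("85" = "D", "89" = "T", "96" = "E", "156" = "G", "292" = "K")
    if (!is.null(ov))
        res[names(ov)] <- ov
    call <- if (res[["85"]] == "N" && res[["89"]] == "D" &&
                res[["96"]] == "Q") {
        "na_pump_excluded"
    } else if (res[["292"]] != "K") {
        "divergent_unknown"
    } else if (blhInGenome) {
        "bona_fide_pump"
    } else {
        "candidate_pump"
    }
    antenna <- res[["156"]] == "G" && subtree %in% c("I", "III")
    list(subtree = subtree, call = call, antenna = antenna)
}

.emptyTruth <- function() {
    data.frame(magId = character(0), metagenomeId = character(0),
               contigId = character(0), start = integer(0), end = integer(0),
               strand = character(0), kind = character(0),
               genes = character(0), expectedSubtree = character(0),
               expectedCall = character(0), expectedAntenna = logical(0),
               stringsAsFactors = FALSE)
}

#' Plant a feature into a genome
#'
#' Reverse-translates the specified proteins (uniform synonymous codons),
#' applies mutations/overrides, flanks every gene with in-frame stop
#' codons, separates genes by short background spacers, and inserts the
#' cassette mid-contig (or across two contigs for split features). Truth
#' rows record the interval and the expected downstream classification
#' derived from the spec itself.
#'
#' @param bin a [GenomeBin-class].
#' @param spec a [plantSpec()].
#' @param panel reference panel supplying the proteins.
#' @param seed optional RNG seed.
#' @param contigIndex contig (or first of two contigs) to plant into.
#' @param blhInGenome does the final genome carry a brp/blh gene (used for
#'   the expected functional call); `NULL` derives it from this spec's own
#'   genes — pass `TRUE` when another planted feature contributes it.
#' @return list `(bin, truth)` — the modified genome and the truth rows.
#' @export
plantFeature <- function(bin, spec, panel, seed = NULL, contigIndex = 1L,
                         blhInGenome = NULL) {
    .withSeed(seed, {
        tokens <- spec$genes
        if (spec$kind == "pgc" && is.null(tokens))
            tokens <- pgcReference()$symbol
        strands <- rep(spec$strand, length(tokens))
        if (!is.null(spec$rearrangement)) {
            perm <- spec$rearrangement
            if (length(perm) != length(tokens) ||
                !setequal(abs(perm), seq_along(tokens)))
                stop("rearrangement must be a signed permutation of the genes")
            strands <- ifelse(perm > 0, spec$strand,
                              ifelse(spec$strand == "+", "-", "+"))
            tokens <- tokens[abs(perm)]
        }
        ctgs <- as.character(contigs(bin))
        nm <- names(contigs(bin))
        parts <- if (isTRUE(spec$splitAcrossContigs)) {
            half <- ceiling(length(tokens) / 2)
            list(seq_len(half), seq(half + 1L, length(tokens)))
        } else {
            list(seq_along(tokens))
        }
        truth <- list()
        for (p in seq_along(parts)) {
            ci <- contigIndex + p - 1L
            if (ci > length(ctgs))
                stop("not enough contigs to split the feature across")
            idx <- parts[[p]]
            cassette <- .buildCassette(tokens[idx], strands[idx], panel, spec)
            at <- nchar(ctgs[ci]) %/% 2L
            if (nchar(ctgs[ci]) < 200L)
                stop("contig too short to plant into: ", nm[ci])
            ctgs[ci] <- paste0(substr(ctgs[ci], 1, at), cassette,
                               substr(ctgs[ci], at + 1L, nchar(ctgs[ci])))
            truth[[p]] <- data.frame(
                magId = magId(bin), metagenomeId = metagenomeId(bin),
                contigId = nm[ci], start = at,
                end = at + nchar(cassette), strand = spec$strand,
                kind = spec$kind,
                genes = paste(tokens[idx], collapse = ","),
                stringsAsFactors = FALSE)
        }
        truth <- do.call(rbind, truth)
        if (is.null(blhInGenome))
            blhInGenome <- "brp_blh" %in% tokens
        exp <- .expectedFromSpec(spec, blhInGenome)
        truth$expectedSubtree <- exp$subtree
        truth$expectedCall <- exp$call
        truth$expectedAntenna <- exp$antenna
        newContigs <- DNAStringSet(ctgs)
        names(newContigs) <- nm
        list(bin = GenomeBin(magId(bin), metagenomeId(bin), newContigs),
             truth = truth)
    })
}

#' Default planted feature mix
#'
#' One special MAG per listed metagenome (recycled round-robin over the
#' collection): a dual phototroph (complete PGC + xanthorhodopsin operon),
#' three PGC variants (complete, one-block inversion, split across
#' contigs), xanthorhodopsin and proteorhodopsin pump operons, a solitary
#' rhodopsin with brp/blh elsewhere in the genome, a pump candidate without
#' brp/blh, an NDQ Na-pump decoy, a K292A divergent homolog, and an E96Q
#' pump (functional despite the divergent position 96).
#'
#' @return named list of [plantSpec()] lists; names are labels, elements
#'   may contain more than one spec (planted into the same MAG).
#' @export
defaultFeatureMix <- function() {
    nref <- nrow(pgcReference())
    inv <- seq_len(nref)
    inv[5:9] <- -rev(inv[5:9])   # one internal block inversion
    list(
        dual = list(plantSpec("pgc"),
                    plantSpec("rhodopsin_operon",
                              genes = c("rhodopsin:III", "crtY", "brp_blh"))),
        pgc_complete = list(plantSpec("pgc")),
        pgc_rearranged = list(plantSpec("pgc", rearrangement = inv)),
        pgc_split = list(plantSpec("pgc", splitAcrossContigs = TRUE)),
        xr_operon = list(plantSpec("rhodopsin_operon",
                                   genes = c("rhodopsin:III", "crtE", "crtB",
                                             "crtY", "brp_blh"))),
        pr_operon = list(plantSpec("rhodopsin_operon",
                                   genes = c("rhodopsin:I", "brp_blh"))),
        solitary_with_blh = list(
            plantSpec("solitary_rhodopsin", genes = c("rhodopsin:I")),
            plantSpec("brp_blh_only", genes = c("brp_blh"))),
        pump_without_blh = list(
            plantSpec("solitary_rhodopsin", genes = c("rhodopsin:II"))),
        na_pump = list(plantSpec("na_pump", genes = c("rhodopsin:II"),
                                 overrides = c("85" = "N", "89" = "D",
                                               "96" = "Q"))),
        k292a_divergent = list(
            plantSpec("solitary_rhodopsin", genes = c("rhodopsin:I"),
                      overrides = c("292" = "A"))),
        e96q_pump = list(plantSpec("rhodopsin_operon",
                                   genes = c("rhodopsin:II", "brp_blh"),
                                   overrides = c("96" = "Q")))
    )
}

# expected phototrophy mode of a MAG given its planted specs
.expectedMode <- function(specs) {
    hasPgc <- any(vapply(specs, function(s) s$kind == "pgc", logical(1)))
    calls <- vapply(specs, function(s)
        .expectedFromSpec(s, blhInGenome = any(vapply(specs, function(q)
            "brp_blh" %in% c(q$genes), logical(1))))$call, character(1))
    pump <- any(calls == "bona_fide_pump", na.rm = TRUE)
    cand <- any(calls == "candidate_pump", na.rm = TRUE)
    if (hasPgc && pump) "dual"
    else if (hasPgc) "pgc_only"
    else if (pump || cand) "rhodopsin_only"
    else "none"
}

#' Generate a synthetic MAG collection with planted ground truth
#'
#' Writes a complete, pipeline-consumable input set to `outDir`: one
#' nucleotide FASTA per MAG, the manifest (with host flags), coverage, QC
#' and taxonomy tables, and the truth manifest (TSV + JSON). Each
#' metagenome contains one host MAG (GC 0.69, highest expected coverage by
#' default) plus associated MAGs; feature-mix entries are planted
#' round-robin, one per metagenome. Coverages are log-normal with a
#' configurable host multiplier; one designated associate is planted at a
#' fixed high coverage ratio (default 17x the host) to exercise the
#' abundance calibration. Everything is a pure function of `seed`.
#'
#' @param outDir output directory (created if needed).
#' @param nMetagenomes number of metagenomes/cultures (default 14).
#' @param magsRange integer range for associated-MAG counts per metagenome
#'   (default `c(3, 6)`, a scaled-down culture; host not included).
#' @param featureMix list of spec lists (see [defaultFeatureMix()]).
#' @param mutationRate global per-residue substitution rate applied to all
#'   planted features (overrides each spec's rate when > 0).
#' @param hostGc host GC fraction (default 0.69).
#' @param associateGc associate GC fraction (default 0.5).
#' @param contigBp background contig length for associates (default 6000).
#' @param hostContigBp host contig length (default 15000).
#' @param hostMultiplier expected host:associate coverage ratio (default 10).
#' @param sdlog log-normal coverage spread (default 0.8).
#' @param highAbundance list `(metagenome, ratio)` planting one associate
#'   at `ratio` times the host coverage (default metagenome 2, ratio 17);
#'   `NULL` to disable.
#' @param commonSpeciesIn number of metagenomes sharing the common
#'   associate species (default 12, capped at `nMetagenomes`).
#' @param panel reference panel (default: shipped PGC + rhodopsin panels).
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return list `(dir, manifest, collection, truth, paths)`; `paths` names
#'   every written file.
#' @export
generateCollection <- function(outDir, nMetagenomes = 14,
                               magsRange = c(3, 6),
                               featureMix = defaultFeatureMix(),
                               mutationRate = 0,
                               hostGc = 0.69, associateGc = 0.5,
                               contigBp = 6000, hostContigBp = 15000,
                               hostMultiplier = 10, sdlog = 0.8,
                               highAbundance = list(metagenome = 2,
                                                    ratio = 17),
                               commonSpeciesIn = 12,
                               panel = NULL, seed = 1) {
    if (is.null(panel))
        panel <- combinePanels(pgcPanel(), rhodopsinReferences())
    dir.create(file.path(outDir, "fasta"), recursive = TRUE,
               showWarnings = FALSE)
    set.seed(seed)
    if (mutationRate > 0)
        featureMix <- lapply(featureMix, function(specs)
            lapply(specs, function(s) { s$mutationRate <- mutationRate; s }))
    mgIds <- sprintf("C%02d", seq_len(nMetagenomes))
    bins <- list()
    manifest <- list()
    truth <- list()
    qc <- list()
    cov <- list()
    tax <- list()
    hostIds <- character(nMetagenomes)
    mixNames <- names(featureMix)
    commonIn <- min(commonSpeciesIn, nMetagenomes)
    hostLineage <- paste("Bacteria", "Cyanobacteriota", "Cyanophyceae",
                         "Oscillatoriales", "Coleofasciculaceae",
                         "Coleofasciculus", "Coleofasciculus sp", sep = ";")
    commonLineage <- paste("Bacteria", "Pseudomonadota",
                           "Alphaproteobacteria", "Rhodobacterales",
                           "Roseobacteraceae", "Marinovum",
                           "Marinovum communis", sep = ";")
    phyla <- c("Pseudomonadota", "Bacteroidota", "Planctomycetota",
               "Actinomycetota", "Balneolota")
    for (g in seq_len(nMetagenomes)) {
        mg <- mgIds[g]
        nAssoc <- sample(magsRange[1]:magsRange[2], 1L)
        hostId <- sprintf("H1-%s-01", mg)
        hostIds[g] <- hostId
        host <- GenomeBin(hostId, mg, setNames(
            DNAStringSet(generateBackground(hostContigBp, hostGc)),
            paste0(hostId, "_ctg1")))
        bins[[hostId]] <- host
        manifest[[hostId]] <- data.frame(
            mag_id = hostId, metagenome_id = mg,
            fasta_path = file.path("fasta", paste0(hostId, ".fna")),
            is_host = 1L, stringsAsFactors = FALSE)
        hostCov <- rlnorm(1, meanlog = log(400), sdlog = 0.3)
        cov[[hostId]] <- data.frame(mag_id = hostId, metagenome_id = mg,
                                    mapped_bases = round(hostCov *
                                        genomeSize(host)),
                                    stringsAsFactors = FALSE)
        qc[[hostId]] <- data.frame(mag_id = hostId,
                                   completeness = round(runif(1, 92, 99.5), 2),
                                   contamination = round(runif(1, 0, 4), 2),
                                   stringsAsFactors = FALSE)
        tax[[hostId]] <- data.frame(mag_id = hostId, lineage = hostLineage,
                                    stringsAsFactors = FALSE)
        specLabel <- if (g <= length(mixNames)) mixNames[g] else NA
        for (a in seq_len(nAssoc)) {
            mid <- sprintf("A%d-%s-%02d", (a %% 3) + 1, mg, a + 1)
            planted <- !is.na(specLabel) && a == 1L
            specs <- if (planted) featureMix[[specLabel]] else list()
            nCtg <- max(2L, length(specs) + 1L)
            ctgSeqs <- vapply(seq_len(nCtg), function(i)
                generateBackground(contigBp, associateGc), character(1))
            ctgs <- setNames(DNAStringSet(ctgSeqs),
                             sprintf("%s_ctg%d", mid, seq_len(nCtg)))
            bin <- GenomeBin(mid, mg, ctgs)
            blhGenome <- any(vapply(specs, function(s)
                "brp_blh" %in% s$genes, logical(1)))
            for (s in seq_along(specs)) {
                res <- plantFeature(bin, specs[[s]], panel,
                                    contigIndex = s,
                                    blhInGenome = blhGenome)
                bin <- res$bin
                truth[[length(truth) + 1L]] <- res$truth
            }
            tax[[mid]] <- data.frame(mag_id = mid,
                lineage = if (a == 1L && g <= commonIn) commonLineage
                          else .randomLineage(phyla, mid),
                stringsAsFactors = FALSE)
            bins[[mid]] <- bin
            manifest[[mid]] <- data.frame(
                mag_id = mid, metagenome_id = mg,
                fasta_path = file.path("fasta", paste0(mid, ".fna")),
                is_host = 0L, stringsAsFactors = FALSE)
            ratio <- if (!is.null(highAbundance) &&
                         g == highAbundance$metagenome && a == 2L)
                highAbundance$ratio
            else
                rlnorm(1, meanlog = log(1 / hostMultiplier), sdlog = sdlog)
            cov[[mid]] <- data.frame(mag_id = mid, metagenome_id = mg,
                                     mapped_bases = round(ratio * hostCov *
                                         genomeSize(bin)),
                                     stringsAsFactors = FALSE)
            qc[[mid]] <- data.frame(mag_id = mid,
                                    completeness = round(runif(1, 82, 99.5), 2),
                                    contamination = round(runif(1, 0, 8), 2),
                                    stringsAsFactors = FALSE)
        }
    }
    truthTab <- if (length(truth)) do.call(rbind, truth) else .emptyTruth()
    rownames(truthTab) <- NULL
    # per-MAG expected modes: planted MAGs from their specs, all other
    # associates "none", hosts "cyano_oxygenic"
    manTab <- do.call(rbind, manifest)
    rownames(manTab) <- NULL
    plantedMags <- unique(truthTab$magId)
    modes <- data.frame(magId = manTab$mag_id,
                        metagenomeId = manTab$metagenome_id,
                        stringsAsFactors = FALSE)
    modes$expectedMode <- ifelse(manTab$is_host == 1L, "cyano_oxygenic",
                                 "none")
    for (g in seq_along(mixNames)) {
        if (g > nMetagenomes) break
        mgMags <- truthTab$magId[truthTab$metagenomeId == mgIds[g]]
        if (length(mgMags))
            modes$expectedMode[modes$magId == mgMags[1]] <-
                .expectedMode(featureMix[[mixNames[g]]])
    }
    coll <- MagCollection(bins)
    attr(coll, "hostIds") <- hostIds
    # write everything
    for (m in names(bins))
        writeFasta(contigs(bins[[m]]),
                   file.path(outDir, "fasta", paste0(m, ".fna")))
    paths <- list(
        manifest = file.path(outDir, "manifest.tsv"),
        coverage = file.path(outDir, "coverage.tsv"),
        qc = file.path(outDir, "qc.tsv"),
        taxonomy = file.path(outDir, "taxonomy.tsv"),
        truth = file.path(outDir, "truth.tsv"),
        truthJson = file.path(outDir, "truth.json"))
    write.table(manTab, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(do.call(rbind, cov), paths$coverage, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, qc), paths$qc, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(do.call(rbind, tax), paths$taxonomy, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truthTab, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
        list(seed = seed, nMetagenomes = nMetagenomes,
             magsRange = magsRange, mutationRate = mutationRate,
             features = truthTab, modes = modes),
        paths$truthJson, auto_unbox = TRUE, digits = NA)
    invisible(list(dir = outDir, manifest = manTab, collection = coll,
                   truth = truthTab, modes = modes, paths = paths,
                   hostIds = hostIds))
}

.randomLineage <- function(phyla, mid) {
    ph <- sample(phyla, 1L)
    paste("Bacteria", ph, paste0(ph, "_class"),
          paste0("Order_", sample(LETTERS, 1L)),
          paste0("Family_", sample(LETTERS, 1L)),
          paste0("Genus_", mid), paste0("Species_", mid), sep = ";")
}

#' Shipped PGC reference protein panel
#'
#' Synthetic stand-in proteins, one per reference PGC gene family, used by
#' the translated screen and by the generator for planting.
#'
#' @param path optional replacement panel FASTA.
#' @return `AAStringSet` panel.
#' @export
pgcPanel <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "synthetic_pgc_panel.faa",
                            package = "cyanophot", mustWork = TRUE)
    readPanel(path)
}
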