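rhoPanel <- rhodopsinReferences()
anchorI <- as.character(rhoPanel[[which(S4Vectors::mcols(rhoPanel)$subtree == "I")]])
anchorIII <- as.character(rhoPanel[[which(S4Vectors::mcols(rhoPanel)$subtree == "III")]])

.override <- function(prot, pos, res) {
    aa <- strsplit(prot, "")[[1]]
    aa[pos] <- res
    paste(aa, collapse = "")
}

test_that("anchor mapping is the identity on the anchor itself and shifts under insertions", {
    m <- anchorMap(anchorI, anchorI)
    expect_equal(m$hitPos, m$anchorPos)
    expect_equal(m$hitRes, strsplit(anchorI, "")[[1]])

    ins <- paste0(substr(anchorI, 1, 10), "W", substr(anchorI, 11, nchar(anchorI)))
    m2 <- anchorMap(ins, anchorI)
    expect_equal(m2$hitPos[1:10], 1:10)
    expect_equal(m2$hitPos[11:nrow(m2)], (11:nrow(m2)) + 1L)

    trunc <- substr(anchorI, 1, 60)   # ends before anchor position 85
    m3 <- anchorMap(trunc, anchorI)
    prof <- extractProfile(m3)
    expect_true(is.na(prof$res85))
    expect_false(prof$hasDTE)
})

test_that("anchor mapping refuses unrelated sequences", {
    set.seed(59)
    # a short unrelated fragment cannot reach 15% identity over the
    # anchor-length alignment
    expect_error(anchorMap(randomProtein(30), anchorI),
                 "anchor mapping unreliable")
})

test_that("diagnostic profiles flag the DTE triad, G-156, K-292 and the NDQ motif", {
    prof <- extractProfile(anchorMap(anchorI, anchorI))
    expect_true(prof$hasDTE)
    expect_true(prof$hasG156)
    expect_true(prof$hasRetinalK)
    expect_false(prof$naPumpMotif)

    e96q <- extractProfile(anchorMap(.override(anchorI, 96, "Q"), anchorI))
    expect_false(e96q$hasDTE)
    expect_true(e96q$hasRetinalK)    # still pump-eligible

    k292a <- extractProfile(anchorMap(.override(anchorI, 292, "A"), anchorI))
    expect_false(k292a$hasRetinalK)

    ndq <- extractProfile(anchorMap(
        .override(anchorI, c(85, 89, 96), c("N", "D", "Q")), anchorI))
    expect_true(ndq$naPumpMotif)
    expect_false(ndq$hasDTE)
})

test_that("nearest-reference subtree assignment is stable and flags chimeras", {
    for (st in c("I", "II", "III")) {
        ref <- as.character(rhoPanel[[which(S4Vectors::mcols(rhoPanel)$subtree == st)]])
        a <- assignSubtree(ref, rhoPanel)
        expect_equal(a$subtree, st)
        expect_gt(a$margin, 0)
        expect_false(a$lowConfidence)
    }
    # ~90% identity derivative of the subtree-III reference stays in III
    set.seed(61)
    mut <- mutateProtein(anchorIII, 0.10, protect = c(85, 89, 96, 156, 292))
    a <- assignSubtree(mut, rhoPanel)
    expect_equal(a$subtree, "III")

    half <- nchar(anchorI) %/% 2
    chimera <- paste0(substr(anchorI, 1, half),
                      substr(anchorIII, half + 1, nchar(anchorIII)))
    expect_true(assignSubtree(chimera, rhoPanel)$lowConfidence)
})

.feat <- function(contig, start, end, label, strand = "+")
    data.frame(contigId = contig, start = start, end = end, strand = strand,
               label = label, source = "predicted", stringsAsFactors = FALSE)

test_that("operon context distinguishes adjacent, genome-wide and absent brp/blh", {
    hit <- .feat("c1", 1000, 1900, "rhodopsin")
    xrOperon <- rbind(hit,
                      .feat("c1", 2000, 2700, "crtY"),
                      .feat("c1", 2800, 3500, "brp_blh"))
    ctx <- operonContext(hit, xrOperon)
    expect_true(ctx$brpBlhAdjacent)
    expect_true(ctx$brpBlhInGenome)
    expect_equal(ctx$crtGenes, "crtY")

    full <- rbind(hit,
                  .feat("c1", 2000, 2600, "crtE"),
                  .feat("c1", 2700, 3300, "crtB"),
                  .feat("c1", 3400, 4000, "crtY"),
                  .feat("c1", 4100, 4800, "brp_blh"))
    ctx <- operonContext(hit, full)
    expect_setequal(ctx$crtGenes, c("crtE", "crtB", "crtY"))
    expect_true(ctx$brpBlhAdjacent)

    solitary <- rbind(hit, .feat("c2", 500, 1200, "brp_blh"))
    ctx <- operonContext(hit, solitary)
    expect_false(ctx$brpBlhAdjacent)
    expect_true(ctx$brpBlhInGenome)

    distant <- rbind(hit, .feat("c1", 8000, 8700, "brp_blh"))
    ctx <- operonContext(hit, distant)
    expect_false(ctx$brpBlhAdjacent)   # outside the 5 kb window
    expect_true(ctx$brpBlhInGenome)

    expect_error(operonContext(.feat("c9", 1, 10, "rhodopsin"), xrOperon),
                 "not present")
})

test_that("the functional call follows the motif/operon decision rule", {
    mkProf <- function(r85 = "D", r89 = "T", r96 = "E", r156 = "G",
                       rK = "K") {
        extractProfile(anchorMap(
            .override(anchorI, c(85, 89, 96, 156, 292),
                      c(r85, r89, r96, r156, rK)), anchorI))
    }
    ctxBlh <- list(naPumpMotif = FALSE, brpBlhInGenome = TRUE)
    ctxNone <- list(naPumpMotif = FALSE, brpBlhInGenome = FALSE)

    fc <- callRhodopsinFunction("III", mkProf(), ctxBlh)
    expect_equal(fc$call, "bona_fide_pump")
    expect_true(fc$antenna)

    # E96Q: DTE broken but still a pump (E. sibiricum-type divergence)
    fc <- callRhodopsinFunction("II", mkProf(r96 = "Q"), ctxBlh)
    expect_equal(fc$call, "bona_fide_pump")
    expect_false(fc$antenna)          # subtree II gets no antenna prediction

    prof <- mkProf(r85 = "N", r89 = "D", r96 = "Q")
    fc <- callRhodopsinFunction("II", prof,
                                list(naPumpMotif = prof$naPumpMotif,
                                     brpBlhInGenome = TRUE))
    expect_equal(fc$call, "na_pump_excluded")

    fc <- callRhodopsinFunction("I", mkProf(rK = "A"), ctxBlh)
    expect_equal(fc$call, "divergent_unknown")

    fc <- callRhodopsinFunction("I", mkProf(), ctxNone)
    expect_equal(fc$call, "candidate_pump")
})

test_that("removing brp/blh only demotes bona fide pumps to candidates", {
    set.seed(67)
    panel <- combinePanels(pgcPanel(), rhoPanel)
    bin <- GenomeBin("M1", "G1",
                     c(c1 = randomDna(6000), c2 = randomDna(3000)))
    res <- plantFeature(bin, plantSpec("rhodopsin_operon",
                                      genes = c("rhodopsin:III", "crtY",
                                                "brp_blh")), panel)
    hits <- screenGenome(res$bin, panel)
    recWith <- classifyRhodopsins(hits, rhoPanel)
    expect_equal(recWith$call, "bona_fide_pump")

    hitsNoBlh <- hits[hits$geneLabel != "brp_blh", ]
    recWithout <- classifyRhodopsins(hitsNoBlh, rhoPanel)
    expect_equal(recWithout$call, "candidate_pump")
    # everything except the call and operon flags is untouched
    same <- c("subtree", "res85", "res89", "res96", "res156", "resK",
              "hasDTE", "hasG156", "hasRetinalK", "antenna")
    expect_equal(recWith[, same], recWithout[, same])
})

test_that("every rhodopsin hit receives exactly one of the four calls", {
    set.seed(71)
    panel <- combinePanels(pgcPanel(), rhoPanel)
    bin <- GenomeBin("M1", "G1", c(c1 = randomDna(5000),
                                   c2 = randomDna(5000),
                                   c3 = randomDna(5000)))
    r1 <- plantFeature(bin, plantSpec("rhodopsin_operon",
                                     genes = c("rhodopsin:I", "brp_blh")),
                       contigIndex = 1, panel = panel)
    r2 <- plantFeature(r1$bin, plantSpec("na_pump", genes = "rhodopsin:II",
                                         overrides = c("85" = "N",
                                                       "89" = "D",
                                                       "96" = "Q")),
                       contigIndex = 2, panel = panel)
    r3 <- plantFeature(r2$bin, plantSpec("solitary_rhodopsin",
                                         genes = "rhodopsin:I",
                                         overrides = c("292" = "A")),
                       contigIndex = 3, panel = panel)
    hits <- screenGenome(r3$bin, panel)
    rec <- classifyRhodopsins(hits, rhoPanel)
    expect_equal(nrow(rec), sum(hits$geneLabel == "rhodopsin"))
    expect_true(all(rec$call %in% c("bona_fide_pump", "candidate_pump",
                                    "na_pump_excluded", "divergent_unknown")))
    expect_setequal(rec$call, c("bona_fide_pump", "na_pump_excluded",
                                "divergent_unknown"))
})
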