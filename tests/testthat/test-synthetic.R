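test_that("background generation is seed-deterministic with calibrated GC", {
    a <- generateBackground(500, 0.5, seed = 99)
    b <- generateBackground(500, 0.5, seed = 99)
    expect_identical(a, b)

    big <- generateBackground(1e5, 0.69, seed = 101)
    expect_lt(abs(gcContent(big) - 0.69), 0.02)   # ~5 sigma binomial band

    expect_error(generateBackground(100, 0), "gc must lie")
    expect_error(generateBackground(100, 1), "gc must lie")
    expect_error(generateBackground(0, 0.5), "lengthBp > 0")
})

test_that("reverse translation is exactly invertible by translation", {
    set.seed(103)
    for (i in 1:10) {
        prot <- randomProtein(sample(20:120, 1))
        dna <- reverseTranslate(prot)
        back <- as.character(Biostrings::translate(
            Biostrings::DNAStringSet(dna),
            genetic.code = Biostrings::getGeneticCode("11"),
            no.init.codon = TRUE))
        expect_equal(back, prot)
    }
    expect_identical(reverseTranslate("MKWVT", seed = 5),
                     reverseTranslate("MKWVT", seed = 5))
})

test_that("protein mutation respects rate bounds and protected positions", {
    prot <- randomProtein(200)
    expect_identical(mutateProtein(prot, 0), prot)
    expect_error(mutateProtein(prot, 0.9), "rate")

    mut <- mutateProtein(prot, 0.5, protect = c(10, 20, 30), seed = 7)
    expect_equal(substr(mut, 10, 10), substr(prot, 10, 10))
    expect_equal(substr(mut, 20, 20), substr(prot, 20, 20))
    expect_equal(substr(mut, 30, 30), substr(prot, 30, 30))
    ham <- mean(strsplit(mut, "")[[1]] != strsplit(prot, "")[[1]])
    expect_gt(ham, 0.3)
    expect_lt(ham, 0.7)
})

test_that("planted features record truth consistent with their spec", {
    set.seed(107)
    panel <- combinePanels(pgcPanel(), rhodopsinReferences())
    bin <- GenomeBin("M1", "G1", c(c1 = randomDna(4000),
                                   c2 = randomDna(4000)))

    xr <- plantFeature(bin, plantSpec("rhodopsin_operon",
                                     genes = c("rhodopsin:III", "crtY",
                                               "brp_blh")), panel)
    expect_equal(xr$truth$expectedSubtree, "III")
    expect_equal(xr$truth$expectedCall, "bona_fide_pump")
    expect_true(xr$truth$expectedAntenna)
    expect_lte(xr$truth$end, genomeSize(xr$bin))

    na <- plantFeature(bin, plantSpec("na_pump", genes = "rhodopsin:II",
                                      overrides = c("85" = "N", "89" = "D",
                                                    "96" = "Q")), panel)
    expect_equal(na$truth$expectedCall, "na_pump_excluded")

    ka <- plantFeature(bin, plantSpec("solitary_rhodopsin",
                                      genes = "rhodopsin:I",
                                      overrides = c("292" = "A")), panel)
    expect_equal(ka$truth$expectedCall, "divergent_unknown")

    cand <- plantFeature(bin, plantSpec("solitary_rhodopsin",
                                        genes = "rhodopsin:I"), panel)
    expect_equal(cand$truth$expectedCall, "candidate_pump")

    split <- plantFeature(bin, plantSpec("pgc", splitAcrossContigs = TRUE),
                          panel)
    expect_equal(nrow(split$truth), 2L)
    expect_setequal(split$truth$contigId, c("c1", "c2"))

    tiny <- GenomeBin("T", "G", c(c1 = "ACGTACGT"))
    expect_error(plantFeature(tiny, plantSpec("solitary_rhodopsin",
                                              genes = "rhodopsin:I"), panel),
                 "too short")
})

test_that("collection generation is a pure function of the seed", {
    d1 <- tempfile(); d2 <- tempfile()
    g1 <- generateCollection(d1, nMetagenomes = 2, seed = 404,
                             featureMix = defaultFeatureMix()["na_pump"])
    g2 <- generateCollection(d2, nMetagenomes = 2, seed = 404,
                             featureMix = defaultFeatureMix()["na_pump"])
    expect_equal(g1$truth, g2$truth)
    expect_identical(readLines(g1$paths$manifest),
                     readLines(g2$paths$manifest))
    fa <- file.path(d1, g1$manifest$fasta_path[1])
    fb <- file.path(d2, g2$manifest$fasta_path[1])
    expect_identical(readLines(fa), readLines(fb))
})

test_that("per-metagenome MAG counts honour the configured culture range", {
    d <- tempfile()
    g <- generateCollection(d, nMetagenomes = 4, magsRange = c(3, 40),
                            featureMix = list(), seed = 11)
    counts <- table(g$manifest$metagenome_id[g$manifest$is_host == 0])
    expect_true(all(counts >= 3 & counts <= 40))
    # exactly one host per metagenome, flagged in the manifest
    expect_equal(unname(table(g$manifest$metagenome_id[g$manifest$is_host == 1])),
                 rep(1L, 4), ignore_attr = TRUE)
    # all written tables exist and are consistent
    expect_true(all(file.exists(unlist(g$paths))))
    cov <- readCoverageTable(g$paths$coverage)
    expect_setequal(cov$magId, g$manifest$mag_id)
})
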