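.tinyCollection <- function(ids, mgs = "g1") {
    bins <- mapply(function(m, g)
        GenomeBin(m, g, c(c1 = "ACGTACGTACGT")),
        ids, rep(mgs, length.out = length(ids)))
    MagCollection(bins)
}

test_that("the QC filter applies strict completeness/contamination bounds", {
    coll <- .tinyCollection(c("a", "b", "c", "d"))
    qc <- data.frame(magId = c("a", "b", "c", "d"),
                     completeness = c(85.0, 80.0, 95.0, 99.0),
                     contamination = c(5.0, 5.0, 10.0, 0.0),
                     stringsAsFactors = FALSE)
    kept <- suppressMessages(filterMags(qc, coll))
    expect_setequal(magIds(kept), c("a", "d"))       # 80.0 and 10.0 excluded
    expect_setequal(attr(kept, "removed"), c("b", "c"))

    expect_error(filterMags(qc[-1, ], coll), "no QC row.*a")
})

test_that("relative abundance is calibrated to the host (=100%)", {
    cov <- data.frame(magId = c("host", "m1", "m2"),
                      metagenomeId = "g1",
                      mappedBases = c(8e9, 0, NA), stringsAsFactors = FALSE)
    sizes <- c(host = 8e6, m1 = 2e6, m2 = 4e6)
    cov$mappedBases[3] <- 17 * (8e9 / 8e6) * 4e6   # 17x the host coverage
    ab <- computeAbundance(cov, sizes, "host")
    expect_equal(ab$coverage[1], 1000)
    expect_equal(ab$relativeAbundance[1], 100)      # host self-calibration
    expect_equal(ab$relativeAbundance[2], 0)        # zero mapped bases
    expect_equal(ab$relativeAbundance[3], 1700)     # 17:1 ratio

    zero <- cov
    zero$mappedBases[1] <- 0
    expect_error(computeAbundance(zero, sizes, "host"), "host coverage")
})

test_that("relative abundance is invariant under read-depth rescaling", {
    set.seed(97)
    ids <- c("host", paste0("m", 1:6))
    cov <- data.frame(magId = ids, metagenomeId = "g1",
                      mappedBases = runif(7, 1e6, 1e9),
                      stringsAsFactors = FALSE)
    sizes <- setNames(runif(7, 1e6, 1e7), ids)
    a1 <- computeAbundance(cov, sizes, "host")
    cov2 <- cov
    cov2$mappedBases <- cov2$mappedBases * 3.7
    a2 <- computeAbundance(cov2, sizes, "host")
    expect_equal(a1$relativeAbundance, a2$relativeAbundance)
    expect_equal(a1$relativeAbundance[1], 100)
})

.lineage <- function(sp, ph = "Pseudomonadota")
    paste("Bacteria", ph, "Cls", "Ord", "Fam", "Gen", sp, sep = ";")

test_that("commonality counts each taxon once per metagenome", {
    n <- 14
    rows <- list()
    for (g in 1:n) {
        rows[[length(rows) + 1]] <- data.frame(
            magId = paste0("h", g), metagenomeId = paste0("g", g),
            lineage = .lineage("ubiquitous"), stringsAsFactors = FALSE)
        if (g <= 12)
            rows[[length(rows) + 1]] <- data.frame(
                magId = paste0("c", g), metagenomeId = paste0("g", g),
                lineage = .lineage("common"), stringsAsFactors = FALSE)
    }
    # duplicate carrier in one metagenome must not inflate the count
    rows[[length(rows) + 1]] <- data.frame(
        magId = "c1b", metagenomeId = "g1",
        lineage = .lineage("common"), stringsAsFactors = FALSE)
    cm <- commonality(do.call(rbind, rows))
    expect_equal(cm$count[cm$taxon == "ubiquitous"], n)
    expect_equal(cm$count[cm$taxon == "common"], 12L)
    expect_true(all(cm$count <= n))
    expect_equal(cm$count, sort(cm$count, decreasing = TRUE))

    expect_equal(nrow(commonality(do.call(rbind, rows)[0, ])), 0L)
})

test_that("presence matrices match hand-built expectations at each rank", {
    asg <- data.frame(
        magId = c("a1", "a2", "b1", "b2", "c1"),
        metagenomeId = c("g1", "g1", "g2", "g2", "g3"),
        lineage = c(.lineage("s1", "P1"), .lineage("s2", "P2"),
                    .lineage("s3", "P1"), .lineage("s2", "P2"),
                    .lineage("s4", "P3")),
        stringsAsFactors = FALSE)
    sp <- presenceMatrix(asg, "species")
    expect_equal(dim(sp), c(4L, 3L))
    expect_equal(sp["s2", ], c(g1 = 1L, g2 = 1L, g3 = 0L))
    expect_equal(sp["s1", ], c(g1 = 1L, g2 = 0L, g3 = 0L))
    expect_true(all(rowSums(sp) > 0))       # no all-zero taxon rows
    # column sums reproduce per-metagenome richness
    expect_equal(unname(colSums(sp)), c(2L, 2L, 1L))

    ph <- presenceMatrix(asg, "phylum")
    expect_equal(ph["P1", ], c(g1 = 1L, g2 = 1L, g3 = 0L))
    expect_equal(ph["P2", ], c(g1 = 1L, g2 = 1L, g3 = 0L))

    bad <- asg
    bad$lineage[1] <- "only;three;ranks"
    expect_error(presenceMatrix(bad, "species"), "malformed lineage")
})

test_that("MAGs without a taxonomy row become their own unclassified taxon", {
    coll <- .tinyCollection(c("x", "y"), c("g1", "g2"))
    tax <- data.frame(magId = "x", lineage = .lineage("s1"),
                      stringsAsFactors = FALSE)
    asg <- joinTaxonomy(tax, coll)
    expect_equal(nrow(asg), 2L)
    expect_match(asg$lineage[2], "unclassified_y")
    expect_equal(commonality(asg)$count, c(1L, 1L))
})
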