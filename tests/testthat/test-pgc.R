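# Hit tables are fabricated directly: inventoryPgc consumes dereplicated
# hits, so the screen itself is not needed to test the inventory logic.

.mkHits <- function(symbols, contig = "c1", start0 = 1000, gap = 1000,
                    strands = NULL, magId = "M1") {
    n <- length(symbols)
    if (is.null(strands)) strands <- rep("+", n)
    starts <- start0 + (seq_len(n) - 1) * gap
    data.frame(magId = magId, contigId = contig,
               referenceId = paste0("R", seq_len(n)), geneLabel = symbols,
               start = starts, end = starts + 600, strand = strands,
               frame = 1L, score = 500, identity = 1, queryCov = 1,
               orfProtein = "M", stringsAsFactors = FALSE)
}

test_that("a complete planted reference cluster inventories as a contiguous PGC", {
    ref <- pgcReference()
    inv <- inventoryPgc(.mkHits(ref$symbol), NULL)
    expect_equal(completeness(inv), 1.0)
    expect_true(hasPgc(inv))
    expect_true(inv@contiguous)
    expect_equal(orderVector(inv), seq_len(nrow(ref)))
})

test_that("pufL and pufM are mandatory for a PGC call", {
    ref <- pgcReference()
    noPuf <- setdiff(ref$symbol, c("pufL", "pufM"))
    inv <- inventoryPgc(.mkHits(noPuf), NULL)
    expect_gt(completeness(inv), 0.9)
    expect_false(hasPgc(inv))

    few <- inventoryPgc(.mkHits(c("pufL", "pufM", "bchH")), NULL)
    expect_false(hasPgc(few))   # completeness below the 0.5 floor
    expect_equal(completeness(few), 3 / nrow(ref))
})

test_that("a cluster split across contigs keeps its PGC call but not contiguity", {
    ref <- pgcReference()
    half <- nrow(ref) %/% 2
    hits <- rbind(.mkHits(ref$symbol[1:half], contig = "c1"),
                  .mkHits(ref$symbol[(half + 1):nrow(ref)], contig = "c2"))
    inv <- inventoryPgc(hits, NULL)
    expect_equal(completeness(inv), 1.0)
    expect_true(hasPgc(inv))
    expect_false(inv@contiguous)
})

test_that("completeness grows monotonically as genes accumulate", {
    ref <- pgcReference()
    prev <- -1
    for (k in c(3, 10, 20, nrow(ref))) {
        inv <- inventoryPgc(.mkHits(ref$symbol[1:k]), NULL)
        expect_gte(completeness(inv), prev)
        prev <- completeness(inv)
    }
})

test_that("synteny comparison counts signed breakpoints and blocks", {
    ident <- inventoryFromOrder(1:5)
    cmp <- syntenyCompare(ident, inventoryFromOrder(1:5, "Y"))
    expect_equal(cmp$breakpoints, 0L)
    expect_equal(cmp$blocks, 1L)

    inverted <- inventoryFromOrder(c(1, -3, -2, 4, 5), "Y")
    cmp <- syntenyCompare(ident, inverted)
    expect_equal(cmp$breakpoints, 2L)
    expect_true(cmp$blocks %in% c(2L, 3L))

    disjoint <- syntenyCompare(inventoryFromOrder(1:3),
                               inventoryFromOrder(10:12, "Y"))
    expect_equal(disjoint$sharedGenes, 0L)
    expect_true(is.na(disjoint$breakpoints))
})

test_that("breakpoints are symmetric and invariant under whole-cluster reflection", {
    set.seed(73)
    for (i in 1:25) {
        n <- sample(3:7, 1)
        a <- sample(1:n) * sample(c(-1, 1), n, replace = TRUE)
        b <- sample(1:n) * sample(c(-1, 1), n, replace = TRUE)
        ia <- inventoryFromOrder(a, "A")
        ib <- inventoryFromOrder(b, "B")
        expect_equal(syntenyCompare(ia, ib)$breakpoints,
                     syntenyCompare(ib, ia)$breakpoints)
        refl <- inventoryFromOrder(rev(-a), "C")
        expect_equal(syntenyCompare(ia, refl)$breakpoints, 0L)
    }
})

test_that("breakpoint counts match exhaustive adjacency enumeration", {
    set.seed(79)
    ident4 <- inventoryFromOrder(1:4)
    for (p in allSignedPermutations(4)) {
        got <- syntenyCompare(ident4, inventoryFromOrder(p, "P"))$breakpoints
        expect_equal(got, oracleBreakpoints(1:4, p), info = paste(p, collapse = ","))
    }
    for (i in 1:30) {
        n <- sample(2:6, 1)
        a <- sample(1:n) * sample(c(-1, 1), n, replace = TRUE)
        b <- sample(1:n) * sample(c(-1, 1), n, replace = TRUE)
        expect_equal(syntenyCompare(inventoryFromOrder(a, "A"),
                                    inventoryFromOrder(b, "B"))$breakpoints,
                     oracleBreakpoints(a, b))
    }
})

test_that("synteny plot data carries one deterministic row per located gene", {
    ref <- pgcReference()
    invA <- inventoryPgc(.mkHits(ref$symbol, magId = "A"), NULL)
    invB <- inventoryPgc(.mkHits(rev(ref$symbol), magId = "B"), NULL)
    tab <- exportSyntenyPlotData(list(invA, invB))
    expect_equal(nrow(tab), 2L * nrow(ref))
    expect_true(all(tab$class %in% c("bch", "crt", "puf", "cycA",
                                     "other_conserved")))
    expect_equal(tab, tab[order(tab$magId, tab$contigId, tab$start), ],
                 ignore_attr = TRUE)
    empty <- inventoryPgc(.mkHits("pufL")[0, ], NULL)
    expect_equal(nrow(exportSyntenyPlotData(list(empty))), 0L)
})
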