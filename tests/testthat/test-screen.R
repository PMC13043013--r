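# Fixtures: a panel protein reverse-translated and inserted in frame with
# flanking stops into random background, then screened back out.

.insertAt <- function(bg, cassette, at) {
    paste0(substr(bg, 1, at), cassette, substr(bg, at + 1, nchar(bg)))
}

test_that("an exact planted reference copy is recovered as a single perfect hit", {
    set.seed(41)
    panel <- pgcPanel()
    pufM <- as.character(panel[[which(S4Vectors::mcols(panel)$label == "pufM")]])
    cassette <- paste0("TAA", reverseTranslate(pufM), "TAA")
    bg <- randomDna(4000)
    bin <- GenomeBin("M1", "G1", c(ctg1 = .insertAt(bg, cassette, 2000)))
    hits <- screenGenome(bin, panel)
    pm <- hits[hits$geneLabel == "pufM", ]
    expect_equal(nrow(pm), 1L)
    expect_equal(pm$identity, 1.0)
    expect_equal(pm$queryCov, 1.0)
    expect_equal(pm$orfProtein, pufM)
    expect_equal(pm$strand, "+")
    # coordinates: ORF sits right after the inserted 5' stop codon
    expect_equal(pm$start, 2003L)
    expect_equal(pm$end, 2003L + 3L * nchar(pufM))
})

test_that("screening is symmetric under reverse complementation", {
    set.seed(43)
    panel <- pgcPanel()
    pufM <- as.character(panel[[which(S4Vectors::mcols(panel)$label == "pufM")]])
    cassette <- paste0("TAA", reverseTranslate(pufM), "TAA")
    bg <- randomDna(3000)
    fwdSeq <- .insertAt(bg, cassette, 1500)
    rcSeq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fwdSeq)))
    L <- nchar(fwdSeq)
    hitsF <- screenGenome(GenomeBin("F", "G", c(c1 = fwdSeq)), panel)
    hitsR <- screenGenome(GenomeBin("R", "G", c(c1 = rcSeq)), panel)
    expect_equal(nrow(hitsF), nrow(hitsR))
    # same families and scores, coordinates reflected, strands flipped
    oF <- hitsF[order(hitsF$geneLabel), ]
    oR <- hitsR[order(hitsR$geneLabel), ]
    expect_equal(oF$geneLabel, oR$geneLabel)
    expect_equal(oF$score, oR$score)
    expect_equal(oF$start, L - oR$end)
    expect_equal(oF$end, L - oR$start)
    expect_true(all(oF$strand != oR$strand))
})

test_that("a remote-divergence insert below the identity floor is rejected", {
    set.seed(47)
    panel <- pgcPanel()
    idx <- which(S4Vectors::mcols(panel)$label == "pufM")
    pufM <- strsplit(as.character(panel[[idx]]), "")[[1]]
    # degrade to ~25% positional identity: keep each residue with p = 0.25
    keep <- runif(length(pufM)) < 0.25
    degraded <- vapply(seq_along(pufM), function(i)
        if (keep[i]) pufM[i] else sample(setdiff(AA20, pufM[i]), 1),
        character(1))
    expect_lt(mean(degraded == pufM), 0.30)
    cassette <- paste0("TAA", reverseTranslate(paste(degraded, collapse = "")),
                       "TAA")
    bg <- randomDna(3000)
    bin <- GenomeBin("M1", "G1", c(c1 = .insertAt(bg, cassette, 1500)))
    hits <- screenGenome(bin, panel)
    expect_false("pufM" %in% hits$geneLabel)
})

test_that("planted recovery is exact at mutation rate zero, with dereplication", {
    set.seed(53)
    panel <- pgcPanel()
    labs <- c("pufL", "pufM", "bchH")
    bg <- randomDna(8000)
    at <- 1000
    for (lb in labs) {
        prot <- as.character(panel[[which(S4Vectors::mcols(panel)$label == lb)]])
        cassette <- paste0("TAA", reverseTranslate(prot), "TAA")
        bg <- .insertAt(bg, cassette, at)
        at <- at + nchar(cassette) + 2000
    }
    bin <- GenomeBin("M1", "G1", c(c1 = bg))
    hits <- screenGenome(bin, panel)
    expect_setequal(hits$geneLabel, labs)          # no false families
    expect_equal(nrow(hits), 3L)                   # one hit per family
    expect_true(all(hits$identity == 1.0))
})

test_that("screening an empty MAG warns and returns no hits", {
    bin <- methods::new("GenomeBin", magId = "E", metagenomeId = "G",
                        contigs = Biostrings::DNAStringSet())
    expect_warning(h <- screenGenome(bin, pgcPanel()), "empty MAG")
    expect_equal(nrow(h), 0L)
})
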