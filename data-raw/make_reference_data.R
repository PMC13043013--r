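# One-off generator for the shipped synthetic reference data under
# inst/extdata. Deterministic (fixed seed); run from the repo root.
set.seed(20241001)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# roughly uniprot-ish residue frequencies to avoid pathological compositions
FREQ <- c(A=8.3,C=1.4,D=5.5,E=6.7,F=3.9,G=7.1,H=2.3,I=5.9,K=5.8,L=9.7,
          M=2.4,N=4.1,P=4.7,Q=3.9,R=5.5,S=6.6,T=5.3,V=6.9,W=1.1,Y=2.9)

randProt <- function(n) paste(sample(AA, n, replace=TRUE, prob=FREQ[AA]),
                              collapse="")

mutate <- function(prot, rate, protect=integer(0)) {
  aa <- strsplit(prot, "")[[1]]
  hit <- runif(length(aa)) < rate
  hit[protect] <- FALSE
  for (i in which(hit)) aa[i] <- sample(setdiff(AA, aa[i]), 1)
  paste(aa, collapse="")
}

dir.create("inst/extdata", recursive=TRUE, showWarnings=FALSE)

## ---- ordered reference PGC (canonical Roseobacter-type layout) ----
pgc <- data.frame(
  symbol = c("crtA","crtI","crtB","tspO","crtC","crtD","crtE","crtF",
             "bchC","bchX","bchY","bchZ","pufB","pufA","pufL","pufM","pufC",
             "bchP","pucC","bchG","ppsR","ppaA","bchF","bchN","bchB","bchH",
             "bchL","bchM","lhaA","puhA","puhB","puhC","acsF","puhE","cycA"),
  class = c("crt","crt","crt","other_conserved","crt","crt","crt","crt",
            "bch","bch","bch","bch","puf","puf","puf","puf","puf",
            "bch","other_conserved","bch","other_conserved","other_conserved",
            "bch","bch","bch","bch","bch","bch","other_conserved",
            "other_conserved","other_conserved","other_conserved",
            "other_conserved","other_conserved","cycA"),
  stringsAsFactors = FALSE)
pgc$ref_index <- seq_len(nrow(pgc))
write.table(pgc, "inst/extdata/synthetic_pgc_reference.tsv", sep="\t",
            quote=FALSE, row.names=FALSE)

## ---- synthetic PGC protein panel (one protein per gene family) ----
lens <- sample(100:200, nrow(pgc), replace=TRUE)
lens[match(c("pufL","pufM"), pgc$symbol)] <- c(274, 307)  # realistic puf sizes
lines <- character(0)
for (i in seq_len(nrow(pgc))) {
  acc <- sprintf("SYNPGC%03d", i)
  lines <- c(lines,
             sprintf(">%s|%s synthetic reference protein for %s", acc,
                     pgc$symbol[i], pgc$symbol[i]),
             randProt(lens[i]))
}
writeLines(lines, "inst/extdata/synthetic_pgc_panel.faa")

## ---- synthetic rhodopsin panel: 3 subtree anchors + operon genes ----
L <- 300
anchorPos <- c(85,89,96,156,292)
canon <- c("D","T","E","G","K")
base <- strsplit(randProt(L), "")[[1]]
base[anchorPos] <- canon
base <- paste(base, collapse="")
refI   <- base
refII  <- mutate(base, 0.30, protect=anchorPos)
refIII <- mutate(base, 0.30, protect=anchorPos)

lines <- c(
  sprintf(">SYNRHO1|rhodopsin subtree=I synthetic proteorhodopsin anchor (Bacteroidota-type)"),
  refI,
  sprintf(">SYNRHO2|rhodopsin subtree=II synthetic proteorhodopsin anchor (E. sibiricum-type branch)"),
  refII,
  sprintf(">SYNRHO3|rhodopsin subtree=III synthetic xanthorhodopsin anchor"),
  refIII,
  ">SYNBLH1|brp_blh synthetic beta-carotene 15,15'-dioxygenase",
  randProt(260),
  ">SYNCRTY1|crtY synthetic lycopene cyclase",
  randProt(240))
writeLines(lines, "inst/extdata/synthetic_rhodopsin_panel.faa")

cat("identity I-II:", mean(strsplit(refI,"")[[1]]==strsplit(refII,"")[[1]]), "\n")
cat("identity I-III:", mean(strsplit(refI,"")[[1]]==strsplit(refIII,"")[[1]]), "\n")
cat("identity II-III:", mean(strsplit(refII,"")[[1]]==strsplit(refIII,"")[[1]]), "\n")
cat("files written\n")
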