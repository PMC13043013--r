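# Independent oracles, deliberately implemented without the package's
# alignment/ORF/synteny code paths: quadratic-space Gotoh DP in plain R,
# a naive per-frame codon scan, and exhaustive adjacency enumeration.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

randomDna <- function(n, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# best affine-gap alignment score by three-state DP (Gotoh).
# Convention: a gap of length L costs open + L * ext.
oracleAlignScore <- function(q, t, type = c("local", "global"),
                             mat = NULL, open = 11, ext = 1) {
    type <- match.arg(type)
    if (is.null(mat))
        mat <- cyanophot::substitutionMatrix("BLOSUM62")
    qs <- strsplit(q, "")[[1]]
    ts <- strsplit(t, "")[[1]]
    n <- length(qs)
    m <- length(ts)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)  # gap in target (consumes query)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes target)
    if (type == "global") {
        M[1, 1] <- 0
        for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
        for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
    } else {
        M[, 1] <- 0
        M[1, ] <- 0
    }
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- mat[qs[i], ts[j]]
            diag <- max(M[i, j], X[i, j], Y[i, j],
                        if (type == "local") 0 else NEG)
            M[i + 1, j + 1] <- diag + s
            X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                                   X[i, j + 1] - ext,
                                   Y[i, j + 1] - (open + ext))
            Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                                   Y[i + 1, j] - ext,
                                   X[i + 1, j] - (open + ext))
            if (type == "local")
                best <- max(best, M[i + 1, j + 1])
        }
    }
    if (type == "local")
        best
    else
        max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# naive six-frame ORF scan: walk codons of every frame, emit maximal
# stop-free runs of >= minAa codons with forward-strand coordinates.
oracleOrfs <- function(seq, minAa) {
    code <- Biostrings::getGeneticCode("11")
    revcomp <- function(x) {
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
    }
    n <- nchar(seq)
    out <- list()
    for (fr in c(1, 2, 3, -1, -2, -3)) {
        s <- if (fr > 0) seq else revcomp(seq)
        off <- abs(fr) - 1
        nCod <- (n - off) %/% 3
        if (nCod < 1) next
        runStart <- 0          # codon index of current stop-free run
        runProt <- character(0)
        flush <- function(endCodon) {
            if (length(runProt) >= minAa) {
                a <- off + 3 * runStart
                b <- off + 3 * endCodon
                out[[length(out) + 1]] <<- data.frame(
                    start = if (fr > 0) a else n - b,
                    end = if (fr > 0) b else n - a,
                    strand = if (fr > 0) "+" else "-",
                    frame = fr,
                    protein = paste(runProt, collapse = ""),
                    stringsAsFactors = FALSE)
            }
        }
        for (ci in seq_len(nCod)) {
            codon <- substr(s, off + 3 * (ci - 1) + 1, off + 3 * ci)
            aa <- if (grepl("[^ACGT]", codon)) "X"
                  else unname(code[codon])
            if (aa == "*") {
                flush(ci - 1)
                runStart <- ci
                runProt <- character(0)
            } else {
                runProt <- c(runProt, aa)
            }
        }
        flush(nCod)
    }
    if (length(out) == 0)
        return(data.frame(start = integer(0), end = integer(0),
                          strand = character(0), frame = integer(0),
                          protein = character(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[order(res$start, res$end, res$frame), ]
}

# exhaustive signed-adjacency breakpoint count between two signed
# permutations over the same element set
oracleBreakpoints <- function(a, b) {
    adj <- function(v) {
        if (length(v) < 2) return(list())
        lapply(seq_len(length(v) - 1), function(i) c(v[i], v[i + 1]))
    }
    adjB <- adj(b)
    count <- 0
    for (p in adj(a)) {
        hit <- FALSE
        for (q in adjB)
            if ((q[1] == p[1] && q[2] == p[2]) ||
                (q[1] == -p[2] && q[2] == -p[1])) hit <- TRUE
        if (!hit) count <- count + 1
    }
    count
}

# all signed permutations of 1..n as a list of integer vectors
allSignedPermutations <- function(n) {
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i]))
                out[[length(out) + 1]] <- c(v[i], rest)
        out
    }
    base <- perms(seq_len(n))
    out <- list()
    signs <- expand.grid(rep(list(c(1, -1)), n))
    for (p in base)
        for (r in seq_len(nrow(signs)))
            out[[length(out) + 1]] <- p * unlist(signs[r, ])
    out
}

# lightweight PgcInventory from a signed order vector (for synteny tests)
.pgcRefCache <- new.env()
inventoryFromOrder <- function(v, magId = "X") {
    if (is.null(.pgcRefCache$ref))
        .pgcRefCache$ref <- cyanophot::pgcReference()
    ref <- .pgcRefCache$ref
    idx <- abs(v)
    genes <- data.frame(symbol = ref$symbol[idx], class = ref$class[idx],
                        refIndex = idx, contigId = "c1",
                        start = seq_along(v) * 1000L,
                        end = seq_along(v) * 1000L + 500L,
                        strand = ifelse(v > 0, "+", "-"),
                        stringsAsFactors = FALSE)
    methods::new("PgcInventory", magId = magId, genes = genes,
                 completeness = length(v) / nrow(ref), hasPgc = FALSE,
                 contiguous = TRUE,
                 span = list(contigId = "c1", start = 1000L,
                             end = max(genes$end)),
                 orderVector = as.integer(v))
}
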