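## Independent oracles and small fixture builders used across tests.

## brute-force motif count: left-to-right greedy sliding scan
oracleMotifCount <- function(seq, motif) {
    n <- nchar(seq); w <- nchar(motif); i <- 1L; cnt <- 0L
    while (i + w - 1L <= n) {
        if (substr(seq, i, i + w - 1L) == motif) {
            cnt <- cnt + 1L; i <- i + w
        } else i <- i + 1L
    }
    cnt
}

## brute-force cluster partition: all-pairs links + graph components
oracleClusters <- function(chrom, rank, maxGap = 8L) {
    n <- length(rank)
    edges <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j && chrom[i] == chrom[j] &&
            abs(rank[i] - rank[j]) <= maxGap)
            edges <- rbind(edges, c(i, j))
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    keep <- comp %in% which(tabulate(comp) >= 2L)
    split(which(keep), comp[keep])
}

## exhaustive global affine alignment score by memoised recursion over
## (i, j, state); state: 0 = diagonal/open, 1 = gap in b, 2 = gap in a
oracleAlignScore <- function(a, b, match = 5, mismatch = -4,
                             gapOpen = 6, gapExt = 2) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    memo <- new.env(hash = TRUE)
    rec <- function(i, j, state) {
        key <- paste(i, j, state)
        if (!is.null(memo[[key]])) return(memo[[key]])
        if (i > n && j > m) return(0)
        best <- -Inf
        if (i <= n && j <= m) {
            s <- if (av[i] == bv[j]) match else mismatch
            best <- max(best, s + rec(i + 1L, j + 1L, 0L))
        }
        if (i <= n) {
            cost <- gapExt + if (state == 1L) 0 else gapOpen
            best <- max(best, -cost + rec(i + 1L, j, 1L))
        }
        if (j <= m) {
            cost <- gapExt + if (state == 2L) 0 else gapOpen
            best <- max(best, -cost + rec(i, j + 1L, 2L))
        }
        memo[[key]] <- best
        best
    }
    rec(1L, 1L, 0L)
}

## Jaccard index of two closed intervals
jaccardIv <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
    inter / (max(a2, b2) - min(a1, b1) + 1)
}

## random DNA string
randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

## match/mismatch substitution matrix over ACGT (+X) as AA letters
acgtMatrix <- function(match = 5, mismatch = -4) {
    l <- c("A", "C", "G", "T", "X")
    m <- matrix(mismatch, 5, 5, dimnames = list(l, l))
    diag(m) <- match
    m
}
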