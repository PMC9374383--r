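## Independent brute-force oracles and small fixtures shared across tests.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

## Slide a 23-nt window over the sequence and its reverse complement and keep
## windows ending in GG; coordinates are derived independently of the
## implementation (string positions only).
guideOracle <- function(seqchr) {
    L <- nchar(seqchr)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqchr)))
    hits <- list()
    if (L >= 23) {
        for (s in seq_len(L - 22)) {
            w <- substr(seqchr, s, s + 22)
            if (substr(w, 22, 23) == "GG")
                hits[[length(hits) + 1]] <-
                    data.frame(protospacer = substr(w, 1, 20), strand = "+",
                               cut_nt = s + 16)
            w <- substr(rc, s, s + 22)
            if (substr(w, 22, 23) == "GG")
                hits[[length(hits) + 1]] <-
                    data.frame(protospacer = substr(w, 1, 20), strand = "-",
                               cut_nt = L - s - 16)
        }
    }
    if (!length(hits))
        return(data.frame(protospacer = character(), strand = character(),
                          cut_nt = integer()))
    do.call(rbind, hits)
}

guideKey <- function(df) sort(paste(df$protospacer, df$strand, df$cut_nt))

randomCDS <- function(maxNt = 300) {
    L <- 3 * sample(2:(maxNt %/% 3), 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## Two-sided rank-sum p by full enumeration of rank assignments.
rankSumEnumerationP <- function(x, y) {
    n <- length(x)
    ranks <- rank(c(x, y))
    obs <- sum(ranks[seq_len(n)])
    all <- utils::combn(length(ranks), n)
    stat <- apply(all, 2, function(idx) sum(rank(c(x, y))[idx]))
    mu <- mean(stat)
    mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

## Minimal three-guide library (one target, one of each control) for scoring
## unit tests.
toyLibrary <- function() {
    tgt <- data.frame(guide_id = "t1", category = "target",
                      protospacer = "ACGTACGTACGTACGTACGT", pam = "AGG",
                      strand = "+", cut_nt = 17L, cut_aa = 6L,
                      gc_fraction = 0.5)
    GuideLibrary(rbind(
        tgt,
        data.frame(guide_id = c("p1", "n1"),
                   category = c("positive_control", "negative_control"),
                   protospacer = c("ACGTACGTACGTACGTACGA",
                                   "ACGTACGTACGTACGTACGC"),
                   pam = NA_character_, strand = ".", cut_nt = NA_integer_,
                   cut_aa = NA_integer_, gc_fraction = c(0.45, 0.55))))
}

## Standard simulated screen used by several suites: 260 targets + 22/41
## controls on a 499-codon protein (the screen's library make-up).
simLibrary <- function(seed = 1) simulateTilingLibrary(seed = seed)
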