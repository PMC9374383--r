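makeCounts <- function(m) {
    rownames(m) <- c("t1", "p1", "n1")[seq_len(nrow(m))]
    ScreenCounts(m)
}

test_that("frequencies normalise each sample to 1", {
    m <- matrix(c(10L, 30L, 60L), ncol = 1,
                dimnames = list(NULL, "d0_r1"))
    expect_equal(as.numeric(toFrequencies(m, pseudocount = 0)),
                 c(0.1, 0.3, 0.6))
    expect_equal(as.numeric(toFrequencies(
        matrix(c(0L, 0L, 100L), ncol = 1,
               dimnames = list(NULL, "d0_r1")), pseudocount = 1)),
        c(1, 1, 101) / 103)
    set.seed(1)
    big <- matrix(rpois(60, 40), 10,
                  dimnames = list(NULL, sprintf("d0_r%d", 1:6)))
    expect_equal(colSums(toFrequencies(big)), rep(1, 6),
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("an all-zero sample is an error naming the sample", {
    m <- matrix(c(1L, 2L, 0L, 0L), 2,
                dimnames = list(NULL, c("d0_r1", "d22_r1")))
    expect_error(toFrequencies(m, pseudocount = 0), "d22_r1")
})

test_that("representation QC applies the strict 5%-of-expected rule", {
    ## threshold for N = 323 is 0.05/323 ~ 1.548e-4
    expect_false(qcFilter(1.0e-4, nLibrary = 323))
    expect_true(qcFilter(2.0e-4, nLibrary = 323))
    ## N = 100: threshold 5e-4, strict inequality
    expect_equal(unname(qcFilter(c(4e-4, 6e-4), nLibrary = 100)),
                 c(FALSE, TRUE))
    expect_false(qcFilter(5e-4, nLibrary = 100))
    ## a uniform library passes everywhere
    expect_true(all(qcFilter(rep(1 / 50, 50), nLibrary = 50)))
    expect_error(qcFilter(0.1, nLibrary = 0), "positive")
})

test_that("the CRISPR score is the end/start frequency ratio per replicate", {
    f <- cbind(d0_r1 = c(0.10, 0.90), d22_r1 = c(0.01, 0.99))
    s <- crisprScore(f, day = c(0, 22), replicate = c(1, 1))
    expect_equal(unname(s[1, "score_r1"]), 0.1)  # 10-fold depletion
    ## unchanged frequency scores exactly 1
    f2 <- cbind(d0_r1 = c(0.5, 0.5), d22_r1 = c(0.5, 0.5))
    expect_equal(unname(crisprScore(f2, c(0, 22), c(1, 1))[, 1]), c(1, 1))
    ## day0 100/10,000 and day22 50/20,000 at pseudocount 0 -> 0.25
    counts <- cbind(d0_r1 = c(100L, 9900L), d22_r1 = c(50L, 19950L))
    fr <- toFrequencies(counts, pseudocount = 0)
    expect_equal(unname(crisprScore(fr, c(0, 22), c(1, 1))[1, 1]), 0.25)
})

test_that("a zero start frequency instructs the user to add a pseudocount", {
    f <- cbind(d0_r1 = c(0, 1), d22_r1 = c(0.5, 0.5))
    expect_error(crisprScore(f, c(0, 22), c(1, 1)), "pseudocount")
    expect_error(crisprScore(cbind(d22_r1 = 1), day = 22, replicate = 1),
                 "must be present")
})

test_that("replicates combine by median (default) or mean", {
    s <- matrix(c(0.1, 0.2, 0.4), 1)
    expect_equal(unname(combineReplicates(s)), 0.2)
    expect_equal(unname(combineReplicates(s, "mean")), 0.7 / 3)
    expect_equal(unname(combineReplicates(matrix(0.3, 1, 1))), 0.3)
    expect_equal(unname(combineReplicates(matrix(1, 1, 3))), 1)
    expect_error(combineReplicates(matrix(numeric(), 1, 0)), "replicate")
})

test_that("control anchoring fixes the control medians at 0 and -1", {
    x <- c(g1 = -2, n1 = 0.1, n2 = 0, n3 = -0.1, p1 = -0.9, p2 = -1,
           p3 = -1.1)
    z <- controlAnchorZ(x, c("n1", "n2", "n3"), c("p1", "p2", "p3"))
    expect_equal(unname(z[["g1"]]), -2)   # m_neg = 0, m_pos = -1, x = -2
    expect_equal(unname(z[["n2"]]), 0)    # at the negative-control median
    expect_equal(unname(z[["p2"]]), -1)   # at the positive-control median
    expect_equal(attr(z, "m_neg"), 0)
    expect_equal(attr(z, "m_pos"), -1)
})

test_that("degenerate or empty control sets are rejected", {
    x <- c(a = 1, n1 = 0, p1 = 0)
    expect_error(controlAnchorZ(x, "n1", "p1"), "degenerate")
    expect_error(controlAnchorZ(x, character(), "p1"), "control")
    expect_error(controlAnchorZ(x, "n1", "absent"), "control")
})

test_that("anchoring is exact for odd control sets and affine invariant", {
    set.seed(404)
    for (i in 1:25) {
        nNeg <- sample(c(3, 5, 7, 41), 1)
        nPos <- sample(c(3, 5, 7, 21), 1)
        x <- c(setNames(rnorm(nNeg), paste0("n", seq_len(nNeg))),
               setNames(rnorm(nPos, -1), paste0("p", seq_len(nPos))),
               setNames(rnorm(30), paste0("g", 1:30)))
        neg <- paste0("n", seq_len(nNeg))
        pos <- paste0("p", seq_len(nPos))
        z <- controlAnchorZ(x, neg, pos)
        expect_identical(median(unname(z[neg])), 0)
        expect_identical(median(unname(z[pos])), -1)
        ## increasing affine maps leave z unchanged
        a <- runif(1, 0.1, 10); b <- rnorm(1)
        z2 <- controlAnchorZ(a * x + b, neg, pos)
        expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
        ## monotone in the score when m_neg > m_pos
        if (attr(z, "m_neg") > attr(z, "m_pos")) {
            o <- order(x)
            expect_false(is.unsorted(z[o]))
        }
    }
})

test_that("scoreScreen runs the full pipeline deterministically", {
    lib <- simLibrary()
    truth <- trueModel(data.frame(name = "dom", start_aa = 200L,
                                  end_aa = 249L),
                       geneEssential = FALSE, aaLength = 499L)
    counts <- simulateScreenCounts(lib, truth, screenSimConfig(seed = 9))
    s1 <- scoreScreen(counts, lib)
    s2 <- scoreScreen(counts, lib)
    expect_identical(as.data.frame(s1), as.data.frame(s2))

    expect_s4_class(s1, "ScreenScores")
    expect_true(all(c("score_r1", "score_r2", "score_r3") %in% colnames(s1)))
    ## anchors are exact on the realised screen
    expect_equal(median(s1$z[s1$category == "negative_control" &
                                 s1$qc_pass]), 0)
    expect_equal(median(s1$z[s1$category == "positive_control" &
                                 s1$qc_pass]), -1)
    ## essential-gene controls are depleted, nonessential are not
    expect_lt(median(s1$combined_score[s1$category == "positive_control"]),
              0.5)
    expect_gt(anchorStats(s1)$separation, 10)
    ## z carries no value for QC failures (none expected here)
    expect_true(all(is.finite(s1$z[s1$qc_pass])))
})

test_that("day-12 samples are carried but ignored by default scoring", {
    lib <- simLibrary()
    truth <- trueModel(aaLength = 499L, geneEssential = TRUE)
    cfg <- screenSimConfig(seed = 5, days = c(0, 12, 22), depth = 2e5)
    counts <- simulateScreenCounts(lib, truth, cfg)
    expect_equal(sort(unique(colData(counts)$day)), c(0, 12, 22))
    s <- scoreScreen(counts, lib)
    ## scores reflect day 22 vs 0 only: recompute without day 12
    keep <- colData(counts)$day != 12
    s2 <- scoreScreen(ScreenCounts(assay(counts)[, keep]), lib)
    expect_equal(s$combined_score, s2$combined_score)
})

test_that("count tables round-trip through the TSV format", {
    lib <- simLibrary()
    counts <- simulateScreenCounts(lib, trueModel(aaLength = 499L),
                                   screenSimConfig(seed = 2, depth = 5e4))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeScreenCounts(counts, tsv)
    back <- readScreenCounts(tsv)
    expect_equal(assay(back), assay(counts))
    expect_equal(as.data.frame(colData(back)), as.data.frame(colData(counts)))
})
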