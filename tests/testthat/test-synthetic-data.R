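test_that("simulation configs validate their parameters", {
    expect_s4_class(screenSimConfig(), "ScreenSimConfig")
    expect_error(screenSimConfig(frameshiftProb = 1.5), "frameshiftProb")
    expect_error(screenSimConfig(sKo = -0.1), "selection")
    expect_error(screenSimConfig(depth = -1), "depth")
    expect_error(screenSimConfig(days = 22), "day 0")
    expect_error(screenSimConfig(overdispersion = 0), "overdispersion")
    expect_error(trueModel(data.frame(name = "d", start_aa = 10L,
                                      end_aa = 600L), aaLength = 499L),
                 "aaLength")
})

test_that("guide fitness follows category, gene and domain status", {
    lib <- simLibrary()
    cfg <- screenSimConfig()
    dom <- data.frame(name = "dom", start_aa = 200L, end_aa = 249L)

    ## gene nonessential: only in-frame domain lesions are selected against
    fit <- guideFitness(lib, trueModel(dom, FALSE, 499L), cfg)
    expect_true(all(fit$s_ko[fit$category == "positive_control"] == 1))
    expect_true(all(fit$s_ko[fit$category == "target"] == 0))
    expect_true(all(fit$s_if[fit$category != "target"] == 0))
    inDom <- !is.na(lib$cut_aa) & lib$cut_aa >= 200 & lib$cut_aa <= 249
    expect_equal(fit$s_if[match(lib$guide_id[inDom], fit$guide_id)],
                 rep(0.8, sum(inDom)))

    ## gene essential: frameshift is lethal for every target guide
    fit2 <- guideFitness(lib, trueModel(dom, TRUE, 499L), cfg)
    expect_true(all(fit2$s_ko[fit2$category == "target"] == 1))
})

test_that("screen count simulation is deterministic and depth-faithful", {
    lib <- simLibrary()
    truth <- trueModel(aaLength = 499L)
    cfg <- screenSimConfig(seed = 12, depth = 1e5)
    a <- simulateScreenCounts(lib, truth, cfg)
    b <- simulateScreenCounts(lib, truth, cfg)
    expect_identical(assay(a), assay(b))
    expect_true(all(colSums(assay(a)) == 1e5))
    expect_equal(dim(a), c(323L, 6L))

    ## a different seed gives different counts
    c2 <- simulateScreenCounts(lib, truth, screenSimConfig(seed = 13,
                                                          depth = 1e5))
    expect_false(identical(assay(a), assay(c2)))

    ## depth 0 -> all-zero counts
    z <- simulateScreenCounts(lib, truth, screenSimConfig(seed = 1,
                                                          depth = 0))
    expect_true(all(assay(z) == 0))

    ## the simulator does not disturb the caller's RNG stream
    set.seed(99); before <- rnorm(1)
    set.seed(99); invisible(simulateScreenCounts(lib, truth, cfg))
    expect_identical(rnorm(1), before)
})

test_that("with selection off every CRISPR score is centred on 1", {
    lib <- simLibrary()
    truth <- trueModel(aaLength = 499L)
    scores <- unlist(lapply(1:8, function(s) {
        cfg <- screenSimConfig(seed = s, sKo = 0, sDomain = 0, depth = 1e6)
        sc <- simulateScreenCounts(lib, truth, cfg)
        as.numeric(scoreScreen(sc, lib)$combined_score)
    }))
    se <- sd(scores) / sqrt(length(scores))
    expect_lt(abs(mean(scores) - 1), 3 * se + 1e-3)
    expect_equal(median(scores), 1, tolerance = 0.02)
})

test_that("overdispersion widens the count spread at fixed expectation", {
    lib <- simLibrary()
    truth <- trueModel(aaLength = 499L)
    plain <- simulateScreenCounts(lib, truth,
                                  screenSimConfig(seed = 4, depth = 1e6))
    wide <- simulateScreenCounts(
        lib, truth, screenSimConfig(seed = 4, depth = 1e6,
                                    overdispersion = 1e4))
    relSpread <- function(x) {
        m <- assay(x)[, c("d0_r1", "d0_r2", "d0_r3")]
        keep <- rowMeans(m) > 0
        mean(apply(m[keep, ], 1, sd) / rowMeans(m[keep, ]))
    }
    expect_gt(relSpread(wide), 2 * relSpread(plain))
})

test_that("a lethal domain guide in an essential gene is driven below z = -1", {
    lib <- simLibrary()
    dom <- data.frame(name = "dom", start_aa = 200L, end_aa = 249L)
    truth <- trueModel(dom, geneEssential = TRUE, aaLength = 499L)
    cfg <- screenSimConfig(seed = 21, sKo = 1, sDomain = 1, depth = 1e7)
    sc <- scoreScreen(simulateScreenCounts(lib, truth, cfg), lib)
    inDom <- !is.na(lib$cut_aa) & lib$cut_aa >= 200 & lib$cut_aa <= 249
    zDom <- sc$z[match(lib$guide_id[inDom], sc$guide_id)]
    expect_true(all(zDom[!is.na(zDom)] <= -1))
})

test_that("expectedAnchoredZ matches the realised anchored depletion", {
    lib <- simLibrary()
    dom <- data.frame(name = "dom", start_aa = 200L, end_aa = 249L)
    truth <- trueModel(dom, geneEssential = FALSE, aaLength = 499L)
    cfg <- screenSimConfig(seed = 31)
    sc <- scoreScreen(simulateScreenCounts(lib, truth, cfg), lib)
    inDom <- !is.na(lib$cut_aa) & lib$cut_aa >= 205 & lib$cut_aa <= 244
    zDom <- sc$z[match(lib$guide_id[inDom], sc$guide_id)]
    expect_equal(mean(zDom), expectedAnchoredZ(cfg), tolerance = 0.05)
})

test_that("reporter event simulation is deterministic with known truth", {
    conds <- data.frame(drug = c("drug", "DMSO"), r = c(4, 1))
    a <- simulateReporterEvents(conds, nEvents = 500, seed = 6)
    b <- simulateReporterEvents(conds, nEvents = 500, seed = 6)
    expect_identical(a, b)
    expect_equal(mean(a$live), 0.95, tolerance = 0.05)
    expect_error(simulateReporterEvents(data.frame(drug = "x", r = -1)),
                 "r must be")
    expect_error(simulateReporterEvents(data.frame(drug = "x", deg = 2)),
                 "degraded")

    ## full degradation drives the ratio to zero as noise vanishes
    degEv <- simulateReporterEvents(
        data.frame(drug = "drug", deg = 1), nEvents = 200,
        noiseSigma = 0, seed = 7, baselineRatio = 1)
    expect_true(all(degEv$gfp == 0))

    ## equal multipliers in both arms -> fold change 1 in expectation
    nullEv <- simulateReporterEvents(
        data.frame(drug = c("drug", "DMSO"), r = c(2, 2)),
        nEvents = 8000, seed = 8)
    expect_equal(reporterFoldChanges(mfiRatio(nullEv))$fold_change, 1,
                 tolerance = 0.05)
})

test_that("recoveryReport scores calls against the ground truth", {
    truth <- trueModel(data.frame(name = "dom", start_aa = 100L,
                                  end_aa = 150L), FALSE, 499L)
    perfect <- data.frame(start_aa = 100L, end_aa = 150L)
    r <- recoveryReport(perfect, truth)
    expect_equal(r$domains$best_jaccard, 1.0)
    expect_true(r$domains$detected)
    expect_equal(r$false_positives, 0L)

    none <- recoveryReport(perfect[0, ], truth)
    expect_false(none$domains$detected)

    near <- recoveryReport(data.frame(start_aa = 95L, end_aa = 155L), truth)
    expect_equal(near$domains$best_jaccard, 51 / 61)

    stray <- recoveryReport(data.frame(start_aa = c(100L, 300L),
                                       end_aa = c(150L, 320L)), truth)
    expect_equal(stray$false_positives, 1L)
})

test_that("the simulated library reproduces the screen's composition", {
    lib <- simLibrary(seed = 3)
    expect_equal(nrow(lib), 323L)
    expect_equal(aaLength(lib), 499L)
    tgt <- lib[lib$category == "target", ]
    expect_equal(anyDuplicated(tgt$protospacer), 0L)
    ## tiling density supports ~1 guide per 2-3 codons
    gaps <- diff(sort(unique(tgt$cut_aa)))
    expect_lte(median(gaps), 3)
    expect_gt(mean(gaps <= 8), 0.9)
    ## same seed, same library
    expect_identical(as.data.frame(simLibrary(seed = 3)), as.data.frame(lib))
})
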