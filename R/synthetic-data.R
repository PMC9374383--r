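## Ground-truth simulation: pooled tiling-screen count tables under a
## two-outcome (frameshift / in-frame) exponential-growth selection model, and
## dual-fluorescence reporter event tables.

#' ScreenSimConfig: pooled-screen simulation settings
#'
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#' @slot nReplicates independent screen replicates (default 3).
#' @slot depth sequencing reads per sample (default 3.2e6, about 2000x
#'   representation for a 323-guide library).
#' @slot days sampling days (default 0 and 22).
#' @slot doublingsPerDay population doublings per day for an unedited cell
#'   (default 1; 22 days then allows >1e6-fold expansion).
#' @slot frameshiftProb fraction of edited cells carrying a frameshift
#'   (complete loss-of-function) allele; the remainder carry an in-frame
#'   lesion (default 2/3, the standard indel-outcome assumption).
#' @slot sKo selection coefficient of complete knockout when the gene is
#'   essential (1 = lethal; default 1).
#' @slot sDomain selection coefficient of an in-frame lesion inside an
#'   essential domain (default 0.8).
#' @slot abundanceSigma lognormal sdlog of the plasmid-pool abundances
#'   (default 0.5).
#' @slot overdispersion Dirichlet-multinomial concentration; `NA` (default)
#'   uses plain multinomial sampling.
#' @export
setClass("ScreenSimConfig",
         slots = c(seed = "integer", nReplicates = "integer",
                   depth = "numeric", days = "numeric",
                   doublingsPerDay = "numeric", frameshiftProb = "numeric",
                   sKo = "numeric", sDomain = "numeric",
                   abundanceSigma = "numeric", overdispersion = "numeric"))

setValidity("ScreenSimConfig", function(object) {
    inUnit <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
    if (!inUnit(object@frameshiftProb))
        return("frameshiftProb must lie in [0, 1]")
    if (!inUnit(object@sKo) || !inUnit(object@sDomain))
        return("selection coefficients must lie in [0, 1]")
    if (object@depth < 0) return("depth must be non-negative")
    if (object@nReplicates < 1L) return("nReplicates must be >= 1")
    if (length(object@days) < 2L || !0 %in% object@days)
        return("days must include day 0 and at least one later day")
    if (object@abundanceSigma < 0) return("abundanceSigma must be >= 0")
    if (!is.na(object@overdispersion) && object@overdispersion <= 0)
        return("overdispersion concentration must be positive")
    TRUE
})

#' Construct a ScreenSimConfig
#'
#' @param seed,nReplicates,depth,days,doublingsPerDay,frameshiftProb,sKo,sDomain,abundanceSigma,overdispersion
#'   see [ScreenSimConfig-class] for meanings and defaults.
#' @return A validated [ScreenSimConfig-class].
#' @export
screenSimConfig <- function(seed = 1L, nReplicates = 3L, depth = 3.2e6,
                            days = c(0, 22), doublingsPerDay = 1,
                            frameshiftProb = 2 / 3, sKo = 1, sDomain = 0.8,
                            abundanceSigma = 0.5,
                            overdispersion = NA_real_) {
    new("ScreenSimConfig", seed = as.integer(seed),
        nReplicates = as.integer(nReplicates), depth = as.numeric(depth),
        days = sort(as.numeric(days)),
        doublingsPerDay = as.numeric(doublingsPerDay),
        frameshiftProb = as.numeric(frameshiftProb), sKo = as.numeric(sKo),
        sDomain = as.numeric(sDomain),
        abundanceSigma = as.numeric(abundanceSigma),
        overdispersion = as.numeric(overdispersion))
}

setMethod("show", "ScreenSimConfig", function(object) {
    cat("ScreenSimConfig: ", object@nReplicates, " replicates, days ",
        paste(object@days, collapse = "/"), ", depth ",
        format(object@depth, big.mark = ","), "\n  frameshiftProb = ",
        signif(object@frameshiftProb, 3), ", sKo = ", object@sKo,
        ", sDomain = ", object@sDomain, ", abundanceSigma = ",
        object@abundanceSigma, ", seed = ", object@seed, "\n", sep = "")
})

#' TrueModel: simulation ground truth
#'
#' @slot domains `data.frame` of essential-domain intervals (`name`,
#'   `start_aa`, `end_aa`, optionally `class`); may be empty.
#' @slot geneEssential whether frameshift anywhere in the gene is subject to
#'   the knockout selection coefficient.
#' @slot aaLength protein length in codons.
#' @export
setClass("TrueModel",
         slots = c(domains = "data.frame", geneEssential = "logical",
                   aaLength = "integer"))

setValidity("TrueModel", function(object) {
    d <- object@domains
    if (nrow(d)) {
        if (!all(c("name", "start_aa", "end_aa") %in% colnames(d)))
            return("domains needs columns name, start_aa, end_aa")
        if (any(d$start_aa < 1L | d$end_aa < d$start_aa |
                    d$end_aa > object@aaLength))
            return("domain intervals must satisfy 1 <= start <= end <= aaLength")
    }
    if (object@aaLength < 1L) return("aaLength must be positive")
    TRUE
})

#' Construct a TrueModel
#'
#' @param domains essential-domain `data.frame` (`name`, `start_aa`,
#'   `end_aa`); default none.
#' @param geneEssential logical (default `FALSE`).
#' @param aaLength protein length in codons.
#' @return A [TrueModel-class].
#' @export
trueModel <- function(domains = NULL, geneEssential = FALSE, aaLength) {
    if (is.null(domains))
        domains <- data.frame(name = character(), start_aa = integer(),
                              end_aa = integer())
    new("TrueModel", domains = as.data.frame(domains),
        geneEssential = geneEssential, aaLength = as.integer(aaLength))
}

#' @rdname aaLength
setMethod("aaLength", "TrueModel", function(x) x@aaLength)

setMethod("show", "TrueModel", function(object) {
    cat("TrueModel: ", object@aaLength, " aa, gene ",
        if (object@geneEssential) "essential" else "nonessential",
        ", ", nrow(object@domains), " essential domain(s)\n", sep = "")
})

## run expr with a private, restored RNG stream
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = .GlobalEnv)) {
        old <- get(".Random.seed", envir = .GlobalEnv)
        on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    } else {
        on.exit(rm(list = ".Random.seed", envir = .GlobalEnv))
    }
    set.seed(seed)
    expr
}

#' Per-guide true fitness under a simulation model
#'
#' Summarises the selection coefficients each guide experiences: `s_ko`
#' applies to the frameshift outcome (knockout) and `s_if` to the in-frame
#' outcome. Target guides take `s_ko` only if the gene is essential and
#' `s_if = sDomain` only if their cut falls inside an essential domain;
#' positive controls always take `s_ko`; negative controls are neutral.
#'
#' @param library a [GuideLibrary-class].
#' @param truth a [TrueModel-class].
#' @param cfg a [ScreenSimConfig-class].
#' @return `data.frame` with `guide_id`, `category`, `s_ko`, `s_if` and the
#'   end-of-screen growth weight `w_end`.
#' @export
guideFitness <- function(library, truth, cfg) {
    lib <- as.data.frame(library)
    inDomain <- rep(FALSE, nrow(lib))
    if (nrow(truth@domains)) {
        for (i in seq_len(nrow(truth@domains)))
            inDomain <- inDomain |
                (!is.na(lib$cut_aa) &
                     lib$cut_aa >= truth@domains$start_aa[i] &
                     lib$cut_aa <= truth@domains$end_aa[i])
    }
    s_ko <- ifelse(lib$category == "positive_control", cfg@sKo,
            ifelse(lib$category == "target" & truth@geneEssential,
                   cfg@sKo, 0))
    s_if <- ifelse(lib$category == "target" & inDomain, cfg@sDomain, 0)
    dt <- cfg@doublingsPerDay * max(cfg@days)
    f <- cfg@frameshiftProb
    data.frame(guide_id = lib$guide_id, category = lib$category,
               s_ko = s_ko, s_if = s_if,
               w_end = f * 2^(dt * (1 - s_ko)) + (1 - f) * 2^(dt * (1 - s_if)))
}

growthWeight <- function(fitness, cfg, day) {
    dt <- cfg@doublingsPerDay * day
    f <- cfg@frameshiftProb
    f * 2^(dt * (1 - fitness$s_ko)) + (1 - f) * 2^(dt * (1 - fitness$s_if))
}

#' Simulate pooled tiling-screen read counts
#'
#' Plasmid abundances are drawn lognormal(0, `abundanceSigma`) and
#' normalized. Each edited cell carries either a frameshift allele (with
#' probability `frameshiftProb`, fitness `1 - s_ko` when the gene is
#' essential) or an in-frame lesion (fitness `1 - sDomain` inside an
#' essential domain); populations grow exponentially at `doublingsPerDay`,
#' so a guide's expected share at day t is proportional to
#' `a_g * (f * 2^(dt*(1-s_ko)) + (1-f) * 2^(dt*(1-s_if)))`. Counts are drawn
#' per sample as multinomial(depth) (Dirichlet-multinomial when
#' `overdispersion` is set), independently per replicate.
#'
#' @param library a [GuideLibrary-class].
#' @param truth a [TrueModel-class] with coordinates consistent with the
#'   library.
#' @param cfg a [ScreenSimConfig-class].
#' @return A [ScreenCounts-class] with one column per (day, replicate).
#' @export
simulateScreenCounts <- function(library, truth, cfg) {
    stopifnot(is(library, "GuideLibrary"), is(truth, "TrueModel"),
              is(cfg, "ScreenSimConfig"))
    validObject(cfg)
    validObject(truth)
    fitness <- guideFitness(library, truth, cfg)
    n <- nrow(fitness)
    depth <- as.integer(round(cfg@depth))
    withSeed(cfg@seed, {
        a <- rlnorm(n, 0, cfg@abundanceSigma)
        a <- a / sum(a)
        cols <- list()
        for (day in cfg@days) {
            p <- a * growthWeight(fitness, cfg, day)
            p <- p / sum(p)
            for (rep in seq_len(cfg@nReplicates)) {
                q <- if (!is.na(cfg@overdispersion)) {
                    g <- rgamma(n, shape = cfg@overdispersion * p)
                    g / sum(g)
                } else p
                cols[[sprintf("d%s_r%d", format(day, trim = TRUE), rep)]] <-
                    if (depth > 0L) rmultinom(1L, depth, q)[, 1L] else
                        integer(n)
            }
        }
        m <- do.call(cbind, cols)
        rownames(m) <- fitness$guide_id
        ScreenCounts(m)
    })
}

#' Simulate dual-fluorescence reporter events
#'
#' Per-cell BFP intensities are lognormal; GFP is proportional to BFP times
#' the condition's true GFP/BFP scale with independent multiplicative
#' lognormal noise: `gfp = r * (1 - deg) * baselineRatio * bfp *
#' lognormal(0, noiseSigma)`. For a readthrough reporter `r` is the
#' readthrough multiplier relative to the vehicle baseline (`deg = 0`); for a
#' degradation reporter `deg` is the degraded fraction of the fusion (set
#' `baselineRatio` to the intact fusion's GFP/BFP ratio). A configurable
#' fraction of events is live-gated.
#'
#' @param conditions `data.frame` with one row per condition; the columns
#'   among `drug`, `dose_um`, `time_h`, `construct`, `stop_codon`,
#'   `replicate` label the condition, and optional numeric columns `r`
#'   (default 1) and `deg` (default 0) set its ground truth.
#' @param nEvents events per condition (single value or per-row vector).
#' @param noiseSigma sdlog of both lognormal noise terms (default 0.5).
#' @param bfpMeanLog mean of log BFP (default `log(1000)` arbitrary units).
#' @param baselineRatio GFP/BFP scale at `r = 1`, `deg = 0` (default 0.05, a
#'   basal-leak readthrough reporter).
#' @param liveFraction fraction of events passing the live gate (default
#'   0.95).
#' @param seed RNG seed.
#' @return `data.frame` of events: condition columns plus `gfp`, `bfp`,
#'   `live`.
#' @export
simulateReporterEvents <- function(conditions, nEvents = 5000,
                                   noiseSigma = 0.5,
                                   bfpMeanLog = log(1000),
                                   baselineRatio = 0.05,
                                   liveFraction = 0.95, seed = 1) {
    conditions <- as.data.frame(conditions)
    if (!"r" %in% colnames(conditions)) conditions$r <- 1
    if (!"deg" %in% colnames(conditions)) conditions$deg <- 0
    if (any(conditions$r < 0))
        stop("readthrough multipliers r must be >= 0", call. = FALSE)
    if (any(conditions$deg < 0 | conditions$deg > 1))
        stop("degraded fractions must lie in [0, 1]", call. = FALSE)
    if (noiseSigma < 0 || baselineRatio < 0 || any(nEvents < 1))
        stop("noiseSigma and baselineRatio must be non-negative and ",
             "nEvents >= 1", call. = FALSE)
    nEvents <- rep_len(as.integer(nEvents), nrow(conditions))
    condCols <- setdiff(colnames(conditions), c("r", "deg"))
    withSeed(seed, {
        out <- lapply(seq_len(nrow(conditions)), function(i) {
            n <- nEvents[i]
            bfp <- rlnorm(n, bfpMeanLog, noiseSigma)
            gfp <- conditions$r[i] * (1 - conditions$deg[i]) *
                baselineRatio * bfp * rlnorm(n, 0, noiseSigma)
            cbind(conditions[rep(i, n), condCols, drop = FALSE],
                  data.frame(gfp = gfp, bfp = bfp,
                             live = runif(n) < liveFraction))
        })
        out <- do.call(rbind, out)
        rownames(out) <- NULL
        out
    })
}

#' Simulate a tiling guide library
#'
#' Generates a random GC-biased coding sequence, enumerates its guides with
#' [enumerateGuides()], thins them to an (approximately evenly spaced)
#' target count, and adds random-sequence control guides — reproducing the
#' make-up of a domain-scanning screen library (by default 260 target guides
#' over a 499-codon protein plus 22 essential-gene and 41 nonessential
#' controls).
#'
#' @param aaLength protein length in codons including the stop (default
#'   499).
#' @param nTargets number of distinct target guides to keep (default 260).
#' @param nEssential,nNonessential numbers of positive/negative control
#'   guides (defaults 22 and 41).
#' @param gc GC content of the simulated CDS (default 0.62; PAM-dense, as in
#'   a GC-rich transcript).
#' @param seed RNG seed.
#' @return A [GuideLibrary-class].
#' @export
simulateTilingLibrary <- function(aaLength = 499, nTargets = 260,
                                  nEssential = 22, nNonessential = 41,
                                  gc = 0.62, seed = 1) {
    L <- as.integer(aaLength) * 3L
    withSeed(seed, {
        targets <- NULL
        for (attempt in 1:25) {
            probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                       T = (1 - gc) / 2)
            nt <- sample(names(probs), L, replace = TRUE, prob = probs)
            nt[1:3] <- c("A", "T", "G")
            nt[(L - 2L):L] <- c("T", "A", "A")
            cds <- codingSequence(sprintf("sim%d", attempt),
                                  paste(nt, collapse = ""))
            g <- enumerateGuides(cds, collapseDuplicates = TRUE)
            if (nrow(g) >= nTargets) { targets <- g; break }
        }
        if (is.null(targets))
            stop("could not generate enough PAM sites; raise gc or aaLength",
                 call. = FALSE)
        if (nrow(targets) > nTargets) {
            keep <- round(seq(1L, nrow(targets), length.out = nTargets))
            targets <- targets[keep, ]
        }
        randomGuide <- function(n)
            vapply(seq_len(n), function(i)
                paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                      collapse = ""), character(1))
        assembleLibrary(targets,
                        essentialControls = data.frame(
                            guide_id = sprintf("ess_%02d", seq_len(nEssential)),
                            protospacer = randomGuide(nEssential)),
                        nonessentialControls = data.frame(
                            guide_id = sprintf("non_%02d",
                                               seq_len(nNonessential)),
                            protospacer = randomGuide(nNonessential)))
    })
}

#' Expected anchored z of a domain guide under the simulation model
#'
#' Deterministic (infinite-depth) control-anchored z score of a target guide
#' whose cut lies inside an essential domain, given the two-outcome growth
#' model: relative to neutral guides the domain guide retains weight
#' `f * 2^(-dt*sKo*essential) + (1-f) * 2^(-dt*sDomain)` while the positive
#' controls retain `f * 2^(-dt*sKo) + (1-f)`. Because the frameshift fraction
#' `f` is unaffected by an in-frame-only lesion, this also gives the
#' attainable depletion ceiling for in-frame-isolated signal
#' (`geneEssential = FALSE`): segment-calling thresholds for such analyses
#' should be matched to it (e.g. half the ceiling) rather than to the
#' knockout anchor at -1.
#'
#' @param cfg a [ScreenSimConfig-class].
#' @param sDomain,sKo override the config's selection coefficients.
#' @param geneEssential whether the frameshift outcome is lethal for target
#'   guides (default `FALSE`).
#' @return The expected z (log10 anchoring; 0 = neutral, -1 = positive
#'   controls).
#' @export
expectedAnchoredZ <- function(cfg, sDomain = cfg@sDomain, sKo = cfg@sKo,
                              geneEssential = FALSE) {
    dt <- cfg@doublingsPerDay * max(cfg@days)
    f <- cfg@frameshiftProb
    wDom <- f * 2^(-dt * sKo * as.numeric(geneEssential)) +
        (1 - f) * 2^(-dt * sDomain)
    wPos <- f * 2^(-dt * sKo) + (1 - f)
    log10(wDom) / (-log10(wPos))
}

#' Compare called segments with simulation ground truth
#'
#' For each true essential domain, reports the best Jaccard index achieved by
#' any called segment and whether the domain counts as detected
#' (`best_jaccard >= jaccardMin`); segments matching no domain at that level
#' are counted as false positives.
#'
#' @param segments segment table from [callEssentialSegments()].
#' @param truth a [TrueModel-class].
#' @param jaccardMin detection threshold on the Jaccard index (default 0.5).
#' @return A list with `domains` (`name`, `best_jaccard`, `detected`) and
#'   `false_positives` (count).
#' @export
recoveryReport <- function(segments, truth, jaccardMin = 0.5) {
    dom <- truth@domains
    segJac <- rep(0, nrow(segments))
    rows <- lapply(seq_len(nrow(dom)), function(i) {
        jac <- if (nrow(segments))
            intervalOverlap(segments$start_aa, segments$end_aa,
                            dom$start_aa[i], dom$end_aa[i])$jaccard
        else numeric()
        best <- if (length(jac)) max(jac) else 0
        segJac <<- pmax(segJac, jac)
        data.frame(name = dom$name[i], best_jaccard = best,
                   detected = best >= jaccardMin)
    })
    domains <- if (length(rows)) do.call(rbind, rows) else
        data.frame(name = character(), best_jaccard = numeric(),
                   detected = logical())
    list(domains = domains,
         false_positives = sum(segJac < jaccardMin))
}
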