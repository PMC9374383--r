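## Dropout scoring: read frequencies, representation QC, per-replicate CRISPR
## scores (end/start frequency ratio), replicate combination and
## control-anchored z normalization.

#' Convert guide read counts to within-sample frequencies
#'
#' Each guide's frequency is its (pseudocounted) read number divided by the
#' total reads in the sample, so every sample column sums to 1.
#'
#' @param counts a [ScreenCounts-class] or a guide-by-sample count matrix.
#' @param pseudocount non-negative value added to every count before
#'   normalization (default 1; day-22 zeros are expected for guides in
#'   essential domains).
#' @return Numeric matrix of frequencies with the same dimnames as the counts.
#' @examples
#' toFrequencies(matrix(c(10, 30, 60), dimnames = list(NULL, "d0_r1")),
#'               pseudocount = 0)
#' @export
toFrequencies <- function(counts, pseudocount = 1) {
    m <- if (is(counts, "ScreenCounts")) assay(counts, "counts") else
        as.matrix(counts)
    stopifnot(pseudocount >= 0)
    m <- m + pseudocount
    totals <- colSums(m)
    bad <- totals <= 0
    if (any(bad))
        stop("sample(s) with zero total count: ",
             paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
    sweep(m, 2L, totals, "/")
}

#' Representation QC on start-of-screen frequencies
#'
#' A guide passes QC iff its mean day-0 frequency is strictly greater than
#' `minFractionOfExpected` times the expected uniform frequency `1/nLibrary`
#' (the ">5% of expected frequency" rule).
#'
#' @param day0Frequencies numeric matrix (guides x day-0 replicates) or
#'   vector of day-0 frequencies.
#' @param nLibrary library size N used to form the expected frequency 1/N.
#' @param minFractionOfExpected fraction of the expected frequency required
#'   (default 0.05).
#' @return Named logical vector of QC flags.
#' @export
qcFilter <- function(day0Frequencies, nLibrary,
                     minFractionOfExpected = 0.05) {
    nLibrary <- as.integer(nLibrary)
    if (is.na(nLibrary) || nLibrary < 1L)
        stop("nLibrary must be a positive integer", call. = FALSE)
    f <- if (is.matrix(day0Frequencies)) rowMeans(day0Frequencies) else
        day0Frequencies
    f > minFractionOfExpected / nLibrary
}

#' Per-replicate CRISPR scores
#'
#' The CRISPR score of a guide is the ratio of its read frequency at the end
#' of the screen to its frequency at the start, computed per replicate
#' (matched by replicate index). A score of 0.1 indicates a 10-fold depletion.
#'
#' @param frequencies guide-by-sample frequency matrix from
#'   [toFrequencies()].
#' @param day,replicate numeric vectors describing each column (as in the
#'   `colData` of a [ScreenCounts-class]).
#' @param endDay,startDay the two timepoints compared (defaults 22 and 0).
#' @return Matrix of scores, one column per replicate (`score_r<k>`).
#' @export
crisprScore <- function(frequencies, day, replicate, endDay = 22,
                        startDay = 0) {
    stopifnot(ncol(frequencies) == length(day),
              length(day) == length(replicate))
    reps <- sort(unique(replicate[day == endDay]))
    if (!length(reps) || !all(reps %in% replicate[day == startDay]))
        stop("both day ", startDay, " and day ", endDay,
             " must be present for each replicate", call. = FALSE)
    score <- vapply(reps, function(r) {
        i0 <- which(day == startDay & replicate == r)
        i1 <- which(day == endDay & replicate == r)
        f0 <- frequencies[, i0]
        if (any(f0 == 0))
            stop("zero start-of-screen frequency; rerun toFrequencies() ",
                 "with a positive pseudocount", call. = FALSE)
        frequencies[, i1] / f0
    }, numeric(nrow(frequencies)))
    dimnames(score) <- list(rownames(frequencies),
                            sprintf("score_r%d", reps))
    score
}

#' Combine per-replicate scores
#'
#' @param scores matrix of per-replicate scores (guides x replicates).
#' @param method `"median"` (default; robust to one failed replicate) or
#'   `"mean"`.
#' @return Named numeric vector of combined scores.
#' @export
combineReplicates <- function(scores, method = c("median", "mean")) {
    method <- match.arg(method)
    scores <- as.matrix(scores)
    if (ncol(scores) < 1L)
        stop("at least one replicate is required", call. = FALSE)
    apply(scores, 1L, method)
}

#' Control-anchored z scores
#'
#' Rescales (log) scores so that the median of the negative
#' (nonessential-targeting) controls maps to 0 and the median of the positive
#' (essential-gene) controls maps to -1:
#' `z = (x - m_neg) / (m_neg - m_pos)`. Both anchors hold exactly by
#' construction, and z is invariant under any increasing affine transform of
#' the scores.
#'
#' @param logScores named numeric vector of (log) combined scores; `NA`
#'   entries (e.g. QC failures) are propagated and excluded from the control
#'   medians.
#' @param negativeIds,positiveIds guide ids of the negative and positive
#'   control sets.
#' @return Numeric vector of z scores (same names as `logScores`) with
#'   attributes `m_neg` and `m_pos`.
#' @export
controlAnchorZ <- function(logScores, negativeIds, positiveIds) {
    xn <- logScores[intersect(negativeIds, names(logScores))]
    xp <- logScores[intersect(positiveIds, names(logScores))]
    xn <- xn[is.finite(xn)]
    xp <- xp[is.finite(xp)]
    if (!length(xn) || !length(xp))
        stop("both control sets need at least one scored guide",
             call. = FALSE)
    m_neg <- median(xn)
    m_pos <- median(xp)
    if (m_neg == m_pos)
        stop("degenerate controls: negative and positive control medians ",
             "coincide, so the z scale is undefined", call. = FALSE)
    z <- (logScores - m_neg) / (m_neg - m_pos)
    attr(z, "m_neg") <- m_neg
    attr(z, "m_pos") <- m_pos
    z
}

#' Control separation (screen quality)
#'
#' An SSMD-like statistic for how well the essential and nonessential control
#' guides separate on the log-score scale:
#' `(m_neg - m_pos) / sqrt(mad_neg^2 + mad_pos^2)`. Values well above ~2
#' indicate an informative screen; near 0, the anchored z scale is dominated
#' by noise and depleted-segment calls are not meaningful.
#'
#' @param logScores named numeric vector of log scores.
#' @param negativeIds,positiveIds control guide ids.
#' @return A single numeric separation value (`Inf` if both control sets are
#'   exactly constant but distinct).
#' @export
controlSeparation <- function(logScores, negativeIds, positiveIds) {
    xn <- logScores[intersect(negativeIds, names(logScores))]
    xp <- logScores[intersect(positiveIds, names(logScores))]
    xn <- xn[is.finite(xn)]
    xp <- xp[is.finite(xp)]
    if (!length(xn) || !length(xp))
        return(NA_real_)
    denom <- sqrt(mad(xn)^2 + mad(xp)^2)
    delta <- median(xn) - median(xp)
    if (denom == 0) return(sign(delta) * Inf)
    delta / denom
}

#' Score a tiling screen end to end
#'
#' Runs the full dropout-scoring pipeline on a count table: frequencies with
#' pseudocount, day-0 representation QC, per-replicate CRISPR scores,
#' replicate combination, log transform, and control anchoring. Guides
#' failing QC receive no z and are excluded from the control medians.
#' Timepoints other than `startDay`/`endDay` (e.g. a day-12 sample) are
#' carried in the input but ignored by scoring.
#'
#' @param counts a [ScreenCounts-class].
#' @param library the matching [GuideLibrary-class]; guide ids must cover the
#'   count table rows.
#' @param pseudocount see [toFrequencies()].
#' @param qcFraction see [qcFilter()] (`minFractionOfExpected`).
#' @param combine replicate combination method, `"median"` or `"mean"`.
#' @param scale `"log10"` (default) computes z on log10 combined scores,
#'   making depletion and enrichment symmetric; `"linear"` anchors the raw
#'   ratio instead.
#' @param endDay,startDay timepoints compared (defaults 22 and 0).
#' @return A [ScreenScores-class]; see [anchorStats()] for the anchoring
#'   summary.
#' @examples
#' lib <- simulateTilingLibrary(aaLength = 120, nTargets = 40, seed = 1)
#' truth <- trueModel(aaLength = 120)
#' cfg <- screenSimConfig(seed = 1, depth = 1e5)
#' sc <- simulateScreenCounts(lib, truth, cfg)
#' scoreScreen(sc, lib)
#' @export
scoreScreen <- function(counts, library, pseudocount = 1, qcFraction = 0.05,
                        combine = c("median", "mean"),
                        scale = c("log10", "linear"),
                        endDay = 22, startDay = 0) {
    combine <- match.arg(combine)
    scale <- match.arg(scale)
    stopifnot(is(counts, "ScreenCounts"), is(library, "GuideLibrary"))
    ids <- rownames(counts)
    if (!all(ids %in% library$guide_id))
        stop("count table contains guide ids absent from the library",
             call. = FALSE)
    lib <- as.data.frame(library)
    category <- setNames(lib$category, lib$guide_id)[ids]

    freq <- toFrequencies(counts, pseudocount)
    cd <- colData(counts)
    qc <- qcFilter(freq[, cd$day == startDay, drop = FALSE],
                   nLibrary = nrow(library),
                   minFractionOfExpected = qcFraction)
    score <- crisprScore(freq, cd$day, cd$replicate, endDay, startDay)
    combined <- combineReplicates(score, combine)
    logScore <- if (scale == "log10") log10(combined) else combined

    x <- ifelse(qc, logScore, NA_real_)
    names(x) <- ids
    negIds <- ids[category == "negative_control"]
    posIds <- ids[category == "positive_control"]
    z <- controlAnchorZ(x, negIds, posIds)
    sep <- controlSeparation(x, negIds, posIds)

    out <- DataFrame(guide_id = ids, category = category, qc_pass = qc,
                     score, combined_score = combined, log_score = logScore,
                     z = as.numeric(z), row.names = ids)
    out <- new("ScreenScores", out)
    metadata(out) <- list(
        m_neg = attr(z, "m_neg"), m_pos = attr(z, "m_pos"),
        separation = sep, pseudocount = pseudocount,
        qc_fraction = qcFraction, combine = combine, scale = scale,
        end_day = endDay, start_day = startDay)
    out
}

#' Read and write screen count and score TSVs
#'
#' Counts TSV: a `guide_id` column followed by one column per sample named
#' `d<day>_r<replicate>`. Scores TSV: the columns of a
#' [ScreenScores-class].
#'
#' @param x a [ScreenCounts-class] or [ScreenScores-class].
#' @param file path to the TSV.
#' @return `readScreenCounts()` returns a [ScreenCounts-class]; the writers
#'   invisibly return `file`.
#' @export
readScreenCounts <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE)
    stopifnot("guide_id" %in% colnames(df))
    m <- as.matrix(df[, setdiff(colnames(df), "guide_id"), drop = FALSE])
    rownames(m) <- df$guide_id
    ScreenCounts(m)
}

#' @rdname readScreenCounts
#' @export
writeScreenCounts <- function(x, file) {
    df <- data.frame(guide_id = rownames(x), assay(x, "counts"),
                     check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname readScreenCounts
#' @export
writeScreenScores <- function(x, file) {
    write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    invisible(file)
}
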