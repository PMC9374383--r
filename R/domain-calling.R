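## Projection of guide-level z scores onto protein coordinates, depleted
## (essential) segment calling, domain annotation, and GC-artifact flagging.

#' Per-residue profile of anchored z scores
#'
#' For each residue `a` of the protein, averages the z scores of all target
#' guides whose cut falls within `windowRadius` residues
#' (`|cut_aa - a| <= windowRadius`). Only QC-passing target guides with a
#' finite z contribute; residues with no contributing guide carry `NA`.
#'
#' @param scores a [ScreenScores-class] (or data frame with `guide_id`, `z`,
#'   `qc_pass`).
#' @param library the matching [GuideLibrary-class] providing `cut_aa` and
#'   `gc_fraction`.
#' @param windowRadius half-width of the averaging window in residues
#'   (default 5, about two guides per window at typical 1-guide/8-bp tiling
#'   density).
#' @param excludeGC optional GC fraction threshold: guides with
#'   `gc_fraction >= excludeGC` are dropped before profiling (see
#'   [flagGCArtifacts()]); `NULL` (default) keeps all guides.
#' @param aaLength protein length in codons; defaults to the library
#'   metadata.
#' @return A `data.frame` with one row per residue: `aa`, `n_guides`,
#'   `mean_z`.
#' @export
residueProfile <- function(scores, library, windowRadius = 5,
                           excludeGC = NULL, aaLength = NULL) {
    windowRadius <- as.integer(windowRadius)
    if (is.na(windowRadius) || windowRadius < 0L)
        stop("windowRadius must be a non-negative integer", call. = FALSE)
    lib <- as.data.frame(library)
    sc <- as.data.frame(scores)
    df <- merge(sc[, c("guide_id", "z", "qc_pass")],
                lib[, c("guide_id", "category", "cut_aa", "gc_fraction")],
                by = "guide_id")
    df <- df[df$category == "target" & df$qc_pass & is.finite(df$z) &
                 !is.na(df$cut_aa), , drop = FALSE]
    if (!is.null(excludeGC)) {
        flagged <- flagGCArtifacts(library, excludeGC)
        df <- df[!flagged[df$guide_id], , drop = FALSE]
    }
    if (is.null(aaLength))
        aaLength <- metadata(library)$aa_length
    if (is.null(aaLength))
        aaLength <- if (nrow(df)) max(df$cut_aa) + windowRadius else 0L
    aaLength <- as.integer(aaLength)

    n <- numeric(aaLength)
    s <- numeric(aaLength)
    for (i in seq_len(nrow(df))) {
        lo <- max(1L, df$cut_aa[i] - windowRadius)
        hi <- min(aaLength, df$cut_aa[i] + windowRadius)
        idx <- lo:hi
        n[idx] <- n[idx] + 1
        s[idx] <- s[idx] + df$z[i]
    }
    data.frame(aa = seq_len(aaLength), n_guides = as.integer(n),
               mean_z = ifelse(n > 0, s / n, NA_real_))
}

#' Call depleted (essential) protein segments
#'
#' Finds maximal runs of at least `minRun` consecutive covered residues whose
#' windowed mean z is at or below `zThreshold`. An empty call set is a valid
#' result. Residues without guide coverage break runs.
#'
#' @param profile residue profile from [residueProfile()].
#' @param zThreshold call residues with `mean_z <= zThreshold` (default -0.5,
#'   halfway from the nonessential-control anchor at 0 to the
#'   essential-control anchor at -1; for analyses where only in-frame signal
#'   is present, match the threshold to the attainable depletion instead, see
#'   [expectedAnchoredZ()]).
#' @param minRun minimum run length in residues (default 5).
#' @return A `data.frame` of non-overlapping, sorted segments: `start_aa`,
#'   `end_aa`, `length_aa`, `min_z`, `mean_z`.
#' @export
callEssentialSegments <- function(profile, zThreshold = -0.5, minRun = 5) {
    below <- !is.na(profile$mean_z) & profile$mean_z <= zThreshold
    empty <- data.frame(start_aa = integer(), end_aa = integer(),
                        length_aa = integer(), min_z = numeric(),
                        mean_z = numeric())
    if (!any(below)) return(empty)
    ## residues must also be consecutive integers (profiles are, by
    ## construction, a dense 1..aaLength grid; be safe about subsets)
    o <- order(profile$aa)
    aa <- profile$aa[o]
    below <- below[o]
    zz <- profile$mean_z[o]
    grp <- cumsum(!below | c(TRUE, diff(aa) != 1L))
    runs <- split(which(below), grp[below])
    segs <- lapply(runs, function(idx) {
        if (length(idx) < minRun) return(NULL)
        data.frame(start_aa = aa[idx[1L]], end_aa = aa[idx[length(idx)]],
                   length_aa = length(idx),
                   min_z = min(zz[idx]), mean_z = mean(zz[idx]))
    })
    segs <- do.call(rbind, segs)
    if (is.null(segs)) return(empty)
    segs <- segs[order(segs$start_aa), , drop = FALSE]
    rownames(segs) <- NULL
    segs
}

#' Annotate called segments against known domains
#'
#' Reports, for every (segment, domain) pair, the overlap length in residues,
#' the fraction of the domain covered, and the Jaccard index of the two
#' intervals. All coordinates are 1-based inclusive.
#'
#' @param segments segment table from [callEssentialSegments()] (columns
#'   `start_aa`, `end_aa`).
#' @param domains domain annotation table with columns `name`, `start_aa`,
#'   `end_aa` (and optionally `class`), e.g. from [readDomainAnnotation()].
#' @param proteinLength optional protein length used to validate the
#'   annotation.
#' @return A `data.frame` with one row per (segment, domain) pair:
#'   `segment_start`, `segment_end`, `domain`, `domain_start`, `domain_end`,
#'   `overlap_aa`, `domain_fraction`, `jaccard`.
#' @export
annotateSegments <- function(segments, domains, proteinLength = NULL) {
    domains <- as.data.frame(domains)
    stopifnot(all(c("name", "start_aa", "end_aa") %in% colnames(domains)))
    if (any(domains$start_aa < 1L | domains$end_aa < domains$start_aa))
        stop("domain intervals must satisfy 1 <= start_aa <= end_aa",
             call. = FALSE)
    if (!is.null(proteinLength) && any(domains$end_aa > proteinLength))
        stop("domain annotation extends beyond the protein length",
             call. = FALSE)
    if (!nrow(segments) || !nrow(domains))
        return(data.frame(segment_start = integer(), segment_end = integer(),
                          domain = character(), domain_start = integer(),
                          domain_end = integer(), overlap_aa = integer(),
                          domain_fraction = numeric(), jaccard = numeric()))
    pairs <- expand.grid(s = seq_len(nrow(segments)),
                         d = seq_len(nrow(domains)))
    ov <- intervalOverlap(segments$start_aa[pairs$s], segments$end_aa[pairs$s],
                          domains$start_aa[pairs$d], domains$end_aa[pairs$d])
    data.frame(segment_start = segments$start_aa[pairs$s],
               segment_end = segments$end_aa[pairs$s],
               domain = domains$name[pairs$d],
               domain_start = domains$start_aa[pairs$d],
               domain_end = domains$end_aa[pairs$d],
               overlap_aa = ov$overlap,
               domain_fraction = ov$overlap /
                   (domains$end_aa[pairs$d] - domains$start_aa[pairs$d] + 1L),
               jaccard = ov$jaccard)
}

## closed-interval overlap/union arithmetic, vectorised
intervalOverlap <- function(s1, e1, s2, e2) {
    overlap <- pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
    union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - overlap
    list(overlap = overlap,
         jaccard = ifelse(union > 0, overlap / union, 0))
}

#' Flag GC-rich guides as potential off-target artifacts
#'
#' Guides over extremely GC-rich stretches (such as a polyglycine repeat,
#' which is >90% GC) can drop out through off-target cutting rather than
#' on-target fitness effects. This flags guides whose protospacer GC fraction
#' is at or above `gcThreshold`; [residueProfile()] can exclude them.
#'
#' @param library a [GuideLibrary-class].
#' @param gcThreshold GC fraction at or above which a guide is flagged
#'   (default 0.8).
#' @return Named logical vector (by `guide_id`).
#' @export
flagGCArtifacts <- function(library, gcThreshold = 0.8) {
    if (!is.numeric(gcThreshold) || gcThreshold < 0 || gcThreshold > 1)
        stop("gcThreshold must lie in [0, 1]", call. = FALSE)
    lib <- as.data.frame(library)
    setNames(!is.na(lib$gc_fraction) & lib$gc_fraction >= gcThreshold,
             lib$guide_id)
}

#' Read a protein-domain annotation TSV
#'
#' Tab-separated with header `name, start_aa, end_aa, class`; coordinates are
#' 1-based inclusive.
#'
#' @param file path to the TSV.
#' @return A `data.frame`.
#' @export
readDomainAnnotation <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "start_aa", "end_aa") %in% colnames(df)))
    df
}

#' Run the tiling-screen analysis pipeline
#'
#' Convenience wrapper chaining [scoreScreen()], [residueProfile()] and
#' [callEssentialSegments()]. Segment calling is gated on control separation
#' (see [controlSeparation()]): when the essential and nonessential controls
#' do not separate (separation below `minSeparation`), the anchored z scale
#' carries no information and no segments are called.
#'
#' @inheritParams scoreScreen
#' @inheritParams residueProfile
#' @inheritParams callEssentialSegments
#' @param minSeparation minimum control separation required to call segments
#'   (default 2, a conventional "informative assay" SSMD cutoff).
#' @return A list with elements `scores` ([ScreenScores-class]), `separation`
#'   (numeric), `informative` (logical gate), `profile` and `segments`.
#' @export
runTilingPipeline <- function(counts, library, pseudocount = 1,
                              qcFraction = 0.05,
                              combine = c("median", "mean"),
                              scale = c("log10", "linear"),
                              endDay = 22, startDay = 0,
                              windowRadius = 5, excludeGC = NULL,
                              zThreshold = -0.5, minRun = 5,
                              minSeparation = 2) {
    scores <- scoreScreen(counts, library, pseudocount = pseudocount,
                          qcFraction = qcFraction, combine = combine,
                          scale = scale, endDay = endDay, startDay = startDay)
    profile <- residueProfile(scores, library, windowRadius = windowRadius,
                              excludeGC = excludeGC)
    sep <- anchorStats(scores)$separation
    informative <- is.finite(sep) && sep >= minSeparation
    segments <- callEssentialSegments(profile, zThreshold, minRun)
    if (!informative)
        segments <- segments[0L, , drop = FALSE]
    list(scores = scores, separation = sep, informative = informative,
         profile = profile, segments = segments)
}
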