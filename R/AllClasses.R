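## S4 containers. GuideLibrary and ScreenScores extend DFrame so that all the
## usual DataFrame semantics ([, subset, cbind, as.data.frame) come for free;
## ScreenCounts extends SummarizedExperiment.

GUIDE_CATEGORIES <- c("target", "positive_control", "negative_control")

LIBRARY_COLUMNS <- c("guide_id", "category", "protospacer", "pam", "strand",
                     "cut_nt", "cut_aa", "gc_fraction")

#' CodingSequence: a validated protein-coding DNA sequence
#'
#' Thin wrapper around a [Biostrings::DNAString] that enforces the contract a
#' tiling design needs: the sequence is a positive multiple of 3 in length and
#' contains only unambiguous A/C/G/T.
#'
#' @slot id transcript or gene identifier.
#' @slot sequence the coding-strand sequence as a `DNAString`.
#' @export
setClass("CodingSequence",
         slots = c(id = "character", sequence = "DNAString"))

setValidity("CodingSequence", function(object) {
    n <- length(object@sequence)
    if (n == 0L || n %% 3L != 0L)
        return("sequence length must be a positive multiple of 3")
    counts <- alphabetFrequency(object@sequence)
    if (sum(counts[c("A", "C", "G", "T")]) != n)
        return("sequence must contain only A/C/G/T (no ambiguity codes)")
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("id must be a single non-empty string")
    TRUE
})

#' Construct a CodingSequence
#'
#' @param id identifier string (for FASTA input, the record id).
#' @param sequence DNA sequence as a character string or `DNAString`.
#'   Must be a positive multiple of 3 long and contain only A/C/G/T.
#' @return A [CodingSequence-class] object.
#' @examples
#' cds <- codingSequence("toy", "ATGGCCAAATTTGGGCCCAAGGCTGACTGCTAGTAA")
#' aaLength(cds)
#' @export
codingSequence <- function(id, sequence) {
    if (is.character(sequence))
        sequence <- tryCatch(DNAString(sequence), error = function(e)
            stop("invalid DNA sequence: ", conditionMessage(e), call. = FALSE))
    new("CodingSequence", id = as.character(id), sequence = sequence)
}

#' Read coding sequences from a FASTA file
#'
#' Each FASTA record becomes one validated [CodingSequence-class]; the record
#' id (first whitespace-delimited token) becomes the `id`.
#'
#' @param file path to a (single- or multi-record) FASTA file.
#' @return A named list of [CodingSequence-class] objects.
#' @export
readCodingSequence <- function(file) {
    set <- readDNAStringSet(file)
    ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
    out <- lapply(seq_along(set), function(i)
        codingSequence(ids[i], set[[i]]))
    names(out) <- ids
    out
}

setMethod("show", "CodingSequence", function(object) {
    cat("CodingSequence ", object@id, ": ", length(object@sequence),
        " nt (", aaLength(object), " codons incl. stop)\n", sep = "")
})

#' GuideLibrary: a table of Cas9 guides
#'
#' A [S4Vectors::DataFrame] subclass with one row per guide and the columns
#' `guide_id`, `category` (`target`, `positive_control`, `negative_control`),
#' `protospacer` (20 nt, 5'->3' on the targeted strand), `pam` (3 nt),
#' `strand` (`+`/`-` relative to the coding strand, `.` for controls),
#' `cut_nt` (1-based coding-strand coordinate of the nucleotide immediately 5'
#' of the blunt cut; `NA` for controls), `cut_aa` (1-based codon index of the
#' first disrupted codon; `NA` for controls) and `gc_fraction`. `metadata()`
#' carries `cds_id`, `cds_length`, `aa_length` and, once controls are added,
#' `expected_frequency` (1/N, used by screen QC).
#'
#' @export
setClass("GuideLibrary", contains = "DFrame")

setValidity("GuideLibrary", function(object) {
    missing <- setdiff(LIBRARY_COLUMNS, colnames(object))
    if (length(missing))
        return(paste("missing column(s):", paste(missing, collapse = ", ")))
    if (anyDuplicated(object$guide_id))
        return("guide_id values must be unique")
    if (!all(object$category %in% GUIDE_CATEGORIES))
        return(paste("category must be one of:",
                     paste(GUIDE_CATEGORIES, collapse = ", ")))
    gc <- object$gc_fraction
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
        return("gc_fraction must lie in [0, 1]")
    tgt <- object$category == "target"
    if (any(tgt)) {
        pam <- object$pam[tgt]
        if (any(substr(pam, 2L, 3L) != "GG"))
            return("target guides must have an NGG PAM")
        if (any(is.na(object$cut_nt[tgt]) | is.na(object$cut_aa[tgt])))
            return("target guides must carry cut_nt and cut_aa")
        L <- metadata(object)$cds_length
        if (!is.null(L) &&
            any(object$cut_nt[tgt] < 1L | object$cut_nt[tgt] >= L))
            return("target cut_nt must satisfy 1 <= cut_nt < cds_length")
    }
    ctl <- !tgt
    if (any(!is.na(object$cut_nt[ctl])))
        return("control guides must not carry coordinates")
    TRUE
})

#' Construct a GuideLibrary from a guide table
#'
#' @param guides a `data.frame` or `DataFrame` with the columns documented in
#'   [GuideLibrary-class]. Missing control coordinates should be `NA`.
#' @param cdsLength,cdsId,aaLength optional coding-sequence metadata.
#' @return A [GuideLibrary-class].
#' @export
GuideLibrary <- function(guides, cdsLength = NULL, cdsId = NULL,
                         aaLength = NULL) {
    df <- as(as.data.frame(guides), "DFrame")
    meta <- list()
    if (!is.null(cdsLength)) {
        meta$cds_length <- as.integer(cdsLength)
        if (is.null(aaLength))
            aaLength <- cdsLength %/% 3L
    }
    if (!is.null(aaLength)) meta$aa_length <- as.integer(aaLength)
    if (!is.null(cdsId)) meta$cds_id <- cdsId
    out <- new("GuideLibrary", df)
    metadata(out) <- meta
    out
}

setMethod("show", "GuideLibrary", function(object) {
    n <- table(factor(object$category, levels = GUIDE_CATEGORIES))
    cat("GuideLibrary with ", nrow(object), " guides (",
        n[["target"]], " target, ", n[["positive_control"]],
        " positive-control, ", n[["negative_control"]],
        " negative-control)\n", sep = "")
    L <- metadata(object)$cds_length
    if (!is.null(L))
        cat("  CDS: ", metadata(object)$cds_id, " (", L, " nt, ",
            metadata(object)$aa_length, " codons)\n", sep = "")
    ef <- metadata(object)$expected_frequency
    if (!is.null(ef))
        cat("  expected per-guide frequency: ", signif(ef, 4), "\n", sep = "")
    callNextMethod()
})

#' ScreenCounts: guide-by-sample read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `counts` assay
#' of non-negative integers and `colData` columns `day` and `replicate`
#' identifying each sequenced sample. Sample names follow the
#' `d<day>_r<replicate>` convention used by the on-disk TSV format.
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
        return("counts must be non-negative integers")
    cd <- colData(object)
    if (!all(c("day", "replicate") %in% colnames(cd)))
        return("colData must have 'day' and 'replicate'")
    if (anyDuplicated(paste(cd$day, cd$replicate)))
        return("each (day, replicate) pair must be unique")
    if (is.null(rownames(object)))
        return("rownames (guide_id) are required")
    TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides in rows (rownames = guide ids) and
#'   samples in columns. If `day`/`replicate` are not given, column names must
#'   follow `d<day>_r<replicate>` (e.g. `d0_r1`, `d22_r3`).
#' @param day,replicate optional integer vectors, one entry per column.
#' @return A [ScreenCounts-class].
#' @examples
#' m <- matrix(10L, 3, 2, dimnames = list(paste0("g", 1:3), c("d0_r1", "d22_r1")))
#' ScreenCounts(m)
#' @export
ScreenCounts <- function(counts, day = NULL, replicate = NULL) {
    counts <- as.matrix(counts)
    if (is.null(day) || is.null(replicate)) {
        info <- parseSampleNames(colnames(counts))
        day <- info$day
        replicate <- info$replicate
    }
    colnames(counts) <- sprintf("d%s_r%d", format(day, trim = TRUE),
                                as.integer(replicate))
    storage.mode(counts) <- "integer"
    new("ScreenCounts",
        SummarizedExperiment(
            assays = list(counts = counts),
            colData = DataFrame(day = as.numeric(day),
                                replicate = as.integer(replicate),
                                row.names = colnames(counts))))
}

parseSampleNames <- function(x) {
    if (is.null(x) || !all(grepl("^d[0-9]+(\\.[0-9]+)?_r[0-9]+$", x)))
        stop("sample names must follow d<day>_r<replicate>, e.g. d0_r1",
             call. = FALSE)
    parts <- regmatches(x, regexec("^d([0-9.]+)_r([0-9]+)$", x))
    list(day = as.numeric(vapply(parts, `[`, character(1), 2L)),
         replicate = as.integer(vapply(parts, `[`, character(1), 3L)))
}

#' ScreenScores: per-guide CRISPR scores and anchored z
#'
#' A [S4Vectors::DataFrame] subclass with one row per guide: `guide_id`,
#' `category`, `qc_pass`, per-replicate `score_r<k>` columns (day-end /
#' day-start frequency ratios), `combined_score`, `log_score` (log10 by
#' default) and the control-anchored `z`. `metadata()` records the scoring
#' parameters and the anchoring summary (`m_neg`, `m_pos`, `separation`).
#'
#' @export
setClass("ScreenScores", contains = "DFrame")

setValidity("ScreenScores", function(object) {
    need <- c("guide_id", "category", "qc_pass", "combined_score",
              "log_score", "z")
    missing <- setdiff(need, colnames(object))
    if (length(missing))
        return(paste("missing column(s):", paste(missing, collapse = ", ")))
    if (any(object$qc_pass & !is.finite(object$z)))
        return("z must be finite for all QC-passing guides")
    TRUE
})

setMethod("show", "ScreenScores", function(object) {
    cat("ScreenScores for ", nrow(object), " guides (",
        sum(object$qc_pass), " QC-pass)\n", sep = "")
    md <- metadata(object)
    if (!is.null(md$m_neg))
        cat(sprintf("  anchors: m_neg = %.4g, m_pos = %.4g, separation = %.3g\n",
                    md$m_neg, md$m_pos, md$separation))
    callNextMethod()
})

#' Accessors for anchoring metadata
#'
#' `anchorStats()` returns the control medians and separation statistic
#' recorded when a [ScreenScores-class] was anchored.
#'
#' @param x a `ScreenScores` object.
#' @return A list with `m_neg`, `m_pos` (control medians of the log score) and
#'   `separation` (SSMD-like control separation, see [controlSeparation()]).
#' @export
anchorStats <- function(x) {
    md <- metadata(x)
    list(m_neg = md$m_neg, m_pos = md$m_pos, separation = md$separation)
}

#' Protein length accessor
#'
#' Number of codons (including the stop codon) represented by an object.
#'
#' @param x a [CodingSequence-class], [GuideLibrary-class] or
#'   [TrueModel-class].
#' @return Integer codon count.
#' @export
setGeneric("aaLength", function(x) standardGeneric("aaLength"))

#' @rdname aaLength
setMethod("aaLength", "CodingSequence", function(x)
    length(x@sequence) %/% 3L)

#' @rdname aaLength
setMethod("aaLength", "GuideLibrary", function(x)
    metadata(x)$aa_length)
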