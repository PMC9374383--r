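## Tiling-library design: exhaustive NGG-PAM guide enumeration over a coding
## sequence, cut-site -> residue mapping, and library assembly with controls.

#' Enumerate all Cas9 (NGG) guides in a coding sequence
#'
#' Scans both strands of a coding sequence for every 20-nt protospacer whose
#' 23-nt protospacer+PAM window lies entirely within the CDS and whose PAM
#' matches NGG. The blunt SpCas9 cut falls between protospacer positions 17
#' and 18 (3 nt 5' of the PAM); `cut_nt` is the coding-strand coordinate of
#' the nucleotide immediately 5' of the cut, and `cut_aa` the 1-based index of
#' the first codon disrupted by the cut (the codon containing nucleotide
#' `cut_nt + 1`).
#'
#' @param cds a [CodingSequence-class].
#' @param collapseDuplicates if `TRUE` (default), guides with identical
#'   protospacer sequence are merged into a single record (one sgRNA = one
#'   sequence in a pooled library); the first cut site in coding-strand order
#'   is kept as primary and all sites are retained in `all_cut_nt` /
#'   `n_sites`.
#' @return A [GuideLibrary-class] of `category = "target"` guides ordered by
#'   `cut_nt`. A CDS shorter than 23 nt yields an empty library.
#' @examples
#' cds <- codingSequence("toy", "ATGGCCAAATTTGGGCCCAAGGCTGACTGCTAGTAA")
#' enumerateGuides(cds)
#' @export
enumerateGuides <- function(cds, collapseDuplicates = TRUE) {
    stopifnot(is(cds, "CodingSequence"))
    validObject(cds)
    fwd <- as.character(cds@sequence)
    L <- nchar(fwd)
    rev <- as.character(reverseComplement(cds@sequence))

    scan <- function(seqchr) {
        ## protospacer start s has its PAM GG at s+21..s+22
        v <- strsplit(seqchr, "")[[1L]]
        gg <- which(v[-length(v)] == "G" & v[-1L] == "G")
        s <- gg - 21L
        s[s >= 1L & s <= length(v) - 22L]
    }

    rows <- list()
    if (L >= 23L) {
        sp <- scan(fwd)
        if (length(sp))
            rows$plus <- data.frame(
                protospacer = substring(fwd, sp, sp + 19L),
                pam = substring(fwd, sp + 20L, sp + 22L),
                strand = "+", cut_nt = sp + 16L,
                stringsAsFactors = FALSE)
        sm <- scan(rev)
        if (length(sm))
            rows$minus <- data.frame(
                protospacer = substring(rev, sm, sm + 19L),
                pam = substring(rev, sm + 20L, sm + 22L),
                strand = "-", cut_nt = L - sm - 16L,
                stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(protospacer = character(), pam = character(),
                   strand = character(), cut_nt = integer())
    df <- df[order(df$cut_nt, df$strand), , drop = FALSE]
    df$cut_aa <- if (nrow(df)) cutSiteToAA(df$cut_nt, L) else integer()
    df$n_sites <- rep(1L, nrow(df))
    df$all_cut_nt <- as.character(df$cut_nt)

    if (collapseDuplicates && nrow(df) && anyDuplicated(df$protospacer)) {
        keep <- !duplicated(df$protospacer)
        sites <- split(df$cut_nt, df$protospacer)
        first <- df[keep, , drop = FALSE]
        first$n_sites <- lengths(sites)[first$protospacer]
        first$all_cut_nt <- vapply(sites, paste, character(1),
                                   collapse = ",")[first$protospacer]
        df <- first
    }
    rownames(df) <- NULL
    n <- nrow(df)
    df <- cbind(
        data.frame(
            guide_id = sprintf("%s_g%0*d", cds@id,
                               max(3L, nchar(n)), seq_len(max(n, 0L))),
            category = rep("target", n),
            stringsAsFactors = FALSE),
        df)
    df$gc_fraction <- if (n) gcFraction(df$protospacer) else numeric()
    GuideLibrary(df[, c(LIBRARY_COLUMNS, "n_sites", "all_cut_nt")],
                 cdsLength = L, cdsId = cds@id)
}

#' Map a cut coordinate to a codon index
#'
#' Returns the 1-based index of the codon containing nucleotide `cut_nt + 1`,
#' i.e. the first residue whose codon is disrupted by a blunt cut immediately
#' 3' of `cut_nt`. Vectorised over `cut_nt`.
#'
#' @param cut_nt 1-based coding-strand coordinate of the nucleotide
#'   immediately 5' of the cut; must satisfy `1 <= cut_nt < cdsLength`.
#' @param cdsLength CDS length in nucleotides.
#' @return Integer codon index, `floor(cut_nt / 3) + 1`.
#' @examples
#' cutSiteToAA(3, 36)  # cut between codons 1 and 2 disrupts codon 2
#' @export
cutSiteToAA <- function(cut_nt, cdsLength) {
    cut_nt <- as.integer(cut_nt)
    if (any(is.na(cut_nt)) || any(cut_nt < 1L | cut_nt >= cdsLength))
        stop("cut_nt must satisfy 1 <= cut_nt < cdsLength", call. = FALSE)
    cut_nt %/% 3L + 1L
}

#' GC fraction of 20-nt protospacers
#'
#' @param protospacer character vector of 20-nt A/C/G/T sequences.
#' @return Numeric vector in `[0, 1]`: (#G + #C) / 20.
#' @examples
#' gcFraction("ATGGCCAAATTTGGGCCCAA")  # 0.5
#' @export
gcFraction <- function(protospacer) {
    if (any(nchar(protospacer) != 20L))
        stop("protospacers must be exactly 20 nt", call. = FALSE)
    if (any(grepl("[^ACGT]", protospacer)))
        stop("protospacers must contain only A/C/G/T", call. = FALSE)
    (nchar(gsub("[AT]", "", protospacer))) / 20
}

#' Assemble a tiling library with control guides
#'
#' Combines target guides with essential-gene (positive) and nonessential
#' (negative) control guides into a single library table, and records the
#' expected per-guide frequency 1/N used by downstream representation QC.
#' Control guides carry no coordinates (`strand = "."`, `cut_nt`/`cut_aa`
#' `NA`); they exist only for score normalization.
#'
#' @param targets a [GuideLibrary-class] (or guide table) of target guides,
#'   e.g. from [enumerateGuides()].
#' @param essentialControls,nonessentialControls data frames with columns
#'   `guide_id` and `protospacer` (further columns ignored), or character
#'   vectors of protospacers (ids are then generated).
#' @return A [GuideLibrary-class] with all three categories;
#'   `metadata()$expected_frequency` is `1 / nrow`.
#' @export
assembleLibrary <- function(targets, essentialControls,
                            nonessentialControls) {
    tdf <- as.data.frame(targets)
    meta <- if (is(targets, "GuideLibrary")) metadata(targets) else list()
    pos <- controlFrame(essentialControls, "positive_control", "ess")
    neg <- controlFrame(nonessentialControls, "negative_control", "non")
    extra <- setdiff(colnames(tdf), colnames(pos))
    for (col in extra) pos[[col]] <- neg[[col]] <- NA
    all <- rbind(tdf[, colnames(pos), drop = FALSE], pos, neg)
    dup <- all$guide_id[duplicated(all$guide_id)]
    if (length(dup))
        stop("duplicate guide_id across groups: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    lib <- GuideLibrary(all, cdsLength = meta$cds_length,
                        cdsId = meta$cds_id, aaLength = meta$aa_length)
    metadata(lib)$expected_frequency <- 1 / nrow(lib)
    lib
}

controlFrame <- function(x, category, prefix) {
    if (is.character(x))
        x <- data.frame(
            guide_id = sprintf("%s_%02d", prefix, seq_along(x)),
            protospacer = x, stringsAsFactors = FALSE)
    x <- as.data.frame(x)
    stopifnot(all(c("guide_id", "protospacer") %in% colnames(x)))
    data.frame(guide_id = as.character(x$guide_id),
               category = category,
               protospacer = as.character(x$protospacer),
               pam = if ("pam" %in% colnames(x)) x$pam else NA_character_,
               strand = ".",
               cut_nt = NA_integer_, cut_aa = NA_integer_,
               gc_fraction = gcFraction(as.character(x$protospacer)),
               stringsAsFactors = FALSE)
}

#' Read and write guide-library TSVs
#'
#' The on-disk format is a tab-separated table with header `guide_id,
#' category, protospacer, pam, strand, cut_nt, cut_aa, gc_fraction` (plus any
#' extra columns), 1-based coordinates, `.` strand for control rows and `NA`
#' for missing numerics.
#'
#' @param x a [GuideLibrary-class].
#' @param file path to the TSV.
#' @return `readGuideLibrary()` returns a [GuideLibrary-class];
#'   `writeGuideLibrary()` invisibly returns `file`.
#' @export
writeGuideLibrary <- function(x, file) {
    write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    invisible(file)
}

#' @rdname writeGuideLibrary
#' @export
readGuideLibrary <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE,
                     colClasses = c(strand = "character"))
    if ("all_cut_nt" %in% colnames(df))
        df$all_cut_nt <- as.character(df$all_cut_nt)
    GuideLibrary(df)
}
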