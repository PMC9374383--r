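## Dual-fluorescence reporter statistics: GFP/BFP MFI ratios per condition,
## fold changes versus vehicle, the nonparametric readthrough tests, and the
## fluorescence-tracked competition-assay fold change.

CONDITION_COLUMNS <- c("drug", "dose_um", "time_h", "construct",
                       "stop_codon", "replicate")

conditionCols <- function(events)
    intersect(CONDITION_COLUMNS, colnames(events))

conditionLabel <- function(df, cols)
    do.call(paste, c(lapply(cols, function(cc) paste0(cc, "=", df[[cc]])),
                     sep = ", "))

#' GFP/BFP mean-fluorescence-intensity ratios per condition
#'
#' Gates on `live`, groups events by the condition columns present (`drug`,
#' `dose_um`, `time_h`, `construct`, `stop_codon`, `replicate`), and computes
#' the per-channel MFI and their ratio.
#'
#' @param events per-cell event table with numeric `gfp` and `bfp`, logical
#'   `live`, and condition columns; see [simulateReporterEvents()] or
#'   [readReporterEvents()].
#' @param minEvents minimum live events required per condition (default 100).
#' @param mfi `"mean"` (arithmetic, default) or `"gmean"` (geometric, a
#'   common flow-cytometry alternative).
#' @return A `data.frame` with the condition columns plus `n_events`,
#'   `mfi_gfp`, `mfi_bfp`, `ratio`.
#' @examples
#' ev <- data.frame(gfp = c(100, 300), bfp = c(100, 100), live = TRUE,
#'                  drug = "DMSO")
#' mfiRatio(ev, minEvents = 2)$ratio  # means 200/100 = 2
#' @export
mfiRatio <- function(events, minEvents = 100, mfi = c("mean", "gmean")) {
    mfi <- match.arg(mfi)
    stopifnot(all(c("gfp", "bfp", "live") %in% colnames(events)))
    if (any(events$gfp < 0 | events$bfp < 0))
        stop("fluorescence intensities must be non-negative", call. = FALSE)
    cols <- conditionCols(events)
    live <- events[events$live, , drop = FALSE]
    key <- if (length(cols))
        interaction(live[cols], drop = TRUE, lex.order = TRUE)
    else factor(rep("all", nrow(live)))
    avg <- if (mfi == "mean") mean else function(v) exp(mean(log(v)))
    out <- lapply(split(seq_len(nrow(live)), key), function(idx) {
        grp <- live[idx, , drop = FALSE]
        label <- if (length(cols)) conditionLabel(grp[1L, ], cols) else "all"
        if (length(idx) < minEvents)
            stop("fewer than ", minEvents, " live events for condition ",
                 label, call. = FALSE)
        mg <- avg(grp$gfp)
        mb <- avg(grp$bfp)
        if (mb == 0)
            stop("BFP MFI is zero for condition ", label,
                 "; the GFP/BFP ratio is undefined", call. = FALSE)
        cbind(grp[1L, cols, drop = FALSE],
              data.frame(n_events = length(idx), mfi_gfp = mg, mfi_bfp = mb,
                         ratio = mg / mb))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Fold change of a treated GFP/BFP ratio versus its vehicle control
#'
#' `fold = treated_ratio / vehicle_ratio`. For a stop-codon readthrough
#' reporter (BFP-stop-GFP), fold > 1 indicates readthrough; for a
#' degradation reporter (fusion-GFP / IRES-BFP), fold < 1 indicates
#' drug-induced degradation of the fusion. The two conditions must agree on
#' `construct`, `stop_codon`, `time_h` and `replicate` (where present).
#'
#' @param treated,vehicle single rows of the table returned by [mfiRatio()].
#' @return The fold change (numeric scalar).
#' @export
foldChangeVsControl <- function(treated, vehicle) {
    for (col in c("construct", "stop_codon", "time_h", "replicate")) {
        if (col %in% colnames(treated) && col %in% colnames(vehicle) &&
            !identical(treated[[col]], vehicle[[col]]))
            stop("treated and vehicle conditions differ in '", col, "'",
                 call. = FALSE)
    }
    if (!is.finite(vehicle$ratio) || vehicle$ratio <= 0)
        stop("vehicle ratio must be positive", call. = FALSE)
    treated$ratio / vehicle$ratio
}

#' Fold changes versus vehicle for a whole ratio table
#'
#' Matches every non-vehicle condition in an [mfiRatio()] table to the
#' vehicle (`controlDrug`) condition with the same `construct`, `stop_codon`,
#' `time_h` and `replicate`, and divides the ratios.
#'
#' @param ratios output of [mfiRatio()].
#' @param controlDrug name of the vehicle arm (default `"DMSO"`).
#' @return The treated rows of `ratios` with an added `fold_change` column.
#' @export
reporterFoldChanges <- function(ratios, controlDrug = "DMSO") {
    stopifnot("drug" %in% colnames(ratios))
    matchCols <- intersect(c("construct", "stop_codon", "time_h",
                             "replicate"), colnames(ratios))
    veh <- ratios[ratios$drug == controlDrug, , drop = FALSE]
    trt <- ratios[ratios$drug != controlDrug, , drop = FALSE]
    if (!nrow(veh))
        stop("no vehicle ('", controlDrug, "') conditions found",
             call. = FALSE)
    key <- function(df) if (length(matchCols))
        do.call(paste, c(df[matchCols], sep = "\r")) else
        rep("all", nrow(df))
    vkey <- key(veh)
    if (anyDuplicated(vkey))
        stop("multiple vehicle conditions match the same ",
             paste(matchCols, collapse = "/"), call. = FALSE)
    idx <- match(key(trt), vkey)
    if (anyNA(idx))
        stop("no matching vehicle condition for: ",
             paste(conditionLabel(trt[which(is.na(idx))[1L], ],
                                  conditionCols(trt)), collapse = ", "),
             call. = FALSE)
    if (any(veh$ratio[idx] <= 0))
        stop("vehicle ratio must be positive", call. = FALSE)
    trt$fold_change <- trt$ratio / veh$ratio[idx]
    trt
}

## Rank-sum p-value: exact for both groups <= exactMax and untied, otherwise
## the tie-corrected normal approximation; two-sided throughout.
rankSumP <- function(x, y, exactMax = 8) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values", call. = FALSE)
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && length(x) <= exactMax && length(y) <= exactMax
    suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Nonparametric tests on readthrough fold changes
#'
#' Reproduces the reporter statistics: two-sided Wilcoxon rank-sum tests for
#' adjacent dose pairs within each stop codon and timepoint, for stop-codon
#' pairs within each dose and timepoint, and a Kruskal-Wallis test across
#' dose groups within each stop codon and timepoint. P-values are exact for
#' group sizes up to 8 without ties, and tie-corrected normal approximations
#' otherwise; no multiple-testing correction is applied.
#'
#' @param foldChanges a data frame of per-replicate fold changes with columns
#'   `fold_change`, `dose_um`, `stop_codon`, `time_h`, e.g. from
#'   [reporterFoldChanges()].
#' @param alpha significance level for the reported flag (default 0.05).
#' @return A list of data frames: `dose_contrasts` (columns `stop_codon`,
#'   `time_h`, `dose1`, `dose2`, `n1`, `n2`, `p_value`, `significant`),
#'   `codon_contrasts` (`dose_um`, `time_h`, `codon1`, `codon2`, ...) and
#'   `kruskal` (`stop_codon`, `time_h`, `statistic`, `df`, `p_value`).
#' @export
readthroughTests <- function(foldChanges, alpha = 0.05) {
    fc <- as.data.frame(foldChanges)
    stopifnot(all(c("fold_change", "dose_um", "stop_codon", "time_h") %in%
                      colnames(fc)))
    grab <- function(dose, codon, time)
        fc$fold_change[fc$dose_um == dose & fc$stop_codon == codon &
                           fc$time_h == time]

    dose_rows <- list()
    codon_rows <- list()
    kw_rows <- list()
    for (time in sort(unique(fc$time_h))) {
        codons <- sort(unique(fc$stop_codon[fc$time_h == time]))
        for (codon in codons) {
            doses <- sort(unique(
                fc$dose_um[fc$time_h == time & fc$stop_codon == codon]))
            if (length(doses) >= 2L) {
                for (i in seq_len(length(doses) - 1L)) {
                    g1 <- grab(doses[i], codon, time)
                    g2 <- grab(doses[i + 1L], codon, time)
                    dose_rows[[length(dose_rows) + 1L]] <- data.frame(
                        stop_codon = codon, time_h = time,
                        dose1 = doses[i], dose2 = doses[i + 1L],
                        n1 = length(g1), n2 = length(g2),
                        p_value = rankSumP(g1, g2))
                }
                sub <- fc[fc$time_h == time & fc$stop_codon == codon, ]
                kw <- kruskal.test(sub$fold_change, factor(sub$dose_um))
                kw_rows[[length(kw_rows) + 1L]] <- data.frame(
                    stop_codon = codon, time_h = time,
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
            }
        }
        for (dose in sort(unique(fc$dose_um[fc$time_h == time]))) {
            cds <- sort(unique(
                fc$stop_codon[fc$time_h == time & fc$dose_um == dose]))
            if (length(cds) >= 2L) {
                pairs <- utils::combn(cds, 2L)
                for (j in seq_len(ncol(pairs))) {
                    g1 <- grab(dose, pairs[1L, j], time)
                    g2 <- grab(dose, pairs[2L, j], time)
                    codon_rows[[length(codon_rows) + 1L]] <- data.frame(
                        dose_um = dose, time_h = time,
                        codon1 = pairs[1L, j], codon2 = pairs[2L, j],
                        n1 = length(g1), n2 = length(g2),
                        p_value = rankSumP(g1, g2))
                }
            }
        }
    }
    finish <- function(rows) {
        if (!length(rows)) return(NULL)
        out <- do.call(rbind, rows)
        out$significant <- out$p_value < alpha
        rownames(out) <- NULL
        out
    }
    list(dose_contrasts = finish(dose_rows),
         codon_contrasts = finish(codon_rows),
         kruskal = if (length(kw_rows)) {
             out <- do.call(rbind, kw_rows); rownames(out) <- NULL; out
         } else NULL)
}

#' Competition-assay fold change in fluor-positive representation
#'
#' For each sgRNA-marked population tracked by flow cytometry, computes
#' `fold = (pct(drug, t) / pct(drug, 0)) / (pct(vehicle, t) / pct(vehicle,
#' 0))`. Values above 1 indicate drug resistance (enrichment of the edited
#' population), below 1 sensitization (depletion). Per-gene summaries average
#' over that gene's sgRNAs with a standard error.
#'
#' @param data data frame with columns `gene`, `sgrna`, `arm`, `day`,
#'   `pct_pos` (percent fluor-positive cells).
#' @param endDay timepoint compared to day `startDay`.
#' @param startDay baseline day (default 0).
#' @param drugArm,vehicleArm values of `arm` identifying the two treatment
#'   arms (defaults `"drug"` and `"DMSO"`).
#' @return A list with `per_sgrna` (`gene`, `sgrna`, `fold_change`) and
#'   `per_gene` (`gene`, `n_sgrna`, `mean_fold`, `se_fold`).
#' @export
competitionFoldChange <- function(data, endDay, startDay = 0,
                                  drugArm = "drug", vehicleArm = "DMSO") {
    data <- as.data.frame(data)
    stopifnot(all(c("gene", "sgrna", "arm", "day", "pct_pos") %in%
                      colnames(data)))
    pick <- function(sg, arm, day) {
        v <- data$pct_pos[data$sgrna == sg & data$arm == arm &
                              data$day == day]
        if (length(v) != 1L)
            stop("expected exactly one pct_pos for sgRNA ", sg, ", arm ",
                 arm, ", day ", day, call. = FALSE)
        v
    }
    sgs <- unique(data[, c("gene", "sgrna")])
    fold <- vapply(seq_len(nrow(sgs)), function(i) {
        sg <- sgs$sgrna[i]
        d0 <- pick(sg, drugArm, startDay)
        v0 <- pick(sg, vehicleArm, startDay)
        if (d0 <= 0 || v0 <= 0)
            stop("zero day-", startDay, " percentage for sgRNA ", sg,
                 call. = FALSE)
        (pick(sg, drugArm, endDay) / d0) /
            (pick(sg, vehicleArm, endDay) / v0)
    }, numeric(1))
    per_sgrna <- data.frame(gene = sgs$gene, sgrna = sgs$sgrna,
                            fold_change = fold)
    per_gene <- do.call(rbind, lapply(split(per_sgrna, per_sgrna$gene),
        function(g) data.frame(
            gene = g$gene[1L], n_sgrna = nrow(g),
            mean_fold = mean(g$fold_change),
            se_fold = if (nrow(g) > 1L)
                sd(g$fold_change) / sqrt(nrow(g)) else NA_real_)))
    rownames(per_gene) <- NULL
    list(per_sgrna = per_sgrna, per_gene = per_gene)
}

#' Read and write reporter event CSVs
#'
#' Events CSV columns: `gfp, bfp, live, drug, dose_um, time_h, construct,
#' stop_codon` (plus optional `replicate`).
#'
#' @param events an event table.
#' @param file path to the CSV.
#' @return `readReporterEvents()` returns a `data.frame`;
#'   `writeReporterEvents()` invisibly returns `file`.
#' @export
readReporterEvents <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    df$live <- as.logical(df$live)
    df
}

#' @rdname readReporterEvents
#' @export
writeReporterEvents <- function(events, file) {
    utils::write.csv(events, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}
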