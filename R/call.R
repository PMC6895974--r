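#' @include methods.R
NULL

#' Estimate tumor fraction from the fragment-size distribution
#'
#' ctDNA molecules are shorter than cell-free DNA from normal cells; the
#' proportion of cfDNA fragments shorter than \code{thresholdBp} (default
#' 150 bp) is taken as the ctDNA fraction p of the sample.
#'
#' @param dist a \linkS4class{FragmentSizeDistribution}.
#' @param thresholdBp length cutoff in bp (default 150).
#' @return A \linkS4class{TumorFractionEstimate}.
#' @examples
#' d <- FragmentSizeDistribution("s1", c(120, 160), c(30, 70))
#' tumorFraction(estimateTumorFraction(d))  # 0.3
#' @export
estimateTumorFraction <- function(dist, thresholdBp = 150L) {
    stopifnot(is(dist, "FragmentSizeDistribution"), thresholdBp > 0)
    total <- totalFragments(dist)
    if (total < 1L)
        stop("empty fragment-size distribution for sample ", sampleId(dist),
             call. = FALSE)
    short <- sum(dist@counts[dist@lengths < thresholdBp])
    TumorFractionEstimate(sampleId(dist), short, total,
                          thresholdBp = thresholdBp)
}

#' Expected log2 ratio of a gene with given absolute copy number
#'
#' In a sample with tumor fraction p, a gene of absolute copy number ABCN in
#' the tumor appears against a diploid background as
#' \code{log2((ABCN * p + 2 * (1 - p)) / 2)}.
#'
#' @param abcn absolute copy number (>= 0).
#' @param p tumor fraction in (0, 1].
#' @return Numeric log2 ratio (vectorized over both arguments).
#' @examples
#' log2RatioFromAbcn(2, 0.37)    # 0: diploid is neutral at any purity
#' log2RatioFromAbcn(60, 0.003)  # ~0.1204
#' @export
log2RatioFromAbcn <- function(abcn, p) {
    stopifnot(all(abcn >= 0))
    if (any(p <= 0 | p > 1))
        stop("tumor fraction p must lie in (0, 1]", call. = FALSE)
    mix <- abcn * p + 2 * (1 - p)
    stopifnot(all(mix > 0))
    log2(mix / 2)
}

#' Absolute copy number from a gene log2 ratio and tumor fraction
#'
#' Exact inverse of \code{\link{log2RatioFromAbcn}}:
#' \code{ABCN = 2 * (2^log2Ratio + p - 1) / p}, floored at 0.
#'
#' @param log2Ratio gene-level log2 ratio.
#' @param p tumor fraction in (0, 1]; \code{p = 0} returns \code{NA}
#'   (copy number not evaluable) rather than an error.
#' @return Numeric absolute copy number (vectorized).
#' @examples
#' abcnFromLog2Ratio(0, 0.8)  # 2
#' abcnFromLog2Ratio(1, 1)    # 4
#' @export
abcnFromLog2Ratio <- function(log2Ratio, p) {
    if (any(p < 0 | p > 1))
        stop("tumor fraction p must lie in [0, 1]", call. = FALSE)
    out <- pmax(2 * (2^log2Ratio + p - 1) / p, 0)
    out[p == 0] <- NA_real_
    out
}

#' Effective copy number of a tumor-into-normal dilution
#'
#' The copy number apparent in a mixture of tumor fraction p with diploid
#' background: \code{ABCN * p + 2 * (1 - p)}. At the detection-limit
#' dilution this is the smallest effective copy number the pipeline can
#' call.
#'
#' @param abcn absolute copy number in the tumor (>= 0).
#' @param p tumor fraction in [0, 1].
#' @return Numeric effective copy number (vectorized).
#' @examples
#' effectiveCopyNumber(60, 0.003)  # 2.174 ~ 2.2 copies
#' @export
effectiveCopyNumber <- function(abcn, p) {
    stopifnot(all(abcn >= 0), all(p >= 0 & p <= 1))
    abcn * p + 2 * (1 - p)
}

#' Call gene amplifications from segmented log ratios
#'
#' The per-sample amplification threshold is \code{max(3 * SD, floor)} where
#' SD is the population standard deviation of the segment-level log ratios
#' (the floor guards the degenerate single-segment sample whose SD is 0).
#' Each gene's log2 ratio is the probe-count-weighted mean of the segment
#' means overlapping its probes; a gene is called amplified when its log2
#' ratio is strictly above the threshold. When a tumor fraction estimate
#' with p > 0 is supplied, the absolute copy number is computed by
#' \code{\link{abcnFromLog2Ratio}}; otherwise the status is still reported
#' and the copy number is \code{NA}. Only gains are considered; deletions
#' are never called.
#'
#' @param segments a \linkS4class{SegmentSet} for the sample.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param profile the \linkS4class{LogRatioProfile} that was segmented
#'   (source of the per-probe mask).
#' @param tf a \linkS4class{TumorFractionEstimate}, a bare numeric tumor
#'   fraction in [0, 1], or NULL (no copy-number estimation).
#' @param thresholdFloor minimum amplification threshold (default 0.1).
#' @param genes genes to evaluate (default: all genes on the panel).
#' @return data.frame with one row per gene: sample, gene, log2_ratio,
#'   threshold, status (\code{amplified} / \code{neutral} /
#'   \code{not_evaluable}), tumor_fraction, abcn.
#' @export
callAmplifications <- function(segments, panel, profile, tf = NULL,
                               thresholdFloor = 0.1, genes = NULL) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(profile), "profile")
    stopifnot(is(segments, "SegmentSet"))
    p <- if (is.null(tf)) NA_real_
         else if (is(tf, "TumorFractionEstimate")) tumorFraction(tf)
         else as.numeric(tf)
    if (!is.na(p) && (p < 0 || p > 1))
        stop("tumor fraction must lie in [0, 1]", call. = FALSE)
    allGenes <- unique(probeGenes(panel))
    allGenes <- allGenes[allGenes != ""]
    if (is.null(genes)) genes <- allGenes
    missing <- setdiff(genes, allGenes)
    if (length(missing))
        stop("genes absent from panel: ", paste(missing, collapse = ", "),
             call. = FALSE)
    st <- segTable(segments)
    threshold <- max(3 * segmentSd(segments), thresholdFloor)
    mask <- probeMask(profile)
    rows <- lapply(genes, function(g) {
        idx <- geneProbeIndex(panel, g)
        idx <- idx[!mask[idx]]
        if (!length(idx))
            return(data.frame(sample = sampleId(segments), gene = g,
                              log2_ratio = NA_real_, threshold = threshold,
                              status = "not_evaluable",
                              tumor_fraction = p, abcn = NA_real_,
                              stringsAsFactors = FALSE))
        w <- vapply(seq_len(nrow(st)), function(s)
            sum(idx > st$probe_start[s] & idx <= st$probe_end[s]), numeric(1))
        lr <- sum(w * st$mean_log2) / sum(w)
        status <- if (lr > threshold) "amplified" else "neutral"
        abcn <- if (is.na(p) || p == 0) NA_real_
                else abcnFromLog2Ratio(lr, p)
        data.frame(sample = sampleId(segments), gene = g, log2_ratio = lr,
                   threshold = threshold, status = status,
                   tumor_fraction = p, abcn = abcn, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Enrichment odds ratio for a 2x2 amplification table
#'
#' Odds ratio \code{(a/b) / (c/d)} for amplified/not-amplified counts in two
#' groups, with Fisher's exact p-value when the counts are integral. A zero
#' cell triggers the Haldane-Anscombe correction (+0.5 to every cell),
#' flagged in the result.
#'
#' @param a,b amplified / not-amplified counts in group 1.
#' @param c,d amplified / not-amplified counts in group 2.
#' @return list with elements \code{or}, \code{fisher_p} (NA for
#'   non-integral counts) and \code{haldane} (logical).
#' @examples
#' enrichmentOddsRatio(10, 90, 10, 90)$or  # 1
#' @export
enrichmentOddsRatio <- function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
        stop("zero marginal in 2x2 table", call. = FALSE)
    haldane <- any(c(a, b, c, d) == 0)
    if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    or <- (a / b) / (c / d)
    fisher_p <- NA_real_
    if (all(abs(c(a, b, c, d) - round(c(a, b, c, d))) < 1e-9))
        fisher_p <- stats::fisher.test(
            matrix(round(c(a, b, c, d)), 2L, byrow = TRUE))$p.value
    list(or = or, fisher_p = fisher_p, haldane = haldane)
}

#' Odds ratio from two group proportions
#'
#' Convenience wrapper: \code{(p1 / (1 - p1)) / (p2 / (1 - p2))}.
#'
#' @param p1,p2 amplification proportions in the two groups, in (0, 1).
#' @return Numeric odds ratio.
#' @export
oddsRatioFromProportions <- function(p1, p2) {
    stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
    (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Write gene CNV calls to a TSV
#'
#' @param calls data.frame from \code{\link{callAmplifications}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCnvCalls <- function(calls, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(), con)
    utils::write.table(calls, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write amplified calls as a minimal VCF dialect
#'
#' Emits one symbolic \code{<DUP>} record per amplified gene, spanning the
#' gene's probe footprint, with the copy number (when evaluable) and gene
#' log2 ratio in INFO. This is a small fixed dialect for interoperability,
#' not a full VCF writer.
#'
#' @param calls data.frame from \code{\link{callAmplifications}}.
#' @param panel the \linkS4class{ProbePanel} (source of gene coordinates).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCnvVcf <- function(calls, panel, path) {
    tab <- panelTable(panel)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##source=plasmaCNV_v%s",
                         utils::packageVersion("plasmaCNV")),
                 "##ALT=<ID=DUP,Description=\"Gene amplification\">",
                 "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the gene probe footprint\">",
                 "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
                 "##INFO=<ID=LOG2R,Number=1,Type=Float,Description=\"Gene log2 ratio\">",
                 "##INFO=<ID=CN,Number=1,Type=Float,Description=\"Absolute copy number\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    amp <- calls[calls$status == "amplified", , drop = FALSE]
    for (r in seq_len(nrow(amp))) {
        g <- amp$gene[r]
        rows <- tab[tab$gene == g, , drop = FALSE]
        info <- sprintf("END=%d;GENE=%s;LOG2R=%.4f", max(rows$end), g,
                        amp$log2_ratio[r])
        if (!is.na(amp$abcn[r]))
            info <- paste0(info, sprintf(";CN=%.2f", amp$abcn[r]))
        writeLines(sprintf("%s\t%d\t%s_amp\tN\t<DUP>\t.\tPASS\t%s",
                           rows$chrom[1L], min(rows$start) + 1L, g, info),
                   con)
    }
    invisible(path)
}
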