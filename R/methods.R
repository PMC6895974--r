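#' @include AllGenerics.R
NULL

#' Construct a ProbePanel from per-probe vectors
#'
#' Rows may arrive in any order; the constructor sorts probes by
#' (chromosome, start). Coordinates are BED-style 0-based half-open.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open probe coordinates.
#' @param probe_id unique probe identifiers.
#' @param gene gene symbol per probe ("" allowed).
#' @param gc_fraction GC fraction of the probe sequence, in [0, 1].
#' @param overlap_score non-negative degree of overlap with neighboring
#'   probes.
#' @param mappability alignability of the probe region, in [0, 1].
#' @return A \linkS4class{ProbePanel}.
#' @examples
#' ProbePanel(chrom = "chr7", start = c(0, 200), end = c(120, 320),
#'            probe_id = c("p1", "p2"), gene = "EGFR",
#'            gc_fraction = c(0.4, 0.5), overlap_score = 0,
#'            mappability = 1)
#' @export
ProbePanel <- function(chrom, start, end, probe_id, gene,
                       gc_fraction, overlap_score, mappability) {
    n <- length(probe_id)
    df <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start), end = as.numeric(end),
                     probe_id = as.character(probe_id),
                     gene = rep_len(as.character(gene), n),
                     gc_fraction = rep_len(as.numeric(gc_fraction), n),
                     overlap_score = rep_len(as.numeric(overlap_score), n),
                     mappability = rep_len(as.numeric(mappability), n),
                     stringsAsFactors = FALSE)
    bad <- which(!(df$start < df$end))
    if (length(bad))
        stop("probe intervals must satisfy start < end (rows: ",
             paste(bad, collapse = ", "), ")", call. = FALSE)
    df <- df[order(df$chrom, df$start, df$end, df$probe_id), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
        probe_id = df$probe_id, gene = df$gene,
        gc_fraction = df$gc_fraction, overlap_score = df$overlap_score,
        mappability = df$mappability)
    cs <- .panelChecksumFrom(df$chrom, df$start, df$end, df$probe_id,
                             df$gene, df$gc_fraction, df$overlap_score,
                             df$mappability)
    new("ProbePanel", ranges = gr, checksum = cs)
}

#' Construct a DepthProfile
#'
#' @param sampleId sample identifier.
#' @param depths numeric per-probe depths in panel order.
#' @param panel the \linkS4class{ProbePanel} the depths are aligned to.
#' @param stage normalization stage (default "raw").
#' @return A \linkS4class{DepthProfile}.
#' @export
DepthProfile <- function(sampleId, depths, panel, stage = "raw") {
    if (length(depths) != nProbes(panel))
        stop("depths length (", length(depths),
             ") does not match panel probe count (", nProbes(panel), ")",
             call. = FALSE)
    new("DepthProfile", sampleId = as.character(sampleId),
        depths = as.numeric(depths), stage = stage,
        panelChecksum = panelChecksum(panel))
}

#' Construct a FragmentSizeDistribution from a histogram
#'
#' @param sampleId sample identifier.
#' @param lengths fragment lengths in bp (need not be sorted or unique;
#'   counts at duplicate lengths are summed).
#' @param counts fragment counts parallel to \code{lengths}.
#' @return A \linkS4class{FragmentSizeDistribution}.
#' @examples
#' FragmentSizeDistribution("s1", lengths = c(120, 160, 170),
#'                          counts = c(1, 1, 1))
#' @export
FragmentSizeDistribution <- function(sampleId, lengths, counts) {
    lengths <- as.integer(round(lengths))
    counts <- as.integer(round(counts))
    keep <- counts != 0L
    agg <- rowsum(as.numeric(counts[keep]), lengths[keep])
    len <- as.integer(rownames(agg))
    o <- order(len)
    new("FragmentSizeDistribution", sampleId = as.character(sampleId),
        lengths = len[o], counts = as.integer(agg[o, 1L]))
}

#' Construct a LogRatioProfile from per-probe values
#'
#' Mostly useful for assembling profiles from external tools or fixtures;
#' the pipeline itself produces log-ratio profiles via
#' \code{\link{ponLogRatio}}.
#'
#' @param sampleId sample identifier.
#' @param log2Ratios numeric per-probe log2 ratios in panel order (NA where
#'   masked).
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param mask logical exclusion mask (default: the NA entries).
#' @return A \linkS4class{LogRatioProfile}.
#' @export
LogRatioProfile <- function(sampleId, log2Ratios, panel, mask = NULL) {
    if (length(log2Ratios) != nProbes(panel))
        stop("log2Ratios length does not match panel probe count",
             call. = FALSE)
    if (is.null(mask)) mask <- is.na(log2Ratios)
    new("LogRatioProfile", sampleId = as.character(sampleId),
        log2Ratios = as.numeric(log2Ratios), mask = as.logical(mask),
        panelChecksum = panelChecksum(panel))
}

#' Construct a TumorFractionEstimate directly from counts
#'
#' @param sampleId sample identifier.
#' @param shortCount fragments shorter than \code{thresholdBp}.
#' @param totalCount all qualifying fragments.
#' @param thresholdBp length cutoff in bp (default 150).
#' @return A \linkS4class{TumorFractionEstimate}.
#' @export
TumorFractionEstimate <- function(sampleId, shortCount, totalCount,
                                  thresholdBp = 150L) {
    new("TumorFractionEstimate", sampleId = as.character(sampleId),
        p = shortCount / totalCount, shortCount = as.integer(shortCount),
        totalCount = as.integer(totalCount),
        thresholdBp = as.integer(thresholdBp))
}

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("nProbes", "ProbePanel", function(x) length(x@ranges))
#' @rdname accessors
#' @export
setMethod("probeIds", "ProbePanel",
    function(x) GenomicRanges::mcols(x@ranges)$probe_id)
#' @rdname accessors
#' @export
setMethod("probeGenes", "ProbePanel",
    function(x) GenomicRanges::mcols(x@ranges)$gene)
#' @rdname accessors
#' @export
setMethod("probeRanges", "ProbePanel", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("panelChecksum", "ProbePanel", function(x) x@checksum)
#' @rdname accessors
#' @export
setMethod("geneProbeIndex", "ProbePanel", function(x, gene) {
    idx <- which(probeGenes(x) == gene)
    if (!length(idx)) stop("gene not on panel: ", gene, call. = FALSE)
    idx
})

#' Per-probe covariates of a panel
#'
#' @param x a \linkS4class{ProbePanel}.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   probe_id, gene, gc_fraction, overlap_score, mappability, in panel order.
#' @export
panelTable <- function(x) {
    stopifnot(is(x, "ProbePanel"))
    gr <- x@ranges
    mc <- GenomicRanges::mcols(gr)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               probe_id = mc$probe_id, gene = mc$gene,
               gc_fraction = mc$gc_fraction,
               overlap_score = mc$overlap_score,
               mappability = mc$mappability,
               stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "DepthProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("depths", "DepthProfile", function(x) x@depths)
#' @rdname accessors
#' @export
setMethod("depthStage", "DepthProfile", function(x) x@stage)
#' @rdname accessors
#' @export
setMethod("panelChecksum", "DepthProfile", function(x) x@panelChecksum)

#' @rdname accessors
#' @export
setMethod("sampleId", "FragmentSizeDistribution", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("fragmentCounts", "FragmentSizeDistribution",
    function(x) stats::setNames(x@counts, x@lengths))
#' @rdname accessors
#' @export
setMethod("totalFragments", "FragmentSizeDistribution",
    function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("sampleId", "LogRatioProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("log2Ratios", "LogRatioProfile", function(x) x@log2Ratios)
#' @rdname accessors
#' @export
setMethod("probeMask", "LogRatioProfile", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("panelChecksum", "LogRatioProfile", function(x) x@panelChecksum)

#' @rdname accessors
#' @export
setMethod("panelChecksum", "PanelOfNormals", function(x) x@panelChecksum)
#' @rdname accessors
#' @export
setMethod("excludedProbes", "PanelOfNormals", function(x) which(x@excluded))
#' @rdname accessors
#' @export
setMethod("panelChecksum", "BiasModel", function(x) x@panelChecksum)

#' @rdname accessors
#' @export
setMethod("sampleId", "SegmentSet", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("segTable", "SegmentSet", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("segmentSd", "SegmentSet", function(x) x@sdSegments)

#' @rdname accessors
#' @export
setMethod("sampleId", "TumorFractionEstimate", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("tumorFraction", "TumorFractionEstimate", function(x) x@p)

## ---- show methods ----

setMethod("show", "ProbePanel", function(object) {
    g <- unique(probeGenes(object))
    g <- g[g != ""]
    cat("ProbePanel:", nProbes(object), "probes,", length(g), "genes,",
        length(unique(as.character(GenomicRanges::seqnames(object@ranges)))),
        "chromosomes\n")
    cat("  checksum:", object@checksum, "\n")
})

setMethod("show", "DepthProfile", function(object) {
    cat("DepthProfile:", object@sampleId, "(", object@stage, ")\n")
    cat("  ", length(object@depths), "probes; mean depth",
        format(mean(object@depths), digits = 4), "\n")
})

setMethod("show", "FragmentSizeDistribution", function(object) {
    cat("FragmentSizeDistribution:", object@sampleId, "\n")
    cat("  ", sum(object@counts), "fragments over",
        length(object@lengths), "distinct lengths [",
        min(object@lengths), "-", max(object@lengths), "bp ]\n")
})

setMethod("show", "PanelOfNormals", function(object) {
    cat("PanelOfNormals:", object@nSamples, "samples,",
        length(object@probeMedian), "probes (",
        sum(object@excluded), "excluded )\n")
    cat("  panel checksum:", object@panelChecksum, "\n")
})

setMethod("show", "BiasModel", function(object) {
    cat("BiasModel:", if (is.null(object@gcFit)) "identity GC curve"
        else "loess GC curve", "\n")
    cat("  covariate coefficients:",
        paste(names(object@covariateCoef),
              format(object@covariateCoef, digits = 3),
              sep = "=", collapse = ", "), "\n")
    cat("  residual spread (MAD):",
        format(object@residualSpread, digits = 3), "\n")
})

setMethod("show", "LogRatioProfile", function(object) {
    ok <- !object@mask
    cat("LogRatioProfile:", object@sampleId, "\n")
    cat("  ", sum(ok), "evaluable probes; median log2 ratio",
        format(stats::median(object@log2Ratios[ok]), digits = 3), "\n")
})

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet:", object@sampleId, "-", nrow(object@segments),
        "segments; SD of segment means",
        format(object@sdSegments, digits = 4), "\n")
})

setMethod("show", "TumorFractionEstimate", function(object) {
    cat("TumorFractionEstimate:", object@sampleId, "- p =",
        format(object@p, digits = 4),
        sprintf("(%d/%d fragments < %d bp)\n", object@shortCount,
                object@totalCount, object@thresholdBp))
})
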