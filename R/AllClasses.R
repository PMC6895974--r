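#' @import methods
#' @importFrom GenomicRanges GRanges mcols seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' ProbePanel: the capture-panel design
#'
#' Genomic intervals of the hybridization probes, one per target region,
#' together with the three per-probe bias covariates (GC fraction, probe
#' overlap score, mappability) and a gene assignment. Probes are stored as a
#' \link[GenomicRanges]{GRanges} sorted by (chromosome, start); all public
#' coordinates (panel files, exports) are BED-style 0-based half-open.
#'
#' @slot ranges GRanges of probe intervals with metadata columns
#'   \code{probe_id}, \code{gene}, \code{gc_fraction}, \code{overlap_score},
#'   \code{mappability}.
#' @slot checksum character scalar binding downstream objects (panel of
#'   normals, bias model) to this panel.
#' @export
setClass("ProbePanel",
    representation(ranges = "GRanges", checksum = "character"))

setValidity("ProbePanel", function(object) {
    gr <- object@ranges
    mc <- GenomicRanges::mcols(gr)
    need <- c("probe_id", "gene", "gc_fraction", "overlap_score", "mappability")
    if (!all(need %in% colnames(mc)))
        return(paste("missing probe metadata columns:",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (anyDuplicated(mc$probe_id))
        return("duplicate probe_id values in panel")
    if (any(GenomicRanges::width(gr) < 1))
        return("probe intervals must satisfy start < end")
    if (any(mc$gc_fraction < 0 | mc$gc_fraction > 1))
        return("gc_fraction must lie in [0, 1]")
    if (any(mc$mappability < 0 | mc$mappability > 1))
        return("mappability must lie in [0, 1]")
    if (any(mc$overlap_score < 0))
        return("overlap_score must be non-negative")
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    if (!identical(o, seq_along(gr)))
        return("probes must be sorted by (chromosome, start)")
    TRUE
})

.PROFILE_STAGES <- c("raw", "median_normalized", "bias_corrected")

#' DepthProfile: one sample's per-probe depths
#'
#' Mean per-base coverage per probe, aligned to the probe order of a
#' \linkS4class{ProbePanel}, at one of the normalization stages
#' \code{raw}, \code{median_normalized} or \code{bias_corrected}.
#'
#' @slot sampleId character scalar.
#' @slot depths numeric vector, one value per panel probe, all >= 0.
#' @slot stage character scalar, the normalization stage.
#' @slot panelChecksum checksum of the panel the profile is aligned to.
#' @export
setClass("DepthProfile",
    representation(sampleId = "character", depths = "numeric",
                   stage = "character", panelChecksum = "character"))

setValidity("DepthProfile", function(object) {
    if (length(object@stage) != 1L || !object@stage %in% .PROFILE_STAGES)
        return(paste("stage must be one of:",
                     paste(.PROFILE_STAGES, collapse = ", ")))
    if (any(!is.finite(object@depths)) || any(object@depths < 0))
        return("depths must be finite and >= 0")
    TRUE
})

#' FragmentSizeDistribution: histogram of cfDNA template lengths
#'
#' @slot sampleId character scalar.
#' @slot lengths integer vector of fragment lengths (bp), sorted, >= 1.
#' @slot counts integer vector of non-negative counts parallel to
#'   \code{lengths}.
#' @export
setClass("FragmentSizeDistribution",
    representation(sampleId = "character", lengths = "integer",
                   counts = "integer"))

setValidity("FragmentSizeDistribution", function(object) {
    if (length(object@lengths) != length(object@counts))
        return("lengths and counts must be parallel vectors")
    if (any(object@lengths < 1L)) return("fragment lengths must be >= 1")
    if (is.unsorted(object@lengths, strictly = TRUE))
        return("lengths must be strictly increasing")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    TRUE
})

#' BiasModel: combined GC / overlap / mappability depth-bias model
#'
#' Fitted on the per-probe median of median-normalized healthy-donor depths:
#' a local (loess) regression of depth on GC fraction, followed by a linear
#' correction on probe overlap score and mappability, and a global rescale so
#' the median corrected training depth is exactly 1.
#'
#' @slot gcFit the loess fit for the GC curve, or NULL when GC was
#'   degenerate (constant) and the curve is the identity.
#' @slot covariateCoef named numeric coefficients (intercept, overlap_score,
#'   mappability) of the linear stage; unidentifiable terms are 0.
#' @slot scale numeric global rescaling constant.
#' @slot residualSpread numeric, MAD of training residuals (diagnostics).
#' @slot panelChecksum checksum of the training panel.
#' @export
setClass("BiasModel",
    representation(gcFit = "ANY", covariateCoef = "numeric", scale = "numeric",
                   residualSpread = "numeric", panelChecksum = "character"))

#' PanelOfNormals: per-probe reference model from healthy-donor cfDNA
#'
#' @slot panelChecksum checksum of the bound panel.
#' @slot nSamples integer, number of healthy-donor samples (>= 2).
#' @slot probeMedian per-probe median of bias-corrected normalized depth.
#' @slot probeSd per-probe robust scale (1.4826 x MAD across normals).
#' @slot excluded logical mask of probes dropped for low/erratic coverage.
#' @export
setClass("PanelOfNormals",
    representation(panelChecksum = "character", nSamples = "integer",
                   probeMedian = "numeric", probeSd = "numeric",
                   excluded = "logical"))

setValidity("PanelOfNormals", function(object) {
    n <- length(object@probeMedian)
    if (length(object@probeSd) != n || length(object@excluded) != n)
        return("probeMedian, probeSd and excluded must have equal length")
    if (object@nSamples < 2L) return("a panel of normals needs >= 2 samples")
    if (any(object@probeMedian[!object@excluded] <= 0))
        return("non-excluded probes must have positive median depth")
    if (any(object@probeSd < 0)) return("probeSd must be >= 0")
    TRUE
})

#' LogRatioProfile: per-probe log2 ratios against the panel of normals
#'
#' @slot sampleId character scalar.
#' @slot log2Ratios numeric vector aligned to the panel; NA where masked.
#' @slot mask logical; TRUE marks probes excluded from segmentation.
#' @slot panelChecksum checksum of the panel.
#' @export
setClass("LogRatioProfile",
    representation(sampleId = "character", log2Ratios = "numeric",
                   mask = "logical", panelChecksum = "character"))

setValidity("LogRatioProfile", function(object) {
    if (length(object@log2Ratios) != length(object@mask))
        return("log2Ratios and mask must have equal length")
    if (any(!is.finite(object@log2Ratios[!object@mask])))
        return("non-masked log2 ratios must be finite")
    TRUE
})

#' SegmentSet: circular-binary-segmentation output for one sample
#'
#' Segments partition the non-masked probes of each chromosome into runs of
#' constant mean log2 ratio. \code{probe_start}/\code{probe_end} are
#' half-open indices into the panel's probe order; \code{n_probes} counts the
#' non-masked probes contributing to the segment mean (equal to
#' \code{probe_end - probe_start} when nothing is masked).
#'
#' @slot sampleId character scalar.
#' @slot segments data.frame with columns chrom, probe_start, probe_end,
#'   start, end (bp, 0-based half-open), n_probes, mean_log2.
#' @slot sdSegments population standard deviation of the segment means.
#' @slot params list of segmentation parameters (alpha, nPermutations, seed).
#' @export
setClass("SegmentSet",
    representation(sampleId = "character", segments = "data.frame",
                   sdSegments = "numeric", params = "list"))

#' TumorFractionEstimate: insert-size-based ctDNA fraction
#'
#' The proportion of cfDNA fragments shorter than \code{thresholdBp}
#' (default 150 bp) is taken as the ctDNA fraction p of the sample.
#'
#' @slot sampleId character scalar.
#' @slot p tumor (ctDNA) fraction in [0, 1].
#' @slot shortCount,totalCount integer fragment counts.
#' @slot thresholdBp integer length cutoff in bp.
#' @export
setClass("TumorFractionEstimate",
    representation(sampleId = "character", p = "numeric",
                   shortCount = "integer", totalCount = "integer",
                   thresholdBp = "integer"))

setValidity("TumorFractionEstimate", function(object) {
    if (object@totalCount < 1L) return("totalCount must be >= 1")
    if (object@shortCount < 0L || object@shortCount > object@totalCount)
        return("shortCount must lie in [0, totalCount]")
    if (abs(object@p - object@shortCount / object@totalCount) > 1e-12)
        return("p must equal shortCount / totalCount")
    TRUE
})
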