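#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("depthStage", function(x) standardGeneric("depthStage"))
#' @rdname accessors
#' @export
setGeneric("panelChecksum", function(x) standardGeneric("panelChecksum"))
#' @rdname accessors
#' @export
setGeneric("nProbes", function(x) standardGeneric("nProbes"))
#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setGeneric("probeGenes", function(x) standardGeneric("probeGenes"))
#' @rdname accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))
#' @rdname accessors
#' @export
setGeneric("geneProbeIndex", function(x, gene) standardGeneric("geneProbeIndex"))
#' @rdname accessors
#' @export
setGeneric("log2Ratios", function(x) standardGeneric("log2Ratios"))
#' @rdname accessors
#' @export
setGeneric("probeMask", function(x) standardGeneric("probeMask"))
#' @rdname accessors
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))
#' @rdname accessors
#' @export
setGeneric("segmentSd", function(x) standardGeneric("segmentSd"))
#' @rdname accessors
#' @export
setGeneric("tumorFraction", function(x) standardGeneric("tumorFraction"))
#' @rdname accessors
#' @export
setGeneric("fragmentCounts", function(x) standardGeneric("fragmentCounts"))
#' @rdname accessors
#' @export
setGeneric("totalFragments", function(x) standardGeneric("totalFragments"))
#' @rdname accessors
#' @export
setGeneric("excludedProbes", function(x) standardGeneric("excludedProbes"))

#' Accessors for plasmaCNV classes
#'
#' Small, read-only accessors for the slots of the pipeline's S4 classes:
#' sample identifiers, per-probe depths and their normalization stage, panel
#' geometry and covariates, log2 ratios and masks, segment tables, the
#' segment-level standard deviation, tumor fraction and fragment histograms.
#'
#' @param x a plasmaCNV object.
#' @param gene gene symbol (for \code{geneProbeIndex}).
#' @return The slot value; see each class's documentation.
#' @name accessors
NULL
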