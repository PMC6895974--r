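#' @include methods.R
NULL

#' Median-normalize a raw depth profile
#'
#' Divides every probe depth by the sample-wide median depth (the median of
#' the positive depths), so the normalized profile has median 1. This removes
#' sample-to-sample differences in total sequencing yield.
#'
#' @param profile a \linkS4class{DepthProfile} with \code{stage = "raw"}.
#' @return A \linkS4class{DepthProfile} with \code{stage =
#'   "median_normalized"}.
#' @examples
#' p <- generatePanel(simConfig(nGenes = 2, probesPerGene = 2))
#' medianNormalize(DepthProfile("s", c(2, 4, 6, 8), p))
#' @export
medianNormalize <- function(profile) {
    stopifnot(is(profile, "DepthProfile"))
    if (depthStage(profile) != "raw")
        stop("medianNormalize expects a raw profile, got stage ",
             depthStage(profile), call. = FALSE)
    d <- depths(profile)
    pos <- d[d > 0]
    if (!length(pos))
        stop("all probe depths are zero for sample ", sampleId(profile),
             call. = FALSE)
    new("DepthProfile", sampleId = sampleId(profile),
        depths = d / stats::median(pos), stage = "median_normalized",
        panelChecksum = profile@panelChecksum)
}

#' Fit the combined GC / overlap / mappability bias model
#'
#' The per-probe median of the median-normalized healthy-donor depths is the
#' training response, modeled multiplicatively as a smooth GC curve (loess,
#' degree 2, direct surface) times a linear term in probe overlap score and
#' mappability. The two components are decoupled by backfitting: the GC
#' curve is fitted to the response divided by the current linear term, the
#' linear term to the response divided by the current GC prediction, for a
#' few alternating passes (otherwise the smooth absorbs covariate structure
#' through chance GC-covariate correlation). Predictions are finally
#' rescaled so that the median corrected training depth is exactly 1. If a
#' covariate is constant across the panel its term drops out (a constant GC
#' additionally triggers a warning and an identity GC curve).
#'
#' @param normals list of \linkS4class{DepthProfile}s at stage
#'   \code{median_normalized} (>= 2 samples, same panel).
#' @param panel the \linkS4class{ProbePanel} carrying the covariates.
#' @param span loess span for the GC curve (default 0.3).
#' @param nIter backfitting passes (default 3).
#' @return A \linkS4class{BiasModel}.
#' @export
fitBiasModel <- function(normals, panel, span = 0.3, nIter = 3L) {
    if (length(normals) < 2L)
        stop("need >= 2 normal samples to fit a bias model", call. = FALSE)
    for (p in normals) {
        .checkSamePanel(panelChecksum(panel), panelChecksum(p), "normal")
        if (depthStage(p) != "median_normalized")
            stop("bias model is fitted on median-normalized depths, got ",
                 depthStage(p), call. = FALSE)
    }
    tab <- panelTable(panel)
    y <- unname(apply(vapply(normals, depths, numeric(nProbes(panel))),
                      1L, stats::median))

    gcDegenerate <- stats::sd(tab$gc_fraction) < 1e-8
    if (gcDegenerate)
        warning("GC fraction is constant across the panel; ",
                "using an identity GC curve")
    terms <- character()
    if (stats::sd(tab$overlap_score) > 1e-8) terms <- c(terms, "overlap_score")
    if (stats::sd(tab$mappability) > 1e-8) terms <- c(terms, "mappability")

    gcFit <- NULL
    lin <- rep(1, length(y))
    coef <- c(intercept = 1, overlap_score = 0, mappability = 0)
    for (iter in seq_len(max(1L, nIter))) {
        if (!gcDegenerate) {
            yGc <- y / lin
            gcFit <- stats::loess(yGc ~ gc,
                                  data.frame(yGc = yGc,
                                             gc = tab$gc_fraction),
                                  degree = 2, span = span,
                                  family = "gaussian",
                                  control = stats::loess.control(
                                      surface = "direct"))
            predGc <- pmax(stats::predict(
                gcFit, data.frame(gc = tab$gc_fraction)), 0.01)
        } else {
            predGc <- rep(1, length(y))
        }
        r <- y / predGc
        if (length(terms)) {
            fml <- stats::reformulate(terms, response = "r")
            fit <- stats::lm(fml, data = cbind(r = r, tab))
            cf <- stats::coef(fit)
            cf[is.na(cf)] <- 0
            coef["intercept"] <- cf[["(Intercept)"]]
            for (t in terms) coef[t] <- cf[[t]]
        } else {
            coef["intercept"] <- stats::median(r)
        }
        lin <- pmax(coef[["intercept"]] +
                        coef[["overlap_score"]] * tab$overlap_score +
                        coef[["mappability"]] * tab$mappability, 0.01)
        if (gcDegenerate && !length(terms)) break
    }

    model <- new("BiasModel", gcFit = gcFit, covariateCoef = coef, scale = 1,
                 residualSpread = 0, panelChecksum = panelChecksum(panel))
    pred <- .predictBias(model, tab)
    corrected <- y / pred
    model@scale <- stats::median(corrected)
    model@residualSpread <- stats::mad(y / (pred * model@scale) - 1)
    model
}

# expected relative depth per probe under the bias model (before rescaling)
.predictBias <- function(model, tab) {
    predGc <- if (is.null(model@gcFit)) rep(1, nrow(tab)) else
        pmax(stats::predict(model@gcFit, data.frame(gc = tab$gc_fraction)),
             0.01)
    cf <- model@covariateCoef
    lin <- cf[["intercept"]] + cf[["overlap_score"]] * tab$overlap_score +
        cf[["mappability"]] * tab$mappability
    unname(pmax(predGc * lin, 0.01))
}

#' Apply a fitted bias model to a depth profile
#'
#' Divides each median-normalized depth by the model's expected relative
#' depth at the probe's covariates. Predictions are floored at 0.01 so that
#' a pathological covariate combination cannot explode the corrected depth.
#'
#' @param profile a \linkS4class{DepthProfile} at stage
#'   \code{median_normalized}.
#' @param model a \linkS4class{BiasModel} fitted on the same panel.
#' @param panel the \linkS4class{ProbePanel}.
#' @return A \linkS4class{DepthProfile} with \code{stage =
#'   "bias_corrected"}.
#' @export
applyBiasModel <- function(profile, model, panel) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(model), "bias model")
    .checkSamePanel(panelChecksum(panel), panelChecksum(profile), "profile")
    if (depthStage(profile) != "median_normalized")
        stop("bias correction applies to median-normalized depths, got ",
             depthStage(profile), call. = FALSE)
    pred <- .predictBias(model, panelTable(panel)) * model@scale
    new("DepthProfile", sampleId = sampleId(profile),
        depths = depths(profile) / pmax(pred, 0.01),
        stage = "bias_corrected", panelChecksum = profile@panelChecksum)
}

#' Expected relative depth of every probe under a bias model
#'
#' The per-probe prediction (GC curve times linear covariate term, times
#' the global rescale) that \code{\link{applyBiasModel}} divides by. This
#' vector is the model's portable form: written next to the panel of
#' normals it lets a later call session correct a sample without refitting.
#'
#' @param model a \linkS4class{BiasModel}.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @return numeric vector of expected relative depths, floored at 0.01.
#' @export
biasExpectedDepth <- function(model, panel) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(model), "bias model")
    pmax(.predictBias(model, panelTable(panel)) * model@scale, 0.01)
}

#' Bias-correct a profile with a precomputed expected-depth vector
#'
#' @param profile a \linkS4class{DepthProfile} at stage
#'   \code{median_normalized}.
#' @param expected per-probe expected relative depth, e.g. from
#'   \code{\link{biasExpectedDepth}} or \code{\link{readBiasTable}}.
#' @return A \linkS4class{DepthProfile} at stage \code{bias_corrected}.
#' @export
applyBiasCorrection <- function(profile, expected) {
    if (depthStage(profile) != "median_normalized")
        stop("bias correction applies to median-normalized depths, got ",
             depthStage(profile), call. = FALSE)
    if (length(expected) != length(depths(profile)))
        stop("expected-depth vector does not match profile length",
             call. = FALSE)
    new("DepthProfile", sampleId = sampleId(profile),
        depths = depths(profile) / pmax(expected, 0.01),
        stage = "bias_corrected", panelChecksum = profile@panelChecksum)
}

#' Write / read the expected-depth table of a bias model
#'
#' Two tab-separated columns probe_id, expected_depth, with header comments
#' carrying the panel checksum.
#'
#' @param model a \linkS4class{BiasModel}.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param path file path.
#' @return \code{writeBiasTable}: \code{path}, invisibly;
#'   \code{readBiasTable}: numeric expected-depth vector in panel order.
#' @export
writeBiasTable <- function(model, panel, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(sprintf("# panel_checksum=%s",
                                   panelChecksum(panel))), con)
    utils::write.table(
        data.frame(probe_id = probeIds(panel),
                   expected_depth = sprintf("%.10g",
                                            biasExpectedDepth(model, panel))),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBiasTable
#' @export
readBiasTable <- function(path, panel) {
    lines <- readLines(path, n = 10L)
    csLine <- grep("panel_checksum=", lines, value = TRUE)
    if (length(csLine))
        .checkSamePanel(panelChecksum(panel),
                        sub(".*panel_checksum=", "", csLine[1L]),
                        "bias table")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!identical(df$probe_id, probeIds(panel)))
        stop("bias table probe order does not match panel: ", path,
             call. = FALSE)
    as.numeric(df$expected_depth)
}

#' Build a panel of normals
#'
#' Per-probe median and robust scale (1.4826 x MAD, i.e. a normal-consistent
#' MAD) of the bias-corrected depths across healthy-donor samples. Probes
#' whose median falls below \code{minDepth} (in median-normalized units) are
#' excluded from downstream log-ratio computation and segmentation.
#'
#' @param normals list of \linkS4class{DepthProfile}s at stage
#'   \code{bias_corrected} (>= 2 samples, same panel).
#' @param minDepth exclusion threshold on the per-probe median (default
#'   0.2).
#' @return A \linkS4class{PanelOfNormals}.
#' @export
buildPon <- function(normals, minDepth = 0.2) {
    if (length(normals) < 2L)
        stop("a panel of normals needs >= 2 samples", call. = FALSE)
    cs <- panelChecksum(normals[[1L]])
    for (p in normals) .checkSamePanel(cs, panelChecksum(p), "normal")
    d <- vapply(normals, depths, numeric(length(depths(normals[[1L]]))))
    med <- unname(apply(d, 1L, stats::median))
    sd <- unname(apply(d, 1L, stats::mad))  # mad() already scales by 1.4826
    excluded <- med < minDepth
    new("PanelOfNormals", panelChecksum = cs,
        nSamples = length(normals), probeMedian = med, probeSd = sd,
        excluded = excluded)
}

#' Log2 ratios of a sample against the panel of normals
#'
#' \code{log2(depth / probeMedian)} per non-excluded probe. A zero depth is
#' replaced by a pseudodepth (half the smallest positive corrected depth of
#' the sample) so a genuine dropout yields a strongly negative, rather than
#' infinite, log ratio.
#'
#' @param profile a \linkS4class{DepthProfile} at stage
#'   \code{bias_corrected}.
#' @param pon a \linkS4class{PanelOfNormals} built on the same panel.
#' @return A \linkS4class{LogRatioProfile}; excluded probes are masked
#'   (\code{NA}).
#' @export
ponLogRatio <- function(profile, pon) {
    .checkSamePanel(panelChecksum(pon), panelChecksum(profile), "profile")
    if (depthStage(profile) != "bias_corrected")
        stop("PoN normalization applies to bias-corrected depths, got ",
             depthStage(profile), call. = FALSE)
    d <- depths(profile)
    pos <- d[d > 0]
    if (length(pos) && any(d == 0)) d[d == 0] <- min(pos) / 2
    lr <- rep(NA_real_, length(d))
    ok <- !pon@excluded
    lr[ok] <- log2(d[ok] / pon@probeMedian[ok])
    new("LogRatioProfile", sampleId = sampleId(profile), log2Ratios = lr,
        mask = pon@excluded, panelChecksum = panelChecksum(profile))
}

#' Write a panel of normals to its TSV serialization
#'
#' Format v1: header comment lines carrying the panel checksum and sample
#' count, then columns probe_id, median, sd, excluded.
#'
#' @param pon a \linkS4class{PanelOfNormals}.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePon <- function(pon, panel, path) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(pon), "PoN")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(c("# plasmaCNV_pon_format=1",
                             sprintf("# panel_checksum=%s",
                                     pon@panelChecksum),
                             sprintf("# n_samples=%d", pon@nSamples))), con)
    utils::write.table(
        data.frame(probe_id = probeIds(panel),
                   median = sprintf("%.10g", pon@probeMedian),
                   sd = sprintf("%.10g", pon@probeSd),
                   excluded = as.integer(pon@excluded)),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a panel of normals from its TSV serialization
#'
#' @param path path written by \code{\link{writePon}}.
#' @param panel the \linkS4class{ProbePanel} the PoN must be bound to.
#' @return A \linkS4class{PanelOfNormals}.
#' @export
readPon <- function(path, panel) {
    lines <- readLines(path)
    hdr <- lines[grepl("^#", lines)]
    csLine <- grep("panel_checksum=", hdr, value = TRUE)
    nsLine <- grep("n_samples=", hdr, value = TRUE)
    if (!length(csLine) || !length(nsLine))
        stop("not a plasmaCNV PoN file (missing header fields): ", path,
             call. = FALSE)
    cs <- sub(".*panel_checksum=", "", csLine[1L])
    .checkSamePanel(panelChecksum(panel), cs, "PoN file")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!identical(df$probe_id, probeIds(panel)))
        stop("PoN probe order does not match panel: ", path, call. = FALSE)
    new("PanelOfNormals", panelChecksum = cs,
        nSamples = as.integer(sub(".*n_samples=", "", nsLine[1L])),
        probeMedian = as.numeric(df$median), probeSd = as.numeric(df$sd),
        excluded = as.logical(as.integer(df$excluded)))
}
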