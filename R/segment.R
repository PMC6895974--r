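#' @include methods.R
NULL

# Max arc-vs-complement t-like statistic over all arcs (i, j], 0 <= i < j <= n
# (arc size 1..n-1). The statistic compares the mean inside the arc with the
# mean of its complement, scaled by the pooled within-group SD, so arcs and
# their complements score identically and scanning i < j covers the
# circularized sequence. Returns NULL when n < 4 (no admissible split).
.maxArcStat <- function(x) {
    n <- length(x)
    if (n < 4L) return(NULL)
    S <- c(0, cumsum(x))
    tot <- S[n + 1L]
    ss <- sum(x * x)
    i <- 0:(n - 1L)                       # arc starts (exclusive)
    j <- 1:n                              # arc ends (inclusive)
    # mat[j, i]: column-major scan order is (i ascending, j within) so
    # which.max breaks ties at the lexicographically smallest (i, j)
    k <- outer(j, i, "-")
    sumIn <- outer(S[j + 1L], S[i + 1L], "-")
    valid <- k >= 1L & k <= n - 1L
    k[!valid] <- 1L                       # placeholder; masked below
    meanIn <- sumIn / k
    meanOut <- (tot - sumIn) / (n - k)
    v <- (ss - k * meanIn^2 - (n - k) * meanOut^2) / (n - 2L)
    v <- pmax(v, 1e-24)
    stat <- abs(meanIn - meanOut) / sqrt(v * (1 / k + 1 / (n - k)))
    stat[!valid] <- -Inf
    best <- which.max(stat)
    jBest <- (best - 1L) %% n + 1L
    iBest <- (best - 1L) %/% n
    list(stat = stat[best], i = iBest, j = jBest)
}

# Sequential permutation p-value for the observed max arc statistic.
# Permutations are drawn one at a time with sample.int; the loop stops as
# soon as enough exceedances have accrued that p >= alpha is certain.
.permPval <- function(x, obsStat, alpha, nPerm) {
    cap <- ceiling(alpha * (nPerm + 1))
    tol <- 1e-9 * max(1, obsStat)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        xs <- x[sample.int(length(x))]
        if (.maxArcStat(xs)$stat >= obsStat - tol) exceed <- exceed + 1L
        if (exceed >= cap) return(1)
    }
    (1 + exceed) / (1 + nPerm)
}

# recursive CBS on one chromosome's values; returns half-open index pairs
# (into x) of the final segments, processed left to right / depth first
.segmentVector <- function(x, alpha, nPerm) {
    segs <- list()
    recurse <- function(lo, hi) {
        n <- hi - lo + 1L
        if (n >= 4L) {
            m <- .maxArcStat(x[lo:hi])
            p <- .permPval(x[lo:hi], m$stat, alpha, nPerm)
            if (p < alpha) {
                b1 <- lo + m$i          # first element of the arc
                b2 <- lo + m$j          # first element after the arc
                if (m$i > 0L) recurse(lo, b1 - 1L)
                recurse(b1, b2 - 1L)
                if (b2 <= hi) recurse(b2, hi)
                return(invisible())
            }
        }
        segs[[length(segs) + 1L]] <<- c(lo, hi)
        invisible()
    }
    if (length(x)) recurse(1L, length(x))
    segs
}

#' Circular binary segmentation of a log-ratio profile
#'
#' Per chromosome, recursively finds the arc of probes maximizing the
#' arc-vs-complement t-like statistic (Olshen-style CBS) and splits when the
#' permutation p-value -- obtained by shuffling the probe values within the
#' chromosome -- falls below \code{alpha}. Masked probes are ignored.
#' Deterministic for a given \code{seed}; the global RNG state is left
#' untouched.
#'
#' @param profile a \linkS4class{LogRatioProfile}.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param alpha significance level for a split (default 0.01).
#' @param nPermutations permutations per split test (default 1000).
#' @param seed integer RNG seed for the permutations (default 1).
#' @return A \linkS4class{SegmentSet}. The segment table carries panel-index
#'   and genomic (bp, 0-based half-open) coordinates, the number of
#'   contributing probes, and the segment mean log2 ratio; \code{segmentSd}
#'   of the result is the population SD of the segment means.
#' @export
cbsSegment <- function(profile, panel, alpha = 0.01, nPermutations = 1000L,
                       seed = 1L) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(profile), "profile")
    stopifnot(alpha > 0, alpha < 1, nPermutations >= 100L)
    lr <- log2Ratios(profile)
    ok <- !probeMask(profile)
    if (!any(ok))
        stop("no evaluable probes in profile ", sampleId(profile),
             call. = FALSE)
    tab <- panelTable(panel)
    chroms <- unique(tab$chrom)
    rows <- .withSeed(seed, function() {
        out <- list()
        for (ch in chroms) {
            idx <- which(tab$chrom == ch & ok)
            if (!length(idx)) next
            x <- lr[idx]
            for (seg in .segmentVector(x, alpha, nPermutations)) {
                pIdx <- idx[seg[1L]:seg[2L]]
                out[[length(out) + 1L]] <- data.frame(
                    chrom = ch,
                    probe_start = pIdx[1L] - 1L,
                    probe_end = pIdx[length(pIdx)],
                    start = tab$start[pIdx[1L]],
                    end = tab$end[pIdx[length(pIdx)]],
                    n_probes = length(pIdx),
                    mean_log2 = mean(lr[pIdx]),
                    stringsAsFactors = FALSE)
            }
        }
        out
    })
    segments <- do.call(rbind, rows)
    new("SegmentSet", sampleId = sampleId(profile), segments = segments,
        sdSegments = .popSd(segments$mean_log2),
        params = list(alpha = alpha, nPermutations = nPermutations,
                      seed = as.integer(seed)))
}

#' Standard deviation of segment-level log ratios
#'
#' Population SD (configurable to the sample SD) of the segment mean log2
#' ratios of a sample -- the per-sample noise scale against which the
#' amplification threshold (3 x SD) is set.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @param type \code{"population"} (default, divisor n) or \code{"sample"}
#'   (divisor n - 1).
#' @return Non-negative numeric scalar; 0 for a single segment.
#' @export
segmentLevelSd <- function(segments, type = c("population", "sample")) {
    stopifnot(is(segments, "SegmentSet"))
    type <- match.arg(type)
    m <- segTable(segments)$mean_log2
    if (!length(m)) stop("empty segment set", call. = FALSE)
    if (length(m) == 1L) return(0)
    if (type == "population") .popSd(m) else stats::sd(m)
}

#' Export segments as a SEG-like table
#'
#' Tab-separated columns sample, chrom, start_bp, end_bp (0-based
#' half-open), n_probes, mean_log2.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegTable <- function(segments, path) {
    st <- segTable(segments)
    con <- file(path, "w")
    on.exit(close(con))
    pm <- segments@params
    writeLines(.toolHeader(sprintf(
        "# sample=%s alpha=%g n_permutations=%d seed=%d sd_segments=%.6g",
        sampleId(segments), pm$alpha, pm$nPermutations, pm$seed,
        segmentSd(segments))), con)
    utils::write.table(
        data.frame(sample = sampleId(segments), chrom = st$chrom,
                   start_bp = st$start, end_bp = st$end,
                   n_probes = st$n_probes, mean_log2 = st$mean_log2),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
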