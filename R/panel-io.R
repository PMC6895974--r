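#' @include methods.R
NULL

#' Read a probe panel file
#'
#' Parses the 8-column tab-separated panel definition: chrom, start, end
#' (BED-style 0-based half-open), probe_id, gene, gc_fraction,
#' overlap_score, mappability. Lines starting with '#' are comments. Rows
#' may be in any order; the returned panel is sorted by (chromosome, start).
#'
#' @param path path to the panel file.
#' @return A \linkS4class{ProbePanel}.
#' @export
readProbePanel <- function(path) {
    if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    if (!any(keep)) stop("panel file has no probe rows: ", path, call. = FALSE)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 8L))
        stop("panel line ", which(keep)[which(nf != 8L)[1L]],
             ": expected 8 tab-separated columns, found ", nf[nf != 8L][1L],
             call. = FALSE)
    m <- do.call(rbind, fields)
    start <- suppressWarnings(as.numeric(m[, 2L]))
    end <- suppressWarnings(as.numeric(m[, 3L]))
    lineno <- which(keep)
    bad <- which(is.na(start) | is.na(end) | !(start < end))
    if (length(bad))
        stop("panel line ", lineno[bad[1L]],
             ": malformed coordinates (need numeric start < end): ",
             lines[lineno[bad[1L]]], call. = FALSE)
    if (anyDuplicated(m[, 4L]))
        stop("duplicate probe_id in panel: ",
             paste(unique(m[duplicated(m[, 4L]), 4L]), collapse = ", "),
             call. = FALSE)
    ProbePanel(chrom = m[, 1L], start = start, end = end,
               probe_id = m[, 4L], gene = m[, 5L],
               gc_fraction = as.numeric(m[, 6L]),
               overlap_score = as.numeric(m[, 7L]),
               mappability = as.numeric(m[, 8L]))
}

#' Write a probe panel file
#'
#' @param panel a \linkS4class{ProbePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbePanel <- function(panel, path) {
    df <- panelTable(panel)
    hdr <- .toolHeader(sprintf("# panel_checksum=%s", panelChecksum(panel)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines("# chrom\tstart\tend\tprobe_id\tgene\tgc_fraction\toverlap_score\tmappability",
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Count per-probe depths from aligned reads
#'
#' Computes mean per-base coverage over every probe interval from a
#' coordinate-sorted, indexed BAM file. Reads below \code{minMapq},
#' duplicates, secondary and supplementary alignments are excluded.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param panel a \linkS4class{ProbePanel}.
#' @param minMapq minimum mapping quality (default 20).
#' @return A \linkS4class{DepthProfile} with \code{stage = "raw"}.
#' @export
countProbeDepths <- function(bam, panel, minMapq = 20L) {
    stopifnot(minMapq >= 0)
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    chroms <- unique(as.character(GenomicRanges::seqnames(probeRanges(panel))))
    missing <- setdiff(chroms, names(hdr))
    if (length(missing))
        stop("contigs in panel absent from alignment header: ",
             paste(missing, collapse = ", "), call. = FALSE)
    gr <- probeRanges(panel)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    sbp <- Rsamtools::ScanBamParam(which = gr, flag = flag)
    pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                                 min_mapq = as.integer(minMapq),
                                 min_base_quality = 0L,
                                 min_nucleotide_depth = 0L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = FALSE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    res <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
    cov <- numeric(nProbes(panel))
    if (nrow(res)) {
        idx <- as.integer(res$which_label)  # factor levels follow 'which'
        sums <- rowsum(as.numeric(res$count), idx)
        cov[as.integer(rownames(sums))] <- sums[, 1L]
    }
    DepthProfile(.bamSampleId(bam), cov / GenomicRanges::width(gr), panel,
                 stage = "raw")
}

.bamSampleId <- function(bam) sub("\\.bam$", "", basename(bam))

#' Read a per-probe depth table
#'
#' Two tab-separated columns \code{probe_id} and \code{depth} (with header;
#' '#' comment lines allowed). The table must cover exactly the probes of
#' \code{panel}; rows may be in any order.
#'
#' @param path path to the depth table.
#' @param panel a \linkS4class{ProbePanel}.
#' @param sampleId sample identifier (defaults to the file base name).
#' @param stage normalization stage of the stored depths (default "raw").
#' @return A \linkS4class{DepthProfile} in panel order.
#' @export
readDepthTable <- function(path, panel, sampleId = NULL, stage = "raw") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("probe_id", "depth") %in% colnames(df)))
        stop("depth table needs columns probe_id and depth: ", path,
             call. = FALSE)
    ids <- probeIds(panel)
    miss <- setdiff(ids, df$probe_id)
    extra <- setdiff(df$probe_id, ids)
    if (length(miss) || length(extra))
        stop("depth table does not match panel.",
             if (length(miss)) paste0(" Missing: ",
                                      paste(miss, collapse = ", "), "."),
             if (length(extra)) paste0(" Extra: ",
                                       paste(extra, collapse = ", "), "."),
             call. = FALSE)
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe_id in depth table: ", path, call. = FALSE)
    if (is.null(sampleId))
        sampleId <- sub("\\.(tsv|txt)$", "", basename(path))
    DepthProfile(sampleId, df$depth[match(ids, df$probe_id)], panel,
                 stage = stage)
}

#' Write a per-probe depth table
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param panel the matching \linkS4class{ProbePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDepthTable <- function(profile, panel, path) {
    .checkSamePanel(panelChecksum(panel), panelChecksum(profile),
                    "depth profile")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(c(
        sprintf("# sample=%s stage=%s", sampleId(profile),
                depthStage(profile)),
        sprintf("# panel_checksum=%s", panelChecksum(panel)))), con)
    utils::write.table(
        data.frame(probe_id = probeIds(panel), depth = depths(profile)),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Extract the cfDNA fragment-length histogram from paired-end alignments
#'
#' Template lengths are taken as |TLEN| of properly paired, primary,
#' non-duplicate first-in-pair reads, so every template is counted once.
#'
#' @param bam path to a BAM file of paired-end alignments.
#' @param maxSize largest template length retained (default 1000 bp).
#' @param sampleId sample identifier (defaults to the file base name).
#' @return A \linkS4class{FragmentSizeDistribution}.
#' @export
extractFragmentSizes <- function(bam, maxSize = 1000L, sampleId = NULL) {
    stopifnot(maxSize > 0)
    flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                   isFirstMateRead = TRUE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    sbp <- Rsamtools::ScanBamParam(flag = flag, what = "isize")
    isize <- abs(Rsamtools::scanBam(bam, param = sbp)[[1L]]$isize)
    isize <- isize[!is.na(isize) & isize >= 1L & isize <= maxSize]
    if (!length(isize))
        stop("no qualifying read pairs in ", bam,
             " (need properly paired primary non-duplicate reads with ",
             "1 <= |TLEN| <= ", maxSize, ")", call. = FALSE)
    if (is.null(sampleId)) sampleId <- .bamSampleId(bam)
    tab <- table(isize)
    FragmentSizeDistribution(sampleId,
                             lengths = as.integer(names(tab)),
                             counts = as.integer(tab))
}

#' Write a fragment-length histogram
#'
#' @param dist a \linkS4class{FragmentSizeDistribution}.
#' @param path output path for the 2-column (length, count) TSV.
#' @return \code{path}, invisibly.
#' @export
writeFragmentHistogram <- function(dist, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.toolHeader(sprintf("# sample=%s total=%d", sampleId(dist),
                                   totalFragments(dist))), con)
    utils::write.table(data.frame(length = dist@lengths, count = dist@counts),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a fragment-length histogram
#'
#' @param path path to a 2-column (length, count) TSV with header.
#' @param sampleId sample identifier (defaults to the file base name).
#' @return A \linkS4class{FragmentSizeDistribution}.
#' @export
readFragmentHistogram <- function(path, sampleId = NULL) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("length", "count") %in% colnames(df)))
        stop("fragment histogram needs columns length and count: ", path,
             call. = FALSE)
    if (is.null(sampleId))
        sampleId <- sub("\\.(tsv|txt)$", "", basename(path))
    FragmentSizeDistribution(sampleId, df$length, df$count)
}
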