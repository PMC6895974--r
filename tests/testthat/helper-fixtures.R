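# shared in-code fixtures: tiny panels, profiles, SAM/BAM builders

# a minimal panel: `genes` gives probes per gene; probes 100 bp, step 200,
# one chromosome per gene unless chroms supplied
tinyPanel <- function(genes = c(EGFR = 3), chroms = NULL,
                      gc = 0.5, ov = 0, mp = 1) {
    geneNames <- rep(names(genes), genes)
    if (is.null(chroms))
        chroms <- rep(sprintf("chr%02d", seq_along(genes)), genes)
    within <- unlist(lapply(genes, seq_len)) - 1L
    start <- 1000 + within * 200
    n <- length(geneNames)
    ProbePanel(chrom = chroms, start = start, end = start + 100,
               probe_id = sprintf("%s_%02d", geneNames, within + 1L),
               gene = geneNames,
               gc_fraction = rep_len(gc, n),
               overlap_score = rep_len(ov, n),
               mappability = rep_len(mp, n))
}

rawProfile <- function(panel, depths, id = "s1")
    DepthProfile(id, depths, panel, stage = "raw")

correctedProfile <- function(panel, depths, id = "s1")
    new("DepthProfile", sampleId = id, depths = as.numeric(depths),
        stage = "bias_corrected", panelChecksum = panelChecksum(panel))

# SegmentSet straight from segment means, for calling-layer tests
segsFromMeans <- function(panel, means, bounds, id = "s1") {
    tab <- panelTable(panel)
    segs <- do.call(rbind, lapply(seq_along(means), function(k) {
        idx <- (bounds[k] + 1L):bounds[k + 1L]
        data.frame(chrom = tab$chrom[idx[1L]],
                   probe_start = idx[1L] - 1L, probe_end = idx[length(idx)],
                   start = tab$start[idx[1L]], end = tab$end[idx[length(idx)]],
                   n_probes = length(idx), mean_log2 = means[k],
                   stringsAsFactors = FALSE)
    }))
    m <- segs$mean_log2
    new("SegmentSet", sampleId = id, segments = segs,
        sdSegments = sqrt(mean((m - mean(m))^2)),
        params = list(alpha = 0.01, nPermutations = 1000L, seed = 1L))
}

# ---- SAM/BAM fixtures (text SAM converted at test time) ----

# reads: data.frame(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
# tlen, len); len gives the read length for a dummy sequence
writeFixtureBam <- function(reads, seqlens, dir = withr::local_tempdir()) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sam <- file.path(dir, "fixture.sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
    body <- character(0)
    if (nrow(reads))
        body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                        reads$qname, reads$flag, reads$rname, reads$pos,
                        reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                        reads$tlen,
                        vapply(reads$len, function(l)
                            paste(rep("A", l), collapse = ""), ""))
    writeLines(c(hdr, body), sam)
    Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                     indexDestination = TRUE)
}

# brute-force per-base pileup oracle over simple <n>M cigars
oracleProbeDepths <- function(reads, panel, minMapq = 20) {
    tab <- panelTable(panel)
    vapply(seq_len(nrow(tab)), function(i) {
        lo <- tab$start[i] + 1L; hi <- tab$end[i]   # 1-based closed
        cov <- 0
        for (r in seq_len(nrow(reads))) {
            if (reads$mapq[r] < minMapq) next
            if (bitwAnd(reads$flag[r], 0x400) != 0) next  # duplicate
            if (bitwAnd(reads$flag[r], 0x100) != 0) next  # secondary
            if (bitwAnd(reads$flag[r], 0x800) != 0) next  # supplementary
            if (reads$rname[r] != tab$chrom[i]) next
            stopifnot(grepl("^[0-9]+M$", reads$cigar[r]))
            w <- as.integer(sub("M$", "", reads$cigar[r]))
            rlo <- reads$pos[r]; rhi <- reads$pos[r] + w - 1L
            cov <- cov + max(0L, min(hi, rhi) - max(lo, rlo) + 1L)
        }
        cov / (hi - lo + 1L)
    }, numeric(1))
}

# a simple paired-end read pair with the given TLEN
pairedReads <- function(tlens, rname = "chr1", pos0 = 2000) {
    n <- length(tlens)
    do.call(rbind, lapply(seq_len(n), function(i) {
        p1 <- pos0 + (i - 1L) * 1000L
        p2 <- p1 + tlens[i] - 50L
        data.frame(qname = sprintf("pair%d", i),
                   flag = c(99L, 147L), rname = rname,
                   pos = c(p1, p2), mapq = 60L, cigar = "50M",
                   rnext = "=", pnext = c(p2, p1),
                   tlen = c(tlens[i], -tlens[i]), len = 50L,
                   stringsAsFactors = FALSE)
    }))
}
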