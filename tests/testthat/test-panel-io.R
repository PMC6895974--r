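# Panel / depth-table parsing, BAM depth extraction, fragment sizes.

panelText <- function(rows) {
    c("# chrom\tstart\tend\tprobe_id\tgene\tgc\tov\tmap", rows)
}

test_that("panel files parse, validate and sort independent of row order", {
    dir <- withr::local_tempdir()
    rows <- c("chr7\t1000\t1100\te1\tEGFR\t0.45\t0.1\t0.98",
              "chr7\t1200\t1300\te2\tEGFR\t0.52\t0.0\t1.0",
              "chr7\t1400\t1500\te3\tEGFR\t0.40\t0.2\t0.92")
    sorted <- file.path(dir, "sorted.tsv")
    writeLines(panelText(rows), sorted)
    p1 <- readProbePanel(sorted)
    expect_equal(nProbes(p1), 3L)
    expect_equal(probeIds(p1), c("e1", "e2", "e3"))
    expect_equal(geneProbeIndex(p1, "EGFR"), 1:3)

    shuffled <- file.path(dir, "shuffled.tsv")
    writeLines(panelText(rows[c(3, 1, 2)]), shuffled)
    p2 <- readProbePanel(shuffled)
    expect_identical(panelTable(p2), panelTable(p1))
    expect_identical(panelChecksum(p2), panelChecksum(p1))

    # degenerate interval is reported with its line number
    bad <- file.path(dir, "bad.tsv")
    writeLines(panelText(c(rows[1], "chr7\t1200\t1200\te2\tEGFR\t0.5\t0\t1")),
               bad)
    expect_error(readProbePanel(bad), "line 3")
    dup <- file.path(dir, "dup.tsv")
    writeLines(panelText(c(rows[1], sub("e2", "e1", rows[2]))), dup)
    expect_error(readProbePanel(dup), "duplicate probe_id.*e1")
    expect_error(readProbePanel(file.path(dir, "nope.tsv")), "not found")

    # write -> read round trip preserves everything
    out <- file.path(dir, "roundtrip.tsv")
    writeProbePanel(p1, out)
    expect_identical(panelChecksum(readProbePanel(out)), panelChecksum(p1))
})

test_that("probe panel invariants are enforced at construction", {
    expect_error(ProbePanel("chr1", 10, 5, "p1", "G", 0.5, 0, 1),
                 "start < end")
    expect_error(ProbePanel("chr1", c(0, 10), c(5, 20), c("p", "p"),
                            "G", 0.5, 0, 1),
                 "duplicate")
    expect_error(ProbePanel("chr1", 0, 5, "p1", "G", 1.5, 0, 1),
                 "gc_fraction")
    expect_error(ProbePanel("chr1", 0, 5, "p1", "G", 0.5, -1, 1),
                 "overlap_score")
})

test_that("depth tables round-trip and reject probe mismatches", {
    panel <- tinyPanel(c(EGFR = 2, MET = 2))
    dir <- withr::local_tempdir()
    prof <- rawProfile(panel, c(10.5, 20, 0, 7.25), "t1")
    path <- file.path(dir, "t1.tsv")
    writeDepthTable(prof, panel, path)
    back <- readDepthTable(path, panel)
    expect_equal(depths(back), depths(prof))
    expect_equal(sampleId(back), "t1")

    # row order does not matter
    df <- read.table(path, header = TRUE, comment.char = "#")
    rev <- file.path(dir, "rev.tsv")
    write.table(df[nrow(df):1, ], rev, sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_equal(depths(readDepthTable(rev, panel)), depths(prof))

    # missing and extra probes are both named
    miss <- file.path(dir, "miss.tsv")
    write.table(df[-2, ], miss, sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readDepthTable(miss, panel), "Missing: EGFR_02")
    extra <- file.path(dir, "extra.tsv")
    write.table(rbind(df, data.frame(probe_id = "XX_01", depth = 1)),
                extra, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDepthTable(extra, panel), "Extra: XX_01")
})

test_that("probe depths equal mean per-base coverage from alignments", {
    panel <- tinyPanel(c(EGFR = 3))   # chr01:1000-1100,1200-1300,1400-1500
    dir <- withr::local_tempdir()

    # no reads at all -> all-zero profile
    bamEmpty <- writeFixtureBam(
        data.frame(qname = character(), flag = integer(),
                   rname = character(), pos = integer(), mapq = integer(),
                   cigar = character(), rnext = character(),
                   pnext = integer(), tlen = integer(), len = integer()),
        c(chr01 = 10000), dir)
    expect_equal(depths(countProbeDepths(bamEmpty, panel)), c(0, 0, 0))

    # one 100-bp read exactly covering the first probe -> depth 1 there
    one <- data.frame(qname = "r1", flag = 0L, rname = "chr01",
                      pos = 1001L, mapq = 60L, cigar = "100M",
                      rnext = "*", pnext = 0L, tlen = 0L, len = 100L)
    bamOne <- writeFixtureBam(one, c(chr01 = 10000),
                              file.path(dir, "one"))
    expect_equal(depths(countProbeDepths(bamOne, panel)), c(1, 0, 0))

    # a mixed 10-read fixture agrees with the brute-force pileup oracle:
    # partial overlaps, low MAPQ, duplicate and secondary reads
    set.seed(2024)
    reads <- data.frame(
        qname = sprintf("r%02d", 1:10), flag = 0L, rname = "chr01",
        pos = c(951L, 1001L, 1050L, 1080L, 1190L, 1201L, 1250L, 1280L,
                1460L, 1490L),
        mapq = c(60L, 60L, 10L, 60L, 60L, 60L, 60L, 60L, 60L, 60L),
        cigar = "80M", rnext = "*", pnext = 0L, tlen = 0L, len = 80L)
    reads$flag[7] <- 1024L   # duplicate
    reads$flag[8] <- 256L    # secondary
    bam10 <- writeFixtureBam(reads, c(chr01 = 10000),
                             file.path(dir, "ten"))
    expect_equal(depths(countProbeDepths(bam10, panel, minMapq = 20)),
                 oracleProbeDepths(reads, panel, minMapq = 20))

    # contigs missing from the header are reported
    panel2 <- tinyPanel(c(EGFR = 1, MET = 1),
                        chroms = c("chr01", "chrMissing"))
    expect_error(countProbeDepths(bam10, panel2), "chrMissing")
})

test_that("fragment sizes come from qualifying first-in-pair reads only", {
    dir <- withr::local_tempdir()
    bam <- writeFixtureBam(pairedReads(c(120L, 160L, 170L)),
                           c(chr1 = 100000), dir)
    d <- extractFragmentSizes(bam)
    expect_equal(fragmentCounts(d), c("120" = 1L, "160" = 1L, "170" = 1L))
    expect_equal(totalFragments(d), 3L)

    # unpaired reads only -> empty-distribution error
    solo <- data.frame(qname = "r1", flag = 0L, rname = "chr1",
                       pos = 100L, mapq = 60L, cigar = "50M",
                       rnext = "*", pnext = 0L, tlen = 0L, len = 50L)
    bamSolo <- writeFixtureBam(solo, c(chr1 = 100000),
                               file.path(dir, "solo"))
    expect_error(extractFragmentSizes(bamSolo), "no qualifying")

    # 200 pairs with known lengths: histogram equals the generating counts
    set.seed(31)
    tlens <- sample(c(110L, 140L, 155L, 180L, 240L), 200, replace = TRUE,
                    prob = c(0.15, 0.2, 0.3, 0.25, 0.1))
    bam200 <- writeFixtureBam(pairedReads(tlens), c(chr1 = 100000000),
                              file.path(dir, "many"))
    d200 <- extractFragmentSizes(bam200)
    expect_equal(fragmentCounts(d200),
                 vapply(split(tlens, tlens), length, integer(1)))
    expect_equal(totalFragments(d200), 200L)

    # maxSize filters long templates
    expect_equal(totalFragments(extractFragmentSizes(bam200,
                                                     maxSize = 150L)),
                 sum(tlens <= 150L))
})

test_that("fragment histograms round-trip through their TSV form", {
    d <- FragmentSizeDistribution("s9", c(120, 160, 160, 170),
                                  c(5, 2, 3, 1))
    expect_equal(fragmentCounts(d), c("120" = 5L, "160" = 5L, "170" = 1L))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeFragmentHistogram(d, path)
    back <- readFragmentHistogram(path, sampleId = "s9")
    expect_equal(fragmentCounts(back), fragmentCounts(d))
    expect_equal(sampleId(back), "s9")
})
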