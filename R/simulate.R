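#' @include methods.R
NULL

.subSeed <- function(seed, i) {
    as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 69621) %%
               2147483647)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators: panel geometry,
#' sequencing depth, multiplicative sample noise, the injected GC /
#' mappability / overlap bias, and the bimodal cfDNA fragment-length model
#' (a short tumor mode and a longer normal mode).
#'
#' @param seed master RNG seed; every generator derives its own sub-seed
#'   from it.
#' @param nNormals healthy-donor samples for the panel of normals
#'   (default 10).
#' @param nGenes,probesPerGene,genesPerChrom panel geometry (default 150
#'   genes x 10 probes, 7 genes per chromosome, i.e. a 1500-probe panel
#'   spread over 22 chromosomes).
#' @param targetDepth mean raw sequencing depth per probe (default 1000).
#' @param noiseSigma lognormal (natural-log scale) multiplicative
#'   sample noise per probe (default 0.05).
#' @param gcBiasAmplitude,gcBiasCenter the injected GC bias is
#'   \code{exp(-amplitude * (gc - center)^2)} (defaults 6 and 0.35): a
#'   unimodal capture-efficiency curve peaking below the panel's typical GC,
#'   hence monotone decreasing -- and clearly visible as a depth-GC
#'   correlation -- over most probes.
#' @param mapBiasSlope slope of the injected mappability bias
#'   \code{1 + s * (map - 1)} (default 0.6).
#' @param overlapBiasSlope slope of the injected overlap-score bias
#'   (default 0).
#' @param poissonResample whether spike-in mixtures are Poisson-resampled
#'   at the target depth (default TRUE).
#' @param fragmentShortMean,fragmentLongMean,fragmentSd means (bp) of the
#'   tumor and normal fragment-length modes and their common SD (defaults
#'   145, 167, 10).
#' @param fragmentRange admissible fragment lengths (default c(50, 400)).
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simConfig <- function(seed = 1L, nNormals = 10L, nGenes = 150L,
                      probesPerGene = 10L, genesPerChrom = 7L,
                      targetDepth = 1000, noiseSigma = 0.05,
                      gcBiasAmplitude = 6, gcBiasCenter = 0.35,
                      mapBiasSlope = 0.6,
                      overlapBiasSlope = 0, poissonResample = TRUE,
                      fragmentShortMean = 145, fragmentLongMean = 167,
                      fragmentSd = 10, fragmentRange = c(50, 400)) {
    cfg <- list(seed = as.integer(seed), nNormals = as.integer(nNormals),
                nGenes = as.integer(nGenes),
                probesPerGene = as.integer(probesPerGene),
                genesPerChrom = as.integer(genesPerChrom),
                targetDepth = targetDepth, noiseSigma = noiseSigma,
                gcBiasAmplitude = gcBiasAmplitude,
                gcBiasCenter = gcBiasCenter,
                mapBiasSlope = mapBiasSlope,
                overlapBiasSlope = overlapBiasSlope,
                poissonResample = isTRUE(poissonResample),
                fragmentShortMean = fragmentShortMean,
                fragmentLongMean = fragmentLongMean,
                fragmentSd = fragmentSd, fragmentRange = fragmentRange)
    if (cfg$nNormals < 2L) stop("nNormals must be >= 2", call. = FALSE)
    if (cfg$noiseSigma < 0) stop("noiseSigma must be >= 0", call. = FALSE)
    if (cfg$probesPerGene < 1L)
        stop("panel must have at least one probe per gene", call. = FALSE)
    if (cfg$targetDepth <= 0) stop("targetDepth must be > 0", call. = FALSE)
    if (cfg$fragmentSd <= 0) stop("fragmentSd must be > 0", call. = FALSE)
    class(cfg) <- "SimulationConfig"
    cfg
}

# injected relative bias per probe (median-normalized to 1)
.biasVector <- function(config, panel) {
    tab <- panelTable(panel)
    b <- exp(-config$gcBiasAmplitude *
                 (tab$gc_fraction - config$gcBiasCenter)^2) *
        (1 + config$mapBiasSlope * (tab$mappability - 1)) *
        (1 + config$overlapBiasSlope * tab$overlap_score)
    if (any(b <= 0)) stop("injected bias must be positive", call. = FALSE)
    b / stats::median(b)
}

#' Generate a synthetic probe panel
#'
#' Gene blocks are contiguous (\code{probesPerGene} probes of 120 bp, step
#' 200 bp), \code{genesPerChrom} genes per chromosome, 1 Mb apart. GC
#' fraction is Beta(20, 24) (mean ~0.45), mappability Beta(9, 1) and
#' overlap score Gamma(2, scale 0.25). Three landmark genes -- ERBB2, EGFR
#' and MET, the default spike-in targets -- are placed on three different
#' chromosomes (as in the human genome ERBB2 sits apart from EGFR/MET, and
#' separating them keeps one gene's amplification from bleeding into
#' another's segment); deterministic given the config seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @param geneNames optional character vector of gene names (recycled names
#'   GENE004... fill the remainder by default).
#' @return A \linkS4class{ProbePanel}.
#' @export
generatePanel <- function(config, geneNames = NULL) {
    nGenes <- config$nGenes
    if (is.null(geneNames)) {
        geneNames <- sprintf("GENE%03d", seq_len(nGenes))
        landmark <- c("ERBB2", "EGFR", "MET")
        pos <- 1L + (seq_along(landmark) - 1L) * config$genesPerChrom
        pos <- pos[pos <= nGenes]
        geneNames[pos] <- landmark[seq_along(pos)]
    }
    stopifnot(length(geneNames) == nGenes)
    ppg <- config$probesPerGene
    n <- nGenes * ppg
    .withSeed(.subSeed(config$seed, 1L), function() {
        geneIdx <- rep(seq_len(nGenes), each = ppg)
        chrom <- sprintf("chr%d",
                         ceiling(geneIdx / config$genesPerChrom))
        posInChrom <- (geneIdx - 1L) %% config$genesPerChrom
        probeInGene <- rep(seq_len(ppg) - 1L, nGenes)
        start <- 1e5 + posInChrom * 1e6 + probeInGene * 200L
        ProbePanel(chrom = chrom, start = start, end = start + 120L,
                   probe_id = sprintf("%s_p%02d", geneNames[geneIdx],
                                      probeInGene + 1L),
                   gene = geneNames[geneIdx],
                   gc_fraction = stats::rbeta(n, 20, 24),
                   overlap_score = stats::rgamma(n, shape = 2,
                                                 scale = 0.25),
                   mappability = stats::rbeta(n, 9, 1))
    })
}

#' Generate healthy-donor depth profiles
#'
#' Per sample, \code{depth = targetDepth * bias(covariates) *
#' lognormal(0, noiseSigma)}. The injected bias vector (the generator's
#' ground truth, used by parameter-recovery tests) is attached to the
#' returned list as attribute \code{"bias"}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param panel the \linkS4class{ProbePanel} to simulate on.
#' @param n number of samples (default \code{config$nNormals}).
#' @param seed RNG seed (default derived from the config seed).
#' @return list of raw \linkS4class{DepthProfile}s with attribute
#'   \code{"bias"}.
#' @export
generateNormals <- function(config, panel, n = config$nNormals,
                            seed = .subSeed(config$seed, 2L)) {
    bias <- .biasVector(config, panel)
    np <- nProbes(panel)
    out <- lapply(seq_len(n), function(i)
        .withSeed(.subSeed(seed, i), function()
            DepthProfile(sprintf("normal%02d", i),
                         config$targetDepth * bias *
                             stats::rlnorm(np, 0, config$noiseSigma),
                         panel, stage = "raw")))
    attr(out, "bias") <- bias
    out
}

#' Generate a high-copy "cell line" depth profile
#'
#' Emulates deeply sequenced cell-line cfDNA on the same platform: the
#' probe depths carry the same injected bias as the normals times the
#' per-gene copy-number ratio \code{abcn / 2}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param panel the \linkS4class{ProbePanel}.
#' @param abcnByGene named numeric vector of true absolute copy numbers;
#'   genes not named are diploid. Default: the CCLE copy numbers of the two
#'   validation cell lines (ERBB2 = 60, EGFR = 20, MET = 13).
#' @param sampleId sample identifier.
#' @param seed RNG seed.
#' @return A raw \linkS4class{DepthProfile} with attribute \code{"abcn"}
#'   (the per-probe true copy number).
#' @export
generateTumorProfile <- function(config, panel,
                                 abcnByGene = c(ERBB2 = 60, EGFR = 20,
                                                MET = 13),
                                 sampleId = "cellline",
                                 seed = .subSeed(config$seed, 3L)) {
    bias <- .biasVector(config, panel)
    cn <- rep(2, nProbes(panel))
    for (g in names(abcnByGene))
        cn[geneProbeIndex(panel, g)] <- abcnByGene[[g]]
    prof <- .withSeed(seed, function()
        DepthProfile(sampleId,
                     config$targetDepth * bias * (cn / 2) *
                         stats::rlnorm(nProbes(panel), 0,
                                       config$noiseSigma),
                     panel, stage = "raw"))
    attr(prof, "abcn") <- cn
    prof
}

#' Mix a tumor profile into a normal background at a given fraction
#'
#' Depth-space spike-in: the median-relative depths of tumor and background
#' are mixed as \code{fraction * tumor + (1 - fraction) * background} and
#' rescaled to \code{targetDepth}, with optional Poisson resampling of each
#' probe's depth (the depth-space analogue of down-sampling and re-mixing
#' reads). \code{fraction = 0} reproduces the background's distribution.
#'
#' @param tumor,background raw \linkS4class{DepthProfile}s on the same
#'   panel.
#' @param fraction tumor fraction in [0, 1].
#' @param seed RNG seed for the resampling.
#' @param targetDepth output mean depth (default: the background median).
#' @param resample Poisson-resample the mixed depths (default TRUE).
#' @return A raw \linkS4class{DepthProfile}.
#' @export
spikeIn <- function(tumor, background, fraction, seed = 1L,
                    targetDepth = NULL, resample = TRUE) {
    .checkSamePanel(panelChecksum(background), panelChecksum(tumor),
                    "tumor profile")
    stopifnot(fraction >= 0, fraction <= 1)
    dT <- depths(tumor) / stats::median(depths(tumor))
    dB <- depths(background) / stats::median(depths(background))
    if (is.null(targetDepth)) targetDepth <- stats::median(depths(background))
    mix <- targetDepth * (fraction * dT + (1 - fraction) * dB)
    if (resample)
        mix <- .withSeed(seed, function()
            stats::rpois(length(mix), mix))
    new("DepthProfile",
        sampleId = sprintf("%s_in_%s_f%g", sampleId(tumor),
                           sampleId(background), fraction),
        depths = as.numeric(mix), stage = "raw",
        panelChecksum = panelChecksum(background))
}

#' Run the normalization / segmentation / calling pipeline on one sample
#'
#' Convenience wrapper chaining \code{\link{medianNormalize}},
#' \code{\link{applyBiasModel}}, \code{\link{ponLogRatio}},
#' \code{\link{cbsSegment}} and \code{\link{callAmplifications}}.
#'
#' @param raw a raw \linkS4class{DepthProfile}.
#' @param model a \linkS4class{BiasModel}.
#' @param pon a \linkS4class{PanelOfNormals}.
#' @param panel the \linkS4class{ProbePanel}.
#' @param tf tumor fraction (estimate, bare numeric, or NULL).
#' @param alpha,nPermutations,seed segmentation parameters.
#' @param thresholdFloor minimum amplification threshold.
#' @return list with elements \code{logratio}, \code{segments},
#'   \code{calls}.
#' @export
runCnvPipeline <- function(raw, model, pon, panel, tf = NULL, alpha = 0.01,
                           nPermutations = 1000L, seed = 1L,
                           thresholdFloor = 0.1) {
    lrp <- ponLogRatio(applyBiasModel(medianNormalize(raw), model, panel),
                       pon)
    segs <- cbsSegment(lrp, panel, alpha = alpha,
                       nPermutations = nPermutations, seed = seed)
    calls <- callAmplifications(segs, panel, lrp, tf = tf,
                                thresholdFloor = thresholdFloor)
    list(logratio = lrp, segments = segs, calls = calls)
}

#' In-silico spike-in limit-of-detection experiment
#'
#' Emulates the dilution-ladder validation: for each replicate set, a panel
#' of normals is built from freshly simulated healthy donors, a cell-line
#' profile is mixed into a held-out donor at each ladder fraction, and the
#' full pipeline is run. A gene's LOD is the smallest fraction at which it
#' is called amplified in every replicate set; the effective copy number at
#' the LOD (\code{abcn * f + 2 * (1 - f)}) is reported alongside.
#'
#' @param config a \code{\link{simConfig}}.
#' @param cellLines named list of cell-line profiles, each a named numeric
#'   vector of true gene copy numbers. Default: the two validation lines
#'   (HCC1954: ERBB2 = 60; NCI-H1573: EGFR = 20, MET = 13), each spiked
#'   separately.
#' @param fractions descending dilution ladder (default 5\%...0.3\%).
#' @param nPonSets replicate panel-of-normals sets (default 3).
#' @param normalsPerSet healthy donors per replicate set (default 4).
#' @param alpha,nPermutations segmentation parameters.
#' @param thresholdFloor minimum amplification threshold.
#' @return list with elements \code{genes} (per-gene list: gene, abcn,
#'   detection fraction-by-set matrix, the realized fraction-by-set
#'   amplification thresholds of the gene's cell-line runs, lodFraction,
#'   lodEffectiveCopies), \code{thresholds} (per cell line), 
#'   \code{fractions} and \code{panel}.
#' @export
runLodExperiment <- function(config,
                             cellLines = list(
                                 HCC1954 = c(ERBB2 = 60),
                                 `NCI-H1573` = c(EGFR = 20, MET = 13)),
                             fractions = c(0.05, 0.04, 0.03, 0.02, 0.01,
                                           0.006, 0.003),
                             nPonSets = 3L, normalsPerSet = 4L,
                             alpha = 0.01, nPermutations = 1000L,
                             thresholdFloor = 0.1) {
    stopifnot(all(fractions > 0), all(fractions < 1),
              !is.unsorted(rev(fractions), strictly = TRUE))
    panel <- generatePanel(config)
    genes <- unlist(lapply(cellLines, names), use.names = FALSE)
    abcn <- unlist(cellLines, use.names = FALSE)
    names(abcn) <- genes
    detect <- array(FALSE,
                    dim = c(length(fractions), nPonSets, length(genes)),
                    dimnames = list(fraction = fractions,
                                    set = seq_len(nPonSets), gene = genes))
    thr <- array(NA_real_,
                 dim = c(length(fractions), nPonSets, length(cellLines)),
                 dimnames = list(fraction = fractions,
                                 set = seq_len(nPonSets),
                                 cellLine = names(cellLines)))
    for (s in seq_len(nPonSets)) {
        setSeed <- .subSeed(config$seed, 100L + s)
        normals <- generateNormals(config, panel, n = normalsPerSet + 1L,
                                   seed = setSeed)
        ponNormals <- normals[seq_len(normalsPerSet)]
        background <- normals[[normalsPerSet + 1L]]
        mn <- lapply(ponNormals, medianNormalize)
        model <- fitBiasModel(mn, panel)
        pon <- buildPon(lapply(mn, applyBiasModel, model = model,
                               panel = panel))
        for (cl in seq_along(cellLines)) {
            tumor <- generateTumorProfile(
                config, panel, abcnByGene = cellLines[[cl]],
                sampleId = names(cellLines)[cl],
                seed = .subSeed(setSeed, 500L + cl))
            for (fi in seq_along(fractions)) {
                f <- fractions[fi]
                mixed <- spikeIn(tumor, background, f,
                                 seed = .subSeed(setSeed, 1000L * cl + fi),
                                 targetDepth = config$targetDepth,
                                 resample = config$poissonResample)
                res <- runCnvPipeline(mixed, model, pon, panel, tf = f,
                                      alpha = alpha,
                                      nPermutations = nPermutations,
                                      seed = .subSeed(setSeed,
                                                      2000L * cl + fi),
                                      thresholdFloor = thresholdFloor)
                thr[fi, s, cl] <- res$calls$threshold[1L]
                for (g in names(cellLines[[cl]])) {
                    row <- res$calls[res$calls$gene == g, ]
                    detect[fi, s, g] <- row$status == "amplified"
                }
            }
        }
    }
    lineOf <- rep(names(cellLines), lengths(cellLines))
    names(lineOf) <- genes
    perGene <- lapply(genes, function(g) {
        det <- detect[, , g, drop = TRUE]
        det <- matrix(det, nrow = length(fractions))
        allSets <- apply(det, 1L, all)
        lod <- if (any(allSets)) min(fractions[allSets]) else NA_real_
        list(gene = g, abcn = abcn[[g]], detection = det,
             thresholds = thr[, , lineOf[[g]], drop = TRUE],
             lodFraction = lod,
             lodEffectiveCopies = if (is.na(lod)) NA_real_ else
                 effectiveCopyNumber(abcn[[g]], lod))
    })
    names(perGene) <- genes
    list(genes = perGene,
         thresholds = lapply(stats::setNames(names(cellLines),
                                             names(cellLines)),
                             function(cl) thr[, , cl, drop = TRUE]),
         fractions = fractions, panel = panel)
}

#' Analytic detection-limit fraction under the 3-SD rule
#'
#' Given the true copy number and the realized amplification threshold at
#' each ladder fraction, the predicted LOD is the smallest fraction whose
#' expected log2 ratio (\code{\link{log2RatioFromAbcn}}) exceeds the
#' threshold.
#'
#' @param abcn true absolute copy number of the gene.
#' @param fractions the dilution ladder.
#' @param thresholds amplification threshold per fraction (scalar or vector
#'   parallel to \code{fractions}).
#' @return The predicted LOD fraction, or \code{NA} if no ladder fraction
#'   crosses.
#' @export
analyticLodFraction <- function(abcn, fractions, thresholds) {
    thresholds <- rep_len(thresholds, length(fractions))
    crosses <- log2RatioFromAbcn(abcn, fractions) > thresholds
    if (any(crosses)) min(fractions[crosses]) else NA_real_
}

#' Generate a synthetic cfDNA fragment-size distribution
#'
#' Mixture of a short (tumor) and a long (normal) mode, each a rounded
#' normal truncated to \code{config$fragmentRange}. The generating ground
#' truth -- mixture weight, per-mode analytic mass below 150 bp and the
#' implied expected short-fragment proportion -- is attached as attribute
#' \code{"ledger"}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param tumorFraction mixture weight of the short mode, in [0, 1].
#' @param n number of fragments (> 0).
#' @param seed RNG seed.
#' @param thresholdBp cutoff used for the ledger's expected proportion
#'   (default 150).
#' @return A \linkS4class{FragmentSizeDistribution} with attribute
#'   \code{"ledger"}.
#' @export
generateFragments <- function(config, tumorFraction, n,
                              seed = .subSeed(config$seed, 4L),
                              thresholdBp = 150L) {
    stopifnot(tumorFraction >= 0, tumorFraction <= 1)
    if (n <= 0) stop("n must be > 0", call. = FALSE)
    lo <- config$fragmentRange[1L] - 0.5
    hi <- config$fragmentRange[2L] + 0.5
    rtrunc <- function(m, mu) {
        out <- numeric(0)
        while (length(out) < m) {
            x <- stats::rnorm(m - length(out), mu, config$fragmentSd)
            out <- c(out, x[x >= lo & x < hi])
        }
        out
    }
    lens <- .withSeed(seed, function() {
        nTumor <- stats::rbinom(1L, n, tumorFraction)
        round(c(rtrunc(nTumor, config$fragmentShortMean),
                rtrunc(n - nTumor, config$fragmentLongMean)))
    })
    dist <- FragmentSizeDistribution(
        sprintf("sim_f%g", tumorFraction),
        lengths = as.integer(names(table(lens))),
        counts = as.integer(table(lens)))
    massBelow <- function(mu) {
        cut <- thresholdBp - 0.5   # round(X) < threshold  <=>  X < cut
        (stats::pnorm(cut, mu, config$fragmentSd) -
         stats::pnorm(lo, mu, config$fragmentSd)) /
        (stats::pnorm(hi, mu, config$fragmentSd) -
         stats::pnorm(lo, mu, config$fragmentSd))
    }
    mS <- massBelow(config$fragmentShortMean)
    mL <- massBelow(config$fragmentLongMean)
    attr(dist, "ledger") <- list(
        tumorFraction = tumorFraction, n = n,
        shortMassBelow = mS, longMassBelow = mL,
        expectedP = tumorFraction * mS + (1 - tumorFraction) * mL)
    dist
}
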