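Package: plasmaCNV
Title: Tumor-Only Copy Number Amplification Calling for ctDNA Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects gene amplifications from circulating tumor DNA (ctDNA)
    sequenced with hybrid-capture gene panels, without a matched normal
    sample. Per-probe read depths are median-normalized, corrected for GC
    content, probe overlap and mappability bias, and converted to log2
    ratios against a panel of normals built from healthy-donor cfDNA.
    Log ratios are segmented by circular binary segmentation and segments
    above three standard deviations of the segment-level log ratios are
    called amplified. Tumor fraction is estimated from the proportion of
    cfDNA fragments shorter than 150 bp and converted, together with the
    gene log2 ratio, into an absolute copy number. A simulation module
    generates synthetic panels, healthy-donor depth profiles, cell-line
    spike-in dilution ladders and fragment-size distributions, and runs an
    in-silico limit-of-detection experiment over replicate panels of
    normals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'call.R'
    'normalize.R'
    'panel-io.R'
    'plasmaCNV-package.R'
    'segment.R'
    'simulate.R'
    'utils.R'
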