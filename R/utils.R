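# internal helpers: checksums, RNG scoping, file headers

# polynomial rolling hash (mod 2^31-1) over a canonical string; cheap,
# stable across platforms, only used to detect accidental panel/PoN mispairing
.hashString <- function(s) {
    codes <- utf8ToInt(s)
    h <- 0
    m <- 2147483647
    for (chunk in split(codes, ceiling(seq_along(codes) / 4096L))) {
        for (c in chunk) h <- (h * 31 + c) %% m
    }
    sprintf("%08x", h)
}

.panelChecksumFrom <- function(chrom, start, end, probe_id, gene, gc, ov, mp) {
    s <- paste(paste(chrom, start, end, probe_id, gene,
                     sprintf("%.6f", gc), sprintf("%.6f", ov),
                     sprintf("%.6f", mp), sep = ":"),
               collapse = ";")
    paste0("pp", length(probe_id), "-", .hashString(s))
}

.checkSamePanel <- function(a, b, what = "object") {
    if (!identical(a, b))
        stop(what, " was built for a different panel (checksum ", b,
             " != ", a, ")", call. = FALSE)
    invisible(TRUE)
}

# evaluate fn() with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, fn) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    fn()
}

.toolHeader <- function(extra = character()) {
    ver <- as.character(utils::packageVersion("plasmaCNV"))
    c(sprintf("# plasmaCNV v%s", ver), extra)
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))
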