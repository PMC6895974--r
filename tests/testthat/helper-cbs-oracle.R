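# Independent brute-force CBS oracle: same statistic and permutation
# contract as the package (so seeded runs are comparable), but computed
# with naive loops over every arc instead of the package's vectorized
# cumulative sums, and recursion written from scratch.

oracleMaxArc <- function(x) {
    n <- length(x)
    if (n < 4L) return(NULL)
    best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
    for (i in 0:(n - 1L)) {
        for (j in (i + 1L):n) {
            k <- j - i
            if (k >= n) next
            xin <- x[(i + 1L):j]
            xout <- x[-((i + 1L):j)]
            v <- (sum((xin - mean(xin))^2) +
                  sum((xout - mean(xout))^2)) / (n - 2L)
            v <- max(v, 1e-24)
            st <- abs(mean(xin) - mean(xout)) /
                sqrt(v * (1 / k + 1 / (n - k)))
            if (st > best$stat) best <- list(stat = st, i = i, j = j)
        }
    }
    best
}

oraclePermPval <- function(x, obsStat, alpha, nPerm) {
    cap <- ceiling(alpha * (nPerm + 1))
    tol <- 1e-9 * max(1, obsStat)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        xs <- x[sample.int(length(x))]
        if (oracleMaxArc(xs)$stat >= obsStat - tol) exceed <- exceed + 1L
        if (exceed >= cap) return(1)
    }
    (1 + exceed) / (1 + nPerm)
}

# returns a list of c(lo, hi) index pairs, left to right
oracleSegment <- function(x, alpha, nPerm) {
    n <- length(x)
    if (n < 4L) return(list(c(1L, n)))
    m <- oracleMaxArc(x)
    p <- oraclePermPval(x, m$stat, alpha, nPerm)
    if (p >= alpha) return(list(c(1L, n)))
    pieces <- list()
    if (m$i > 0L) pieces <- c(pieces, list(c(1L, m$i)))
    pieces <- c(pieces, list(c(m$i + 1L, m$j)))
    if (m$j < n) pieces <- c(pieces, list(c(m$j + 1L, n)))
    out <- list()
    for (pc in pieces) {
        sub <- oracleSegment(x[pc[1L]:pc[2L]], alpha, nPerm)
        out <- c(out, lapply(sub, function(s) s + pc[1L] - 1L))
    }
    out
}

# package segmentation of a single-chromosome vector, via the public API
cbsOnVector <- function(x, alpha = 0.01, nPerm = 200L, seed = 1L) {
    genes <- c(G1 = length(x))
    panel <- tinyPanel(genes)
    lrp <- LogRatioProfile("v", x, panel)
    st <- segTable(cbsSegment(lrp, panel, alpha = alpha,
                              nPermutations = nPerm, seed = seed))
    cbind(st$probe_start + 1L, st$probe_end)
}
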