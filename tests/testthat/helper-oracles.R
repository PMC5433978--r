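# Independent oracles used to cross-check the implementation. These are
# deliberately written via different routes than the package code: the FST
# oracle runs a nested ANOVA on individual allele indicators (raw sums of
# squares, no frequency algebra), pi is enumerated over allele pairs, window
# statistics are recomputed by direct looping, and the spanning-tree oracle
# comes from igraph.

# Weir-Cockerham via allele-level nested ANOVA (populations / individuals /
# alleles). g1, g2: dosage vectors without NA.
oracleWcFst <- function(g1, g2) {
    alleles <- function(g) t(vapply(as.integer(g), function(x)
        switch(x + 1L, c(0, 0), c(0, 1), c(1, 1)), numeric(2)))
    a1 <- alleles(g1); a2 <- alleles(g2)
    n1 <- length(g1); n2 <- length(g2); r <- 2
    yb1 <- mean(a1); yb2 <- mean(a2); yb <- mean(c(a1, a2))
    i1 <- rowMeans(a1); i2 <- rowMeans(a2)
    SSG <- sum((a1 - i1)^2) + sum((a2 - i2)^2)
    SSI <- 2 * sum((i1 - yb1)^2) + 2 * sum((i2 - yb2)^2)
    SSP <- 2 * n1 * (yb1 - yb)^2 + 2 * n2 * (yb2 - yb)^2
    MSP <- SSP / (r - 1)
    MSI <- SSI / (n1 + n2 - r)
    MSG <- SSG / (n1 + n2)
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    a <- (MSP - MSI) / (2 * nc)
    b <- (MSI - MSG) / 2
    cc <- MSG
    den <- a + b + cc
    list(a = a, b = b, c = cc,
         fst = if (den == 0) NA_real_ else a / den)
}

# pi by explicit enumeration of allele pairs at one site.
oraclePi <- function(g) {
    g <- as.integer(g[!is.na(g)])
    al <- unlist(lapply(g, function(x)
        switch(x + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))))
    n <- length(al)
    if (n < 2) return(NA_real_)
    diffs <- 0L; pairs <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        pairs <- pairs + 1L
        diffs <- diffs + (al[i] != al[j])
    }
    diffs / pairs
}

# brute-force window means over a per-site stats table for one scaffold set
oracleWindows <- function(stats, scaffoldLengths, window, step, minSnps) {
    rows <- list()
    for (sc in sort(unique(stats$scaffold))) {
        s <- stats[stats$scaffold == sc, ]
        len <- scaffoldLengths[[sc]]
        start <- 1
        while (start <= len) {
            end <- min(start + window - 1, len)
            inw <- s$position >= start & s$position <= end
            if (sum(inw) >= minSnps) {
                fst <- s$fst[inw]; fst <- fst[!is.na(fst)]
                rows[[length(rows) + 1]] <- data.frame(
                    CHROM = sc, BIN_START = start, BIN_END = end,
                    N_VARIANTS = sum(inw),
                    MEAN_FST = if (length(fst)) mean(fst) else NA_real_)
            }
            start <- start + step
        }
    }
    do.call(rbind, rows)
}

# Tajima's D from a raw dosage matrix for one window, constants recomputed
# from the published formulas.
oracleTajimaD <- function(d) {
    called <- apply(d, 1, function(g) sum(!is.na(g)))
    alt <- apply(d, 1, function(g) sum(g, na.rm = TRUE))
    seg <- alt > 0 & alt < 2 * called
    S <- sum(seg)
    n <- 2 * min(called)
    if (S == 0 || n < 4) return(NA_real_)
    piSum <- sum(vapply(which(seg), function(i) oraclePi(d[i, ]), 0))
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# double-ranking oracle for comparable-scaffold selection
oracleComparable <- function(info, target, lengthBand, densityBand) {
    o <- info[order(-info$length, info$scaffold), ]
    t1 <- which(o$scaffold == target)
    o <- o[max(1, t1 - lengthBand):min(nrow(o), t1 + lengthBand), ]
    o <- o[order(-o$density, o$scaffold), ]
    t2 <- which(o$scaffold == target)
    o[max(1, t2 - densityBand):min(nrow(o), t2 + densityBand), "scaffold"]
}

# build a small SnpExperiment directly from a dosage matrix
makeSnp <- function(d, pops, scaffold = NULL, position = NULL) {
    n <- nrow(d)
    if (is.null(scaffold)) scaffold <- rep("sc1", n)
    if (is.null(position)) position <- seq_len(n) * 10L
    colnames(d) <- paste0("s", seq_len(ncol(d)))
    SnpExperiment(d, scaffold = scaffold, position = position,
                  ref = rep("A", n), alt = rep("G", n),
                  population = stats::setNames(pops, colnames(d)))
}
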