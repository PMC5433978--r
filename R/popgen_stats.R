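#' Weir-Cockerham variance components at one site
#'
#' Two-population (r = 2) moment estimator of the fixation index. With
#' per-population diploid counts n_i, alt frequencies p_i and observed
#' heterozygote proportions h_i:
#' \deqn{\bar n = \sum n_i / r,\quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1),\quad
#'       \bar p = \sum n_i p_i/(r\bar n)}
#' \deqn{s^2 = \sum n_i (p_i-\bar p)^2/((r-1)\bar n),\quad
#'       \bar h = \sum n_i h_i/(r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],\quad
#'       c = \bar h/2}
#' and FST = a/(a+b+c), undefined (NA) when a+b+c = 0, which happens exactly
#' when both populations are monomorphic for the same allele. The estimator
#' can be negative; negative values are retained.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, NA = missing) for the diploids
#'   of populations 1 and 2 at one site.
#' @return named list with \code{n1, n2, p1, p2, h1, h2, nbar, nc, pbar, s2,
#'   hbar, a, b, c, fst}.
#' @examples
#' # fixed difference: FST = 1
#' wcFstSite(rep(0L, 7), rep(2L, 8))$fst
#' @export
wcFstSite <- function(g1, g2) {
    st <- .wcComponents(matrix(as.integer(g1), nrow = 1),
                        matrix(as.integer(g2), nrow = 1))
    lapply(as.list(st[1, ]), unname)
}

# Vectorised core over sites (rows). d1, d2: dosage matrices per population.
.wcComponents <- function(d1, d2) {
    r <- 2
    n1 <- rowSums(!is.na(d1))
    n2 <- rowSums(!is.na(d2))
    p1 <- rowSums(d1, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(d2, na.rm = TRUE) / (2 * n2)
    h1 <- rowSums(d1 == 1L, na.rm = TRUE) / n1
    h2 <- rowSums(d2 == 1L, na.rm = TRUE) / n2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    den <- a + b + cc
    fst <- ifelse(den == 0, NA_real_, a / den)
    data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, h1 = h1, h2 = h2,
               nbar = nbar, nc = nc, pbar = pbar, s2 = s2, hbar = hbar,
               a = a, b = b, c = cc, fst = fst)
}

#' Per-site nucleotide diversity
#'
#' Average number of pairwise allele differences among the called haplotypes
#' at one site: with n called haplotypes of which x carry the alt allele,
#' \eqn{\pi = x(n-x)/\binom{n}{2}}. Undefined (NA) for n < 2.
#'
#' @param g integer dosage vector (0/1/2, NA = missing) over diploid samples.
#' @return numeric pi value.
#' @examples
#' sitePi(c(1L, 1L))        # x = 2 of n = 4 haplotypes: 4/6
#' sitePi(c(0L, 0L, 0L))    # monomorphic: 0
#' @export
sitePi <- function(g) {
    g <- as.integer(g)
    n <- 2L * sum(!is.na(g))
    if (n < 2L) return(NA_real_)
    x <- sum(g, na.rm = TRUE)
    x * (n - x) / choose(n, 2)
}

.sitePiVec <- function(d) {
    n <- 2L * rowSums(!is.na(d))
    x <- rowSums(d, na.rm = TRUE)
    ifelse(n < 2L, NA_real_, x * (n - x) / (n * (n - 1) / 2))
}

#' Per-site statistics table
#'
#' Computes, for every site of a two-population experiment, the
#' Weir-Cockerham variance components and FST (see [wcFstSite()]),
#' per-population and pooled nucleotide diversity, and the pooled minor
#' allele frequency. Sites where a population has no called diploids get NA
#' components and a \code{skip_reason}.
#'
#' @param x a [SnpExperiment-class] with exactly two population labels.
#' @return data.frame with one row per site: \code{scaffold}, \code{position},
#'   \code{gene_id}, \code{effect}, the component columns of [wcFstSite()],
#'   \code{fst}, \code{pi_pop1}, \code{pi_pop2}, \code{pi_pooled},
#'   \code{maf}, \code{skip_reason}. The two population labels, in sorted
#'   order, are recorded in \code{attr(, "populations")}.
#' @export
siteStats <- function(x) {
    pops <- populations(x)
    labs <- sort(unique(pops))
    if (length(labs) != 2L)
        stop("siteStats requires exactly two populations, got ",
             length(labs))
    d <- dosage(x)
    d1 <- d[, pops == labs[1], drop = FALSE]
    d2 <- d[, pops == labs[2], drop = FALSE]
    st <- .wcComponents(d1, d2)
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    skip <- ifelse(st$n1 == 0L, "no_calls_pop1",
                   ifelse(st$n2 == 0L, "no_calls_pop2", NA_character_))
    bad <- !is.na(skip)
    if (any(bad))
        st[bad, setdiff(colnames(st), c("n1", "n2"))] <- NA_real_
    out <- data.frame(
        scaffold = as.character(GenomicRanges::seqnames(rr)),
        position = GenomicRanges::start(rr),
        gene_id = mc$gene_id, effect = mc$effect,
        st,
        pi_pop1 = .sitePiVec(d1), pi_pop2 = .sitePiVec(d2),
        pi_pooled = .sitePiVec(d),
        maf = pooledMaf(x),
        skip_reason = skip,
        stringsAsFactors = FALSE)
    attr(out, "populations") <- labs
    out
}

#' Sliding-window FST and diversity
#'
#' Slides windows of \code{window} bp in steps of \code{step} bp along each
#' scaffold, starting at position 1 (candidate starts 1, 1+step, 1+2 step,
#' ... while start <= scaffold length; the last window is truncated at the
#' scaffold end). A window is emitted iff it contains at least
#' \code{minSnps} SNPs. Two window FST summaries are reported: the
#' arithmetic mean of defined per-site FST values (\code{MEAN_FST}, the
#' statistic consumed by the bootstrap null) and the variance-component
#' ratio \eqn{\sum a / \sum (a+b+c)} over the same sites (\code{WEIGHTED_FST},
#' the vcftools "weighted" dialect). Sites with undefined FST are excluded
#' from both.
#'
#' @param stats per-site table from [siteStats()].
#' @param scaffoldLengths named numeric vector of scaffold lengths (bp);
#'   must cover every scaffold in \code{stats}.
#' @param window window size in bp (default 10000).
#' @param step increment in bp (default 5000); must satisfy
#'   \code{0 < step <= window}.
#' @param minSnps minimum SNP count for a window to be emitted (default 1).
#' @return data.frame with columns \code{CHROM}, \code{BIN_START},
#'   \code{BIN_END}, \code{N_VARIANTS}, \code{WEIGHTED_FST}, \code{MEAN_FST},
#'   \code{MEAN_PI} (mean pooled per-site pi).
#' @export
slidingWindowStats <- function(stats, scaffoldLengths, window = 10000L,
                               step = 5000L, minSnps = 1L) {
    stopifnot(window > 0, step > 0, step <= window)
    miss <- setdiff(unique(stats$scaffold), names(scaffoldLengths))
    if (length(miss))
        stop("scaffold(s) missing from length table: ",
             paste(head(miss, 5), collapse = ", "))
    res <- lapply(split(stats, stats$scaffold), function(sc) {
        len <- scaffoldLengths[[sc$scaffold[1]]]
        starts <- seq.int(1L, len, by = step)
        ends <- pmin(starts + window - 1L, len)
        # assign each SNP to the windows covering it
        out <- lapply(seq_along(starts), function(i) {
            inw <- sc$position >= starts[i] & sc$position <= ends[i]
            k <- sum(inw)
            if (k < minSnps) return(NULL)
            fst <- sc$fst[inw]
            def <- !is.na(fst)
            den <- sc$a[inw][def] + sc$b[inw][def] + sc$c[inw][def]
            data.frame(CHROM = sc$scaffold[1],
                       BIN_START = starts[i], BIN_END = ends[i],
                       N_VARIANTS = k,
                       WEIGHTED_FST = if (any(def))
                           sum(sc$a[inw][def]) / sum(den) else NA_real_,
                       MEAN_FST = if (any(def)) mean(fst[def]) else NA_real_,
                       MEAN_PI = mean(sc$pi_pooled[inw], na.rm = TRUE),
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Tajima's D normalising constants
#'
#' For a sample of \code{n} haplotypes: \eqn{a_1 = \sum_{i=1}^{n-1} 1/i},
#' \eqn{a_2 = \sum 1/i^2}, \eqn{b_1 = (n+1)/(3(n-1))},
#' \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))}, \eqn{c_1 = b_1 - 1/a_1},
#' \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2}, \eqn{e_1 = c_1/a_1},
#' \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param n number of haplotypes (>= 2).
#' @return named list \code{a1, a2, b1, b2, c1, c2, e1, e2}.
#' @export
tajimaConstants <- function(n) {
    stopifnot(n >= 2)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i)
    a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajimaD <- function(S, n, piSum) {
    if (S == 0L || n < 4L) return(NA_real_)
    k <- tajimaConstants(n)
    thetaW <- S / k$a1
    denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    (piSum - thetaW) / denom
}

#' Tajima's D in nonoverlapping windows
#'
#' Computes Tajima's D over the pooled sample (default) or one population, in
#' nonoverlapping windows of \code{window} bp starting at 1, 10001, ...
#' Within a window, S is the number of segregating sites in the chosen
#' sample, the pairwise-diversity term is the sum of per-site pi values
#' (each using that site's called haplotypes), and the haplotype count n is
#' taken as twice the minimum number of called diploids across the window's
#' sites - a conservative convention under missing data. Windows with
#' S < \code{minSnps} are suppressed; windows with n < 4 get NA.
#'
#' @param x a [SnpExperiment-class].
#' @param window window size in bp (default 10000).
#' @param minSnps minimum segregating sites per window (default 10).
#' @param population optional population label to restrict the sample to;
#'   default NULL pools all samples.
#' @return data.frame with columns \code{CHROM}, \code{BIN_START},
#'   \code{BIN_END}, \code{N_SNPS}, \code{N_HAPLOTYPES}, \code{TajimaD}.
#' @seealso [tajimaDScaffolds()] for whole-scaffold values.
#' @export
tajimaDWindows <- function(x, window = 10000L, minSnps = 10L,
                           population = NULL) {
    d <- .tajimaSubset(x, population)
    rr <- SummarizedExperiment::rowRanges(x)
    sc <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    bin <- (pos - 1L) %/% window
    out <- lapply(split(seq_along(pos), paste(sc, bin)), function(idx) {
        row <- .tajimaOnSites(d[idx, , drop = FALSE])
        if (row$S < minSnps) return(NULL)
        data.frame(CHROM = sc[idx[1]],
                   BIN_START = bin[idx[1]] * window + 1L,
                   BIN_END = (bin[idx[1]] + 1L) * window,
                   N_SNPS = row$S, N_HAPLOTYPES = row$n,
                   TajimaD = row$D, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(data.frame(CHROM = character(), BIN_START = integer(),
                          BIN_END = integer(), N_SNPS = integer(),
                          N_HAPLOTYPES = integer(), TajimaD = numeric()))
    out <- out[order(out$CHROM, out$BIN_START), ]
    rownames(out) <- NULL
    out
}

#' Tajima's D per scaffold
#'
#' Same statistic as [tajimaDWindows()] but computed once per scaffold using
#' all of the scaffold's SNPs (no minimum-S suppression; S = 0 gives NA).
#'
#' @inheritParams tajimaDWindows
#' @return data.frame with columns \code{CHROM}, \code{N_SNPS},
#'   \code{N_HAPLOTYPES}, \code{TajimaD}.
#' @export
tajimaDScaffolds <- function(x, population = NULL) {
    d <- .tajimaSubset(x, population)
    sc <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(x)))
    out <- lapply(split(seq_along(sc), sc), function(idx) {
        row <- .tajimaOnSites(d[idx, , drop = FALSE])
        data.frame(CHROM = sc[idx[1]], N_SNPS = row$S,
                   N_HAPLOTYPES = row$n, TajimaD = row$D,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

.tajimaSubset <- function(x, population) {
    d <- dosage(x)
    if (!is.null(population)) {
        sel <- populations(x) == population
        if (!any(sel)) stop("no samples in population ", population)
        d <- d[, sel, drop = FALSE]
    }
    d
}

.tajimaOnSites <- function(d) {
    called <- rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    seg <- alt > 0L & alt < 2L * called
    S <- sum(seg)
    n <- if (nrow(d)) 2L * min(called) else 0L
    piSum <- if (S) sum(.sitePiVec(d[seg, , drop = FALSE])) else 0
    list(S = S, n = n, D = .tajimaD(S, n, piSum))
}

#' Write per-site and windowed tables in vcftools-style dialects
#'
#' \code{writeFstSiteTable}: CHROM, POS, WEIR_AND_COCKERHAM_FST.
#' \code{writeFstWindowTable}: CHROM, BIN_START, BIN_END, N_VARIANTS,
#' WEIGHTED_FST, MEAN_FST. \code{writeTajimaTable}: CHROM, BIN_START,
#' N_SNPS, TajimaD. All tab-separated with a header.
#'
#' @param stats,windows,tajima tables from [siteStats()],
#'   [slidingWindowStats()], [tajimaDWindows()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @name popgen-writers
NULL

#' @rdname popgen-writers
#' @export
writeFstSiteTable <- function(stats, path) {
    tab <- data.frame(CHROM = stats$scaffold, POS = stats$position,
                      WEIR_AND_COCKERHAM_FST = stats$fst)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname popgen-writers
#' @export
writeFstWindowTable <- function(windows, path) {
    utils::write.table(
        windows[, c("CHROM", "BIN_START", "BIN_END", "N_VARIANTS",
                    "WEIGHTED_FST", "MEAN_FST")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname popgen-writers
#' @export
writeTajimaTable <- function(tajima, path) {
    utils::write.table(
        tajima[, c("CHROM", "BIN_START", "N_SNPS", "TajimaD")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
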