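#' Build the genome-wide FST null pool
#'
#' Collects every defined per-SNP FST value into the resampling pool used by
#' the density-matched bootstrap ([windowBootstrap()]), together with the
#' number of pseudo-replicates B and the RNG seed, so a scan is fully
#' reproducible from its recorded settings.
#'
#' @param stats per-site table from [siteStats()] (or any data.frame with an
#'   \code{fst} column).
#' @param B number of pseudo-replicate data sets (default 500000).
#' @param seed integer RNG seed governing the whole scan.
#' @return an object of class \code{"NullPool"}: list with \code{fst}
#'   (defined values), \code{B}, \code{seed}.
#' @export
buildNullPool <- function(stats, B = 500000L, seed) {
    stopifnot(B >= 1)
    fst <- stats$fst[!is.na(stats$fst)]
    if (!length(fst)) stop("no defined FST values to build a null pool from")
    structure(list(fst = fst, B = as.integer(B), seed = as.integer(seed)),
              class = "NullPool")
}

#' @export
print.NullPool <- function(x, ...) {
    cat(sprintf("NullPool: %d per-SNP FST values, B = %d, seed = %d\n",
                length(x$fst), x$B, x$seed))
    invisible(x)
}

#' Density-matched bootstrap test for window FST
#'
#' For each empirical window with k SNPs, simulates B pseudo-replicate
#' windows by drawing k per-SNP FST values with replacement from the
#' genome-wide pool and averaging, then counts exceedances
#' m = #\{replicate mean >= observed mean\} (one-sided upper tail; ties count
#' as exceedances, which is conservative). The empirical p is m/B and a
#' window is flagged significant iff m = 0, i.e. no simulation produced a
#' value as extreme as observed, so a significant window has p < 1/B. The
#' add-one convention (m+1)/(B+1) is reported alongside as \code{P_UPPER}.
#'
#' By default windows sharing the same SNP count share one simulated null
#' distribution - identical in distribution to per-window simulation and
#' much faster; set \code{sharedNulls = FALSE} for per-window independent
#' streams (each window then gets its own substream derived from the pool
#' seed and the window's rank in (scaffold, start) order, so results do not
#' depend on iteration order).
#'
#' @param windows window table from [slidingWindowStats()] (columns
#'   \code{CHROM}, \code{BIN_START}, \code{BIN_END}, \code{N_VARIANTS},
#'   \code{MEAN_FST}); windows whose \code{MEAN_FST} is NA are dropped.
#' @param pool a \code{NullPool} from [buildNullPool()].
#' @param sharedNulls share one null distribution per distinct SNP count
#'   (default TRUE).
#' @param lowerTail scan for depressed rather than elevated FST
#'   (default FALSE).
#' @return \code{windows} with added columns \code{EXCEEDANCES},
#'   \code{P_EMPIRICAL} (m/B), \code{P_UPPER} ((m+1)/(B+1)) and
#'   \code{SIGNIFICANT} (m = 0).
#' @export
windowBootstrap <- function(windows, pool, sharedNulls = TRUE,
                            lowerTail = FALSE) {
    stopifnot(inherits(pool, "NullPool"))
    windows <- windows[!is.na(windows$MEAN_FST), , drop = FALSE]
    ord <- order(windows$CHROM, windows$BIN_START)
    windows <- windows[ord, , drop = FALSE]
    k <- as.integer(windows$N_VARIANTS)
    stopifnot(all(k >= 1))
    obs <- windows$MEAN_FST
    if (lowerTail) obs <- -obs
    poolVals <- if (lowerTail) -pool$fst else pool$fst
    B <- pool$B
    m <- integer(nrow(windows))
    if (sharedNulls) {
        set.seed(pool$seed)
        for (kk in sort(unique(k))) {
            nulls <- .nullMeans(poolVals, kk, B)
            sel <- which(k == kk)
            m[sel] <- B - findInterval(obs[sel], sort(nulls),
                                       left.open = TRUE)
        }
    } else {
        for (i in seq_len(nrow(windows))) {
            set.seed((pool$seed + i) %% .Machine$integer.max)
            nulls <- .nullMeans(poolVals, k[i], B)
            m[i] <- sum(nulls >= obs[i])
        }
    }
    windows$EXCEEDANCES <- m
    windows$P_EMPIRICAL <- m / B
    windows$P_UPPER <- (m + 1) / (B + 1)
    windows$SIGNIFICANT <- m == 0L
    rownames(windows) <- NULL
    windows
}

# B replicate means of k pool draws, chunked to bound memory.
.nullMeans <- function(pool, k, B) {
    chunk <- max(1L, min(B, as.integer(2e7 %/% k)))
    out <- numeric(B)
    done <- 0L
    while (done < B) {
        nb <- min(chunk, B - done)
        draws <- sample(pool, nb * k, replace = TRUE)
        out[(done + 1L):(done + nb)] <-
            .colMeans(draws, m = k, n = nb)
        done <- done + nb
    }
    out
}

#' Top-percentile SNP ranking
#'
#' Ranks all sites with defined FST in decreasing FST order (ties broken by
#' scaffold then position, ascending - a deterministic stable order) and
#' returns the top \code{ceiling(fraction * N)} sites.
#'
#' @param stats per-site table from [siteStats()].
#' @param fraction top fraction to keep, in (0, 1]; default 0.005 (top 0.5%).
#' @return the selected rows of \code{stats}, ranked, with a \code{rank}
#'   column; the FST range of the selection is in
#'   \code{attr(, "fst_range")}.
#' @export
topFractionSnps <- function(stats, fraction = 0.005) {
    stopifnot(fraction > 0, fraction <= 1)
    def <- stats[!is.na(stats$fst), , drop = FALSE]
    if (!nrow(def)) stop("no defined FST values to rank")
    nTop <- as.integer(ceiling(fraction * nrow(def)))
    ord <- order(-def$fst, def$scaffold, def$position)
    top <- def[ord[seq_len(nTop)], , drop = FALSE]
    top$rank <- seq_len(nTop)
    rownames(top) <- NULL
    attr(top, "fst_range") <- range(top$fst)
    top
}

#' Per-gene counts of top-ranked SNPs
#'
#' Groups a top-SNP selection by gene and splits each gene's count by coding
#' effect class. Unannotated sites are grouped under the reserved label
#' \code{"(unannotated)"}. Rows are sorted by decreasing count, ties by gene
#' id.
#'
#' @param top ranked subset from [topFractionSnps()].
#' @return data.frame with columns \code{gene_id}, \code{count},
#'   \code{synonymous}, \code{nonsynonymous}, \code{other}.
#' @export
perGeneCounts <- function(top) {
    if (!nrow(top))
        return(data.frame(gene_id = character(), count = integer(),
                          synonymous = integer(), nonsynonymous = integer(),
                          other = integer()))
    gene <- ifelse(is.na(top$gene_id), "(unannotated)", top$gene_id)
    eff <- factor(top$effect, levels = c("synonymous", "nonsynonymous",
                                         "other"))
    tab <- table(gene, eff)
    out <- data.frame(gene_id = rownames(tab),
                      count = as.integer(rowSums(tab)),
                      synonymous = as.integer(tab[, "synonymous"]),
                      nonsynonymous = as.integer(tab[, "nonsynonymous"]),
                      other = as.integer(tab[, "other"]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$gene_id), ]
    rownames(out) <- NULL
    out
}

#' Select scaffolds comparable to a target
#'
#' Double ranking used to pick a visually comparable scaffold set: (1) rank
#' all scaffolds by length and keep those within \code{lengthBand} ranks of
#' the target on either side (bands truncate at the list ends); (2) rank
#' that subset by SNP density (count / length) and keep those within
#' \code{densityBand} ranks of the target. With untruncated bands the result
#' has 2 * densityBand + 1 scaffolds including the target.
#'
#' @param info scaffold table from [scaffoldInfo()].
#' @param target scaffold id to centre the bands on.
#' @param lengthBand rank half-width for the length ranking (default 10).
#' @param densityBand rank half-width for the density ranking (default 4).
#' @return rows of \code{info} for the selected scaffolds, ordered by
#'   decreasing density rank proximity (density-rank order).
#' @export
selectComparableScaffolds <- function(info, target, lengthBand = 10L,
                                      densityBand = 4L) {
    if (!target %in% info$scaffold)
        stop("target scaffold not in scaffold table: ", target)
    byLen <- info[order(-info$length, info$scaffold), , drop = FALSE]
    tpos <- which(byLen$scaffold == target)
    sel <- byLen[max(1L, tpos - lengthBand):
                 min(nrow(byLen), tpos + lengthBand), , drop = FALSE]
    byDen <- sel[order(-sel$density, sel$scaffold), , drop = FALSE]
    tpos <- which(byDen$scaffold == target)
    out <- byDen[max(1L, tpos - densityBand):
                 min(nrow(byDen), tpos + densityBand), , drop = FALSE]
    rownames(out) <- NULL
    out
}
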