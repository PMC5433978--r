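#' Scan configuration
#'
#' Bundles every tunable of the end-to-end scan with its default: 10 kb
#' windows advanced in 5 kb steps, at least 10 segregating sites per
#' Tajima window, B = 500000 bootstrap pseudo-replicates, top fraction
#' 0.005, MAF threshold 0.05 (applied only when \code{mafFilter = TRUE};
#' the scan's null pool uses the full SNP set by default), scaffold
#' selection bands of 10 (length) and 4 (density) ranks, and a 0.90
#' parsimony confidence for the network stage.
#'
#' @param vcf,popmap,annotations,scaffoldLengths,haplotypes input paths
#'   (annotations and haplotypes optional).
#' @param window,step,minSnps sliding-window settings (bp, bp, count).
#' @param tajimaMinSnps minimum segregating sites per Tajima window.
#' @param B bootstrap pseudo-replicates.
#' @param seed top-level RNG seed; expanded into per-stage streams.
#' @param fraction top SNP fraction.
#' @param mafFilter apply the MAF filter before the scan (default FALSE).
#' @param mafThreshold pooled MAF cutoff when filtering.
#' @param minCalledPerPop per-population call filter for [readSnpVcf()].
#' @param lengthBand,densityBand scaffold-selection rank bands.
#' @param targetScaffold scaffold to centre scaffold selection on (optional;
#'   default: scaffold holding the top-ranked SNP).
#' @param networkAlpha parsimony confidence for the haplotype network.
#' @return a list of class \code{"ScanConfig"}.
#' @export
scanConfig <- function(vcf = NULL, popmap = NULL, annotations = NULL,
                       scaffoldLengths = NULL, haplotypes = NULL,
                       window = 10000L, step = 5000L, minSnps = 1L,
                       tajimaMinSnps = 10L, B = 500000L, seed = 1L,
                       fraction = 0.005, mafFilter = FALSE,
                       mafThreshold = 0.05, minCalledPerPop = 1L,
                       lengthBand = 10L, densityBand = 4L,
                       targetScaffold = NULL, networkAlpha = 0.90) {
    cfg <- list(vcf = vcf, popmap = popmap, annotations = annotations,
                scaffoldLengths = scaffoldLengths, haplotypes = haplotypes,
                window = as.integer(window), step = as.integer(step),
                minSnps = as.integer(minSnps),
                tajimaMinSnps = as.integer(tajimaMinSnps),
                B = as.integer(B), seed = as.integer(seed),
                fraction = fraction, mafFilter = mafFilter,
                mafThreshold = mafThreshold,
                minCalledPerPop = as.integer(minCalledPerPop),
                lengthBand = as.integer(lengthBand),
                densityBand = as.integer(densityBand),
                targetScaffold = targetScaffold,
                networkAlpha = networkAlpha)
    class(cfg) <- "ScanConfig"
    cfg
}

# Named per-stage RNG streams derived from the top-level seed, so adding a
# stage never perturbs another stage's draws. Kept below 2^31.
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the end-to-end outlier scan
#'
#' Executes the full pipeline: VCF import and filtering, per-site
#' Weir-Cockerham statistics, sliding-window summaries, Tajima's D, the
#' density-matched bootstrap, top-percentile ranking with per-gene counts,
#' comparable-scaffold selection, and (when a haplotype alignment is given)
#' the statistical-parsimony network. All result tables, a run manifest
#' (settings, seed, input checksums) and a plain-text summary are written
#' under \code{outDir}. Reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config a \code{ScanConfig} from [scanConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with every intermediate result
#'   (\code{experiment}, \code{stats}, \code{windows}, \code{tajima},
#'   \code{tajimaScaffolds}, \code{bootstrap}, \code{top},
#'   \code{geneCounts}, \code{scaffolds}, \code{network}, \code{summary}).
#' @export
runScan <- function(config, outDir) {
    stopifnot(inherits(config, "ScanConfig"))
    if (is.null(config$vcf) || is.null(config$popmap) ||
        is.null(config$scaffoldLengths))
        stop("runScan needs vcf, popmap and scaffoldLengths inputs")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(outDir, f)

    popmap <- readPopMap(config$popmap)
    lens <- readScaffoldLengths(config$scaffoldLengths)
    x <- readSnpVcf(config$vcf, popmap, config$minCalledPerPop)
    if (!is.null(config$annotations))
        x <- attachAnnotations(x, readAnnotationTable(config$annotations))
    if (isTRUE(config$mafFilter))
        x <- filterMaf(x, config$mafThreshold)

    stats <- siteStats(x)
    writeFstSiteTable(stats, out("fst_sites.tsv"))
    windows <- slidingWindowStats(stats, lens, config$window, config$step,
                                  config$minSnps)
    writeFstWindowTable(windows, out("fst_windows.tsv"))
    tajima <- tajimaDWindows(x, config$window, config$tajimaMinSnps)
    writeTajimaTable(tajima, out("tajima_windows.tsv"))
    tajimaSc <- tajimaDScaffolds(x)
    utils::write.table(tajimaSc, out("tajima_scaffolds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    pool <- buildNullPool(stats, B = config$B,
                          seed = stageSeed(config$seed, "bootstrap"))
    boot <- windowBootstrap(windows, pool)
    utils::write.table(
        boot[, c("CHROM", "BIN_START", "BIN_END", "N_VARIANTS", "MEAN_FST",
                 "EXCEEDANCES", "P_EMPIRICAL", "SIGNIFICANT")],
        out("window_bootstrap.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)

    top <- topFractionSnps(stats, config$fraction)
    utils::write.table(
        data.frame(rank = top$rank, scaffold = top$scaffold,
                   position = top$position, fst = top$fst,
                   gene_id = ifelse(is.na(top$gene_id), ".", top$gene_id),
                   effect = top$effect),
        out("top_snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    geneCounts <- perGeneCounts(top)
    utils::write.table(geneCounts, out("gene_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    info <- scaffoldInfo(x, lens)
    target <- if (!is.null(config$targetScaffold)) config$targetScaffold
              else top$scaffold[1]
    scafSel <- selectComparableScaffolds(info, target, config$lengthBand,
                                         config$densityBand)
    utils::write.table(scafSel, out("scaffold_selection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    network <- NULL
    if (!is.null(config$haplotypes)) {
        aln <- readHaplotypeAlignment(config$haplotypes, popmap)
        haps <- collapseHaplotypes(aln$sequences, aln$population)
        network <- buildNetwork(haps, alpha = config$networkAlpha)
        writeNetworkTables(network, out("network_nodes.tsv"),
                           out("network_edges.tsv"))
        writeNetworkGraphML(network, out("network.graphml"))
    }

    fstDef <- stats$fst[!is.na(stats$fst)]
    summary <- c(
        sprintf("sites: %d (pool of defined FST values: %d)",
                nrow(stats), length(fstDef)),
        sprintf("mean FST: %.6f  SD: %.6f", mean(fstDef), stats::sd(fstDef)),
        sprintf("top %.3f%% SNPs: %d  FST range: %.4f-%.4f",
                100 * config$fraction, nrow(top),
                attr(top, "fst_range")[1], attr(top, "fst_range")[2]),
        sprintf("significant windows (m = 0 of B = %d): %d", config$B,
                sum(boot$SIGNIFICANT)),
        sprintf("top gene: %s (%d top SNPs: %d synonymous, %d nonsynonymous)",
                geneCounts$gene_id[1], geneCounts$count[1],
                geneCounts$synonymous[1], geneCounts$nonsynonymous[1]),
        sprintf("comparable scaffolds around %s: %d", target,
                nrow(scafSel)),
        if (!is.null(network))
            sprintf("haplotype network: %d haplotypes, %d edges, jMax = %d",
                    nrow(network@nodes), nrow(network@edges), network@jMax))
    writeLines(summary, out("summary.txt"))
    .writeManifest(config, outDir)

    res <- list(experiment = x, stats = stats, windows = windows,
                tajima = tajima, tajimaScaffolds = tajimaSc,
                bootstrap = boot, top = top, geneCounts = geneCounts,
                scaffolds = scafSel, network = network, summary = summary)
    invisible(res)
}

.writeManifest <- function(config, outDir) {
    inputs <- c(vcf = config$vcf, popmap = config$popmap,
                annotations = config$annotations,
                scaffoldLengths = config$scaffoldLengths,
                haplotypes = config$haplotypes)
    sums <- vapply(inputs, function(p)
        unname(tools::md5sum(p)), "")
    lines <- c(
        sprintf("FstScan %s", as.character(utils::packageVersion("FstScan"))),
        sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
        sprintf("window: %d", config$window),
        sprintf("step: %d", config$step),
        sprintf("min_snps: %d", config$minSnps),
        sprintf("tajima_min_snps: %d", config$tajimaMinSnps),
        sprintf("B: %d", config$B),
        sprintf("seed: %d", config$seed),
        sprintf("fraction: %g", config$fraction),
        sprintf("maf_filter: %s", config$mafFilter),
        sprintf("maf_threshold: %g", config$mafThreshold),
        sprintf("min_called_per_pop: %d", config$minCalledPerPop),
        sprintf("length_band: %d", config$lengthBand),
        sprintf("density_band: %d", config$densityBand),
        sprintf("network_alpha: %g", config$networkAlpha),
        sprintf("input %s: %s md5=%s", names(inputs), unname(inputs), sums))
    writeLines(lines, file.path(outDir, "manifest.txt"))
}
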