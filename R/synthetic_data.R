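#' Simulate a two-population exonic SNP dataset
#'
#' Generates a dataset with the statistical structure the scan assumes: two
#' small diploid samples genotyped at biallelic exonic SNPs scattered over
#' many scaffolds, weak genome-wide differentiation, and one gene-sized
#' cluster of strongly differentiated SNPs planted on a single scaffold.
#'
#' Background sites follow a Balding-Nichols construction: an ancestral alt
#' frequency is drawn uniformly on \code{ancestralRange}, each population's
#' frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), and diploid
#' genotypes are binomial(2, p_pop). Cluster sites instead receive divergent
#' frequencies p1 ~ U(\code{clusterFreq1}), p2 ~ U(\code{clusterFreq2}),
#' chosen so realized per-SNP Weir-Cockerham FST at these sample sizes
#' centres near 0.6 inside the 0.38-0.79 band. Genes tile the scaffolds;
#' background SNPs are allocated to genes with gamma-distributed weights so
#' SNP density varies by gene as it does in transcriptome data. Sites that
#' come out monomorphic across all samples are redrawn (the scan's input is
#' by construction a set of variable sites). Missing genotypes are masked at
#' rate \code{missingRate}. Everything is deterministic under \code{seed}.
#'
#' @param n1,n2 diploids in populations 1 and 2 (defaults 7 and 8).
#' @param nSnps total SNP count including the cluster (default 17450).
#' @param nScaffolds number of scaffolds (default 261).
#' @param scaffoldLengthRange scaffold lengths are drawn log-uniformly from
#'   this range in bp (default 50 kb - 2 Mb), exercising window truncation
#'   and scaffold ranking.
#' @param F background differentiation parameter (default 0.008).
#' @param clusterSnps SNPs in the planted outlier cluster (default 13; 0
#'   plants nothing).
#' @param clusterFreq1,clusterFreq2 uniform ranges for the cluster's
#'   population allele frequencies (defaults c(0.08, 0.22) and
#'   c(0.78, 0.92)).
#' @param clusterGeneSpan bp span of the cluster gene (default 17000).
#' @param geneSpan bp span of background genes (default 5000).
#' @param missingRate per-genotype missingness (default 0.02).
#' @param ancestralRange uniform range for ancestral frequencies
#'   (default c(0.05, 0.95)).
#' @param popLabels the two population labels (default c("pop1", "pop2")).
#' @param seed integer seed.
#' @return list with \code{experiment} (a [SnpExperiment-class]),
#'   \code{truth} (data.frame of planted cluster SNPs: scaffold, position,
#'   gene_id, p1, p2), and \code{scaffoldLengths} (named numeric).
#' @export
simulateSnpDataset <- function(n1 = 7L, n2 = 8L, nSnps = 17450L,
                               nScaffolds = 261L,
                               scaffoldLengthRange = c(5e4, 2e6),
                               F = 0.008, clusterSnps = 13L,
                               clusterFreq1 = c(0.08, 0.22),
                               clusterFreq2 = c(0.78, 0.92),
                               clusterGeneSpan = 17000L, geneSpan = 5000L,
                               missingRate = 0.02,
                               ancestralRange = c(0.05, 0.95),
                               popLabels = c("pop1", "pop2"), seed = 1L) {
    stopifnot(n1 >= 1, n2 >= 1, nSnps >= 1, nScaffolds >= 1,
              F >= 0, F < 1, clusterSnps >= 0, clusterSnps <= nSnps,
              missingRate >= 0, missingRate < 1)
    set.seed(seed)
    scafNames <- sprintf("scaffold_%03d", seq_len(nScaffolds))
    lens <- round(exp(stats::runif(nScaffolds, log(scaffoldLengthRange[1]),
                                   log(scaffoldLengthRange[2]))))
    names(lens) <- scafNames

    # gene layout: genes tile scaffolds, one per ~50 kb, >= 1 per scaffold
    nGenes <- pmax(1L, as.integer(round(lens / 5e4)))
    geneScaf <- rep(scafNames, nGenes)
    geneStart <- unlist(lapply(seq_len(nScaffolds), function(i) {
        hi <- max(1L, lens[i] - geneSpan)
        sort(sample.int(hi, nGenes[i], replace = TRUE))
    }))
    geneId <- sprintf("gene_%05d", seq_along(geneScaf))

    # cluster gene sits on the scaffold of median length
    if (clusterSnps > 0L) {
        clusterScaf <- scafNames[order(lens)][ceiling(nScaffolds / 2)]
        hi <- max(1L, lens[[clusterScaf]] - clusterGeneSpan)
        clusterStart <- sample.int(hi, 1L)
        clusterGene <- "gene_cluster"
    }

    # allocate background SNPs to genes with variable per-gene density
    nBg <- nSnps - clusterSnps
    w <- stats::rgamma(length(geneId), shape = 1)
    alloc <- as.integer(stats::rmultinom(1, nBg, prob = w / sum(w)))
    site <- data.frame(
        scaffold = rep(geneScaf, alloc),
        gene_id = rep(geneId, alloc),
        position = unlist(lapply(seq_along(geneId), function(i) {
            if (!alloc[i]) return(integer())
            geneStart[i] + sample.int(geneSpan, alloc[i], replace = TRUE) - 1L
        })),
        cluster = FALSE, stringsAsFactors = FALSE)
    if (clusterSnps > 0L)
        site <- rbind(site, data.frame(
            scaffold = clusterScaf, gene_id = clusterGene,
            position = clusterStart +
                sample.int(clusterGeneSpan, clusterSnps) - 1L,
            cluster = TRUE, stringsAsFactors = FALSE))
    # unique positions within scaffolds
    repeat {
        dup <- duplicated(site[c("scaffold", "position")])
        if (!any(dup)) break
        site$position[dup] <- site$position[dup] + 1L
    }
    site <- site[order(site$scaffold, site$position), ]
    n <- nrow(site)

    # effect classes: cluster mirrors a 7 synonymous / 6 nonsynonymous split
    site$effect <- sample(c("synonymous", "nonsynonymous", "other"),
                          n, replace = TRUE, prob = c(0.55, 0.40, 0.05))
    if (clusterSnps > 0L) {
        ci <- which(site$cluster)
        nSyn <- ceiling(clusterSnps / 2)
        site$effect[ci] <- sample(rep(c("synonymous", "nonsynonymous"),
                                      c(nSyn, clusterSnps - nSyn)))
    }

    freqs <- .drawFrequencies(n, which(site$cluster), F, ancestralRange,
                              clusterFreq1, clusterFreq2)
    geno <- .drawGenotypes(freqs$p1, freqs$p2, n1, n2)
    # redraw sites monomorphic across the pooled sample
    for (iter in seq_len(100L)) {
        tot <- rowSums(geno)
        mono <- tot == 0L | tot == 2L * (n1 + n2)
        if (!any(mono)) break
        idx <- which(mono)
        f2 <- .drawFrequencies(length(idx), which(site$cluster[idx]), F,
                               ancestralRange, clusterFreq1, clusterFreq2)
        freqs$p1[idx] <- f2$p1; freqs$p2[idx] <- f2$p2
        geno[idx, ] <- .drawGenotypes(f2$p1, f2$p2, n1, n2)
    }
    if (missingRate > 0) {
        mask <- matrix(stats::runif(length(geno)) < missingRate,
                       nrow = n)
        # keep at least one call per population per site
        mask[, 1] <- mask[, 1] & rowSums(!mask[, 1:n1, drop = FALSE]) > 1L
        mask[, n1 + 1] <- mask[, n1 + 1] &
            rowSums(!mask[, n1 + seq_len(n2), drop = FALSE]) > 1L
        geno[mask] <- NA_integer_
    }

    alleles <- .drawAlleles(n)
    samples <- c(sprintf("%s_%02d", popLabels[1], seq_len(n1)),
                 sprintf("%s_%02d", popLabels[2], seq_len(n2)))
    colnames(geno) <- samples
    pops <- stats::setNames(rep(popLabels, c(n1, n2)), samples)
    se <- SnpExperiment(geno, scaffold = site$scaffold,
                        position = site$position,
                        ref = alleles$ref, alt = alleles$alt,
                        population = pops, geneId = site$gene_id,
                        effect = site$effect)
    truth <- if (clusterSnps > 0L) {
        ci <- which(site$cluster)
        data.frame(scaffold = site$scaffold[ci],
                   position = site$position[ci],
                   gene_id = site$gene_id[ci],
                   p1 = freqs$p1[ci], p2 = freqs$p2[ci],
                   stringsAsFactors = FALSE)
    } else data.frame(scaffold = character(), position = integer(),
                      gene_id = character(), p1 = numeric(),
                      p2 = numeric())
    truth <- truth[order(truth$scaffold, truth$position), ]
    rownames(truth) <- NULL
    list(experiment = se, truth = truth, scaffoldLengths = lens)
}

.drawFrequencies <- function(n, clusterIdx, F, ancestralRange, cf1, cf2) {
    panc <- stats::runif(n, ancestralRange[1], ancestralRange[2])
    if (F > 0) {
        shape <- (1 - F) / F
        p1 <- stats::rbeta(n, panc * shape, (1 - panc) * shape)
        p2 <- stats::rbeta(n, panc * shape, (1 - panc) * shape)
    } else {
        p1 <- p2 <- panc
    }
    if (length(clusterIdx)) {
        p1[clusterIdx] <- stats::runif(length(clusterIdx), cf1[1], cf1[2])
        p2[clusterIdx] <- stats::runif(length(clusterIdx), cf2[1], cf2[2])
    }
    list(p1 = p1, p2 = p2)
}

.drawGenotypes <- function(p1, p2, n1, n2) {
    n <- length(p1)
    cbind(matrix(stats::rbinom(n * n1, 2L, rep(p1, n1)), nrow = n),
          matrix(stats::rbinom(n * n2, 2L, rep(p2, n2)), nrow = n))
}

.drawAlleles <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(ref = ref, alt = unname(alt))
}

#' Write a simulated dataset to disk
#'
#' Emits the simulated data in the pipeline's input formats: a plain-text
#' VCF, population map TSV, annotation TSV, .fai-style scaffold length
#' table, and the planted-outlier truth TSV.
#'
#' @param sim result of [simulateSnpDataset()].
#' @param prefix output path prefix; files are written as
#'   \code{<prefix>.vcf}, \code{<prefix>.popmap.tsv},
#'   \code{<prefix>.annotations.tsv}, \code{<prefix>.fai},
#'   \code{<prefix>.truth.tsv}.
#' @return named character vector of the written paths, invisibly.
#' @export
writeDataset <- function(sim, prefix) {
    x <- sim$experiment
    paths <- c(vcf = paste0(prefix, ".vcf"),
               popmap = paste0(prefix, ".popmap.tsv"),
               annotations = paste0(prefix, ".annotations.tsv"),
               fai = paste0(prefix, ".fai"),
               truth = paste0(prefix, ".truth.tsv"))
    writeSnpVcf(x, paths[["vcf"]])
    pops <- populations(x)
    utils::write.table(data.frame(sample = names(pops),
                                  population = unname(pops)),
                       paths[["popmap"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    rr <- SummarizedExperiment::rowRanges(x)
    ann <- data.frame(scaffold = as.character(GenomicRanges::seqnames(rr)),
                      position = GenomicRanges::start(rr),
                      gene_id = geneIds(x), effect = effectClasses(x))
    utils::write.table(ann[!is.na(ann$gene_id), ], paths[["annotations"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(name = names(sim$scaffoldLengths),
                                  length = unname(sim$scaffoldLengths)),
                       paths[["fai"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Simulate a two-haplogroup haplotype alignment
#'
#' Builds a fixture for network construction: two divergent haplogroups
#' separated by \code{groupSeparation} mutational steps, each sequence
#' carrying up to \code{withinSteps} private mutations at sites unused by
#' any other sequence (so pairwise distances are additive:
#' within-group <= 2 * withinSteps, between-group >= groupSeparation).
#' Deterministic under \code{seed}.
#'
#' @param nSeqs number of sequences (default 20; split evenly between the
#'   groups, first half group A).
#' @param L alignment length in bp (default 4049).
#' @param groupSeparation steps between the two group cores (default 10).
#' @param withinSteps maximum private mutations per sequence (default 1;
#'   each sequence draws 0..withinSteps of them uniformly).
#' @param popLabels labels for the two groups (default c("grpA", "grpB")).
#' @param seed integer seed.
#' @return list with \code{sequences} (\link[Biostrings]{DNAStringSet}),
#'   \code{population} (character vector) and \code{L}.
#' @export
simulateHaplotypes <- function(nSeqs = 20L, L = 4049L, groupSeparation = 10L,
                               withinSteps = 1L,
                               popLabels = c("grpA", "grpB"), seed = 1L) {
    stopifnot(L >= 1, nSeqs >= 1,
              groupSeparation + nSeqs * withinSteps < L)
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    mutate <- function(seq, sites) {
        for (s in sites) seq[s] <- sample(setdiff(bases, seq[s]), 1L)
        seq
    }
    freeSites <- sample.int(L)   # disjoint site budget, additive distances
    take <- function(k) {
        s <- freeSites[seq_len(k)]
        freeSites <<- freeSites[-seq_len(k)]
        s
    }
    coreB <- mutate(anc, take(groupSeparation))
    nA <- ceiling(nSeqs / 2)
    out <- vector("list", nSeqs)
    pop <- character(nSeqs)
    for (i in seq_len(nSeqs)) {
        inA <- i <= nA
        core <- if (inA) anc else coreB
        # each group's first sequence is its unmutated core, so the planted
        # between-group separation is observed exactly once
        k <- if (i %in% c(1L, nA + 1L) || withinSteps == 0L) 0L
             else sample.int(withinSteps + 1L, 1L) - 1L
        out[[i]] <- paste(mutate(core, if (k) take(k) else integer()),
                          collapse = "")
        pop[i] <- if (inA) popLabels[1] else popLabels[2]
    }
    seqs <- Biostrings::DNAStringSet(unlist(out))
    names(seqs) <- sprintf("%s_%02d", pop, unlist(lapply(
        split(seq_len(nSeqs), pop)[unique(pop)], seq_along)))
    list(sequences = seqs, population = pop, L = L)
}
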