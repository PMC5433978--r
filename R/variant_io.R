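#' Read a sample-to-population map
#'
#' Two-column TSV (\code{sample_id <TAB> population}, no header) mapping each
#' sample to its population label.
#'
#' @param path path to the TSV.
#' @return named character vector: population label per sample id.
#' @export
readPopMap <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("sample", "population"))
    if (anyDuplicated(tab$sample))
        stop("duplicate sample ids in population map: ", path)
    stats::setNames(tab$population, tab$sample)
}

#' Read scaffold lengths (FASTA .fai style)
#'
#' Reads a tab-separated table whose first two columns are scaffold name and
#' length in bp (the layout of a \code{samtools faidx} .fai file; extra
#' columns are ignored).
#'
#' @param path path to the TSV/.fai file.
#' @return named numeric vector of lengths.
#' @export
readScaffoldLengths <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    len <- as.numeric(tab[[2]])
    if (any(len <= 0)) stop("scaffold lengths must be positive: ", path)
    stats::setNames(len, as.character(tab[[1]]))
}

#' Read a SNP annotation table
#'
#' Sidecar TSV with header \code{scaffold, position, gene_id, effect} giving,
#' per annotated site, the gene it falls in and its coding effect class
#' (\code{synonymous}, \code{nonsynonymous}, or \code{other}). This sidecar
#' is the canonical annotation input; [parseSnpEffAnn()] is a convenience for
#' deriving one from annotator ANN strings.
#'
#' @param path path to the TSV.
#' @return data.frame with the four columns above.
#' @export
readAnnotationTable <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("scaffold", "position", "gene_id", "effect")
    if (!all(need %in% colnames(tab)))
        stop("annotation table must have columns: ",
             paste(need, collapse = ", "))
    tab$position <- as.integer(tab$position)
    key <- paste(tab$scaffold, tab$position)
    if (anyDuplicated(key))
        stop("duplicate (scaffold, position) keys in annotation table")
    tab
}

#' Minimal parser for snpEff-style ANN strings
#'
#' Extracts the first annotation's effect term and gene id from a
#' pipe-delimited ANN field (\code{allele|effect|impact|gene|...}) and maps
#' the effect term onto the three-way class used throughout the package.
#' Annotator dialects vary; the sidecar TSV read by [readAnnotationTable()]
#' is the canonical input.
#'
#' @param ann character vector of ANN field values (NA allowed).
#' @return data.frame with columns \code{gene_id} and \code{effect}.
#' @export
parseSnpEffAnn <- function(ann) {
    gene <- rep(NA_character_, length(ann))
    eff <- rep("other", length(ann))
    ok <- !is.na(ann) & nzchar(ann)
    if (any(ok)) {
        first <- vapply(strsplit(ann[ok], ",", fixed = TRUE), `[`, "", 1L)
        parts <- strsplit(first, "|", fixed = TRUE)
        term <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
        gene[ok] <- vapply(parts, function(p)
            if (length(p) >= 4 && nzchar(p[4])) p[4] else NA_character_, "")
        eff[ok][grepl("synonymous_variant", term)] <- "synonymous"
        eff[ok][grepl("missense_variant|stop_gained|stop_lost|start_lost",
                      term)] <- "nonsynonymous"
    }
    data.frame(gene_id = gene, effect = eff, stringsAsFactors = FALSE)
}

#' Read biallelic SNPs from a VCF into a SnpExperiment
#'
#' Parses a VCF (v4.x, plain or gzipped), keeps biallelic SNP records only
#' (single-nucleotide REF and ALT; indels and multi-allelic records are
#' dropped and counted in a message), converts GT fields to alt-allele
#' dosages (phase separators are ignored), and drops sites where either
#' population has fewer than \code{minCalledPerPop} non-missing diploid
#' calls.
#'
#' @param path VCF path.
#' @param populationMap named character vector (see [readPopMap()]) covering
#'   every sample in the VCF.
#' @param minCalledPerPop minimum non-missing diploid calls required in each
#'   population for a site to be retained (default 1).
#' @return a [SnpExperiment-class].
#' @export
readSnpVcf <- function(path, populationMap, minCalledPerPop = 1L) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
        !grepl(",", alt, fixed = TRUE) & ref != alt
    nDropped <- sum(!snp)
    if (nDropped)
        message(nDropped,
                " non-biallelic-SNP record(s) dropped (indels/multi-allelic)")
    if (!any(snp)) stop("no biallelic SNP records in ", path)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt)) stop("VCF has no GT fields: ", path)
    gt <- gt[snp, , drop = FALSE]
    samples <- colnames(gt)
    missingSamples <- setdiff(samples, names(populationMap))
    if (length(missingSamples))
        stop("sample(s) in VCF absent from population map: ",
             paste(missingSamples, collapse = ", "))
    d <- .gtToDosage(gt)
    pops <- populationMap[samples]
    keep <- .enoughCalls(d, pops, minCalledPerPop)
    if (!all(keep))
        message(sum(!keep), " site(s) dropped: fewer than ", minCalledPerPop,
                " called diploid(s) in a population")
    if (!any(keep)) stop("no sites pass the per-population call filter")
    SnpExperiment(dosage = d[keep, , drop = FALSE],
                  scaffold = fix[snp, "CHROM"][keep],
                  position = as.integer(fix[snp, "POS"][keep]),
                  ref = ref[snp][keep], alt = alt[snp][keep],
                  population = pops)
}

.gtToDosage <- function(gt) {
    g <- gsub("|", "/", gt, fixed = TRUE)
    d <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
    d[g %in% c("0/0")] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g %in% c("1/1")] <- 2L
    d
}

.enoughCalls <- function(d, pops, minCalledPerPop) {
    labs <- unique(pops)
    ok <- rep(TRUE, nrow(d))
    for (lab in labs) {
        called <- rowSums(!is.na(d[, pops == lab, drop = FALSE]))
        ok <- ok & called >= minCalledPerPop
    }
    ok
}

#' Write a SnpExperiment as a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only genotype fields (unphased \code{0/0},
#' \code{0/1}, \code{1/1}, \code{./.}), sufficient to round-trip the dosage
#' matrix, positions and alleles through [readSnpVcf()].
#'
#' @param x a [SnpExperiment-class].
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeSnpVcf <- function(x, path) {
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    d <- dosage(x)
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    body <- paste(as.character(GenomicRanges::seqnames(rr)),
                  GenomicRanges::start(rr),
                  ".", mc$ref, mc$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    hdr <- c("##fileformat=VCFv4.2",
             "##source=FstScan",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(x)), collapse = "\t"))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Filter sites on pooled minor allele frequency
#'
#' Retains sites whose minor allele frequency, computed over the non-missing
#' calls of all samples pooled, is at least \code{threshold}. With
#' \code{threshold = 0} this is the identity.
#'
#' @param x a [SnpExperiment-class].
#' @param threshold MAF cutoff in [0, 0.5].
#' @return the filtered [SnpExperiment-class].
#' @export
filterMaf <- function(x, threshold = 0.05) {
    stopifnot(threshold >= 0, threshold <= 0.5)
    keep <- pooledMaf(x) >= threshold
    if (!all(keep))
        message(sum(!keep), " site(s) dropped with pooled MAF < ", threshold)
    x[keep, ]
}

#' Attach gene annotations to sites
#'
#' Joins an annotation table (see [readAnnotationTable()]) onto the sites of
#' \code{x} by (scaffold, position). Unmatched sites keep \code{NA} gene id
#' and effect class \code{"other"}.
#'
#' @param x a [SnpExperiment-class].
#' @param annotations data.frame with columns \code{scaffold},
#'   \code{position}, \code{gene_id}, \code{effect}.
#' @return \code{x} with \code{gene_id}/\code{effect} row metadata filled in.
#' @export
attachAnnotations <- function(x, annotations) {
    rr <- SummarizedExperiment::rowRanges(x)
    key <- paste(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr))
    akey <- paste(annotations$scaffold, as.integer(annotations$position))
    if (anyDuplicated(akey))
        stop("duplicate (scaffold, position) keys in annotation table")
    idx <- match(key, akey)
    mc <- S4Vectors::mcols(rr)
    mc$gene_id <- ifelse(is.na(idx), NA_character_,
                         annotations$gene_id[idx])
    eff <- ifelse(is.na(idx), "other", annotations$effect[idx])
    eff[is.na(eff)] <- "other"
    mc$effect <- eff
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x)) <- mc
    x
}

#' Write the canonical per-site table
#'
#' Tab-separated site table (scaffold, position, ref, alt, gene id, effect,
#' pooled MAF) mirroring the row metadata of the experiment.
#'
#' @param x a [SnpExperiment-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSiteTable <- function(x, path) {
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    tab <- data.frame(
        scaffold = as.character(GenomicRanges::seqnames(rr)),
        position = GenomicRanges::start(rr),
        ref = mc$ref, alt = mc$alt,
        gene_id = ifelse(is.na(mc$gene_id), ".", mc$gene_id),
        effect = mc$effect,
        maf = pooledMaf(x))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
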