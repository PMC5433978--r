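#' SnpExperiment: biallelic SNP sites by diploid samples
#'
#' An S4 container for a filtered set of biallelic exonic SNPs, extending
#' \linkS4class{RangedSummarizedExperiment}. Rows are SNP sites (a
#' \link[GenomicRanges]{GRanges} over genome scaffolds carrying \code{ref},
#' \code{alt}, \code{gene_id} and \code{effect} metadata columns), columns are
#' diploid samples, and the single \code{"dosage"} assay holds alt-allele
#' dosages coded 0/1/2 with \code{NA} for missing genotypes. The
#' \code{population} column of \code{colData} assigns every sample to a
#' population; the differentiation machinery requires exactly two labels.
#'
#' Validity requires: single-nucleotide \code{ref != alt}; strictly increasing
#' positions within each scaffold; dosages in \{0, 1, 2, NA\}; a non-missing
#' population label per sample.
#'
#' @aliases SnpExperiment-class
#' @seealso [SnpExperiment()] for construction, [readSnpVcf()] to import from
#'   VCF, [simulateSnpDataset()] to generate synthetic data.
#' @exportClass SnpExperiment
setClass("SnpExperiment", contains = "RangedSummarizedExperiment")

.validSnpExperiment <- function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    for (f in c("ref", "alt", "gene_id", "effect"))
        if (!f %in% colnames(mc))
            msg <- c(msg, sprintf("rowRanges metadata column '%s' is required", f))
    if (all(c("ref", "alt") %in% colnames(mc)) && length(rr)) {
        if (!all(nchar(mc$ref) == 1L & nchar(mc$alt) == 1L))
            msg <- c(msg, "ref and alt must be single nucleotides")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref must differ from alt at every site")
    }
    if (length(rr)) {
        sc <- as.character(GenomicRanges::seqnames(rr))
        pos <- GenomicRanges::start(rr)
        if (any(pos < 1L))
            msg <- c(msg, "positions must be >= 1")
        ord <- unlist(lapply(split(pos, sc)[unique(sc)],
                             function(p) all(diff(p) > 0)))
        if (!all(ord))
            msg <- c(msg, "positions must be strictly increasing within a scaffold")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"population" %in% colnames(cd))
        msg <- c(msg, "colData column 'population' is required")
    else if (any(is.na(cd$population)))
        msg <- c(msg, "every sample needs a population label")
    if (length(msg)) msg else TRUE
}
setValidity("SnpExperiment", .validSnpExperiment)

#' Construct a SnpExperiment
#'
#' @param dosage integer matrix of alt-allele dosages (sites x samples),
#'   values 0/1/2 or NA.
#' @param scaffold character vector of scaffold ids, one per site.
#' @param position 1-based site positions (bp) within scaffold.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param population named character vector or plain vector (length = number
#'   of samples) of population labels; names, if present, must match the
#'   dosage column names.
#' @param geneId optional gene id per site (NA = unannotated).
#' @param effect optional effect class per site, one of \code{"synonymous"},
#'   \code{"nonsynonymous"}, \code{"other"}; NA is coerced to \code{"other"}
#'   at unannotated sites.
#' @return A [SnpExperiment-class] object with sites ordered by (scaffold,
#'   position).
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' se <- SnpExperiment(d, scaffold = c("sc1", "sc1"), position = c(10L, 20L),
#'                     ref = c("A", "C"), alt = c("G", "T"),
#'                     population = c(s1 = "popA", s2 = "popB"))
#' se
#' @export
SnpExperiment <- function(dosage, scaffold, position, ref, alt, population,
                          geneId = NA_character_, effect = NA_character_) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    rownames(dosage) <- NULL
    n <- nrow(dosage)
    geneId <- rep_len(as.character(geneId), n)
    effect <- rep_len(as.character(effect), n)
    effect[is.na(effect)] <- "other"
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(scaffold),
        ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
        ref = as.character(ref), alt = as.character(alt),
        gene_id = geneId, effect = effect)
    if (is.null(colnames(dosage)))
        colnames(dosage) <- if (!is.null(names(population)))
            names(population) else paste0("sample", seq_len(ncol(dosage)))
    if (!is.null(names(population))) {
        if (!setequal(names(population), colnames(dosage)))
            stop("population names do not match dosage column names")
        population <- population[colnames(dosage)]
    }
    cd <- S4Vectors::DataFrame(population = as.character(population),
                               row.names = colnames(dosage))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr, colData = cd)
    se <- se[order(as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr)), ]
    new("SnpExperiment", se)
}

#' @describeIn SnpExperiment Number of sites and samples.
#' @param object a \code{SnpExperiment}.
#' @export
setMethod("show", "SnpExperiment", function(object) {
    pops <- table(populations(object))
    cat(sprintf("SnpExperiment: %d biallelic SNPs x %d samples over %d scaffolds\n",
                nrow(object), ncol(object),
                length(unique(as.character(GenomicRanges::seqnames(
                    SummarizedExperiment::rowRanges(object)))))))
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
              collapse = ", "), "\n")
    ann <- sum(!is.na(geneIds(object)))
    cat(sprintf("annotated sites: %d/%d\n", ann, nrow(object)))
    invisible(NULL)
})

#' ParsimonyNetwork: a statistical-parsimony haplotype network
#'
#' Unique haplotypes as nodes (with multiplicity and per-population
#' composition) and mutational-step edges, connected agglomeratively in
#' nondecreasing Hamming distance order up to the parsimony connection limit
#' \code{jMax}. Edges carry \code{steps} (the Hamming distance) and
#' \code{intermediates} (\code{steps - 1} unobserved intermediate haplotypes).
#' Equal-distance alternative connections between the same pair of components
#' are all retained, giving TCS-style reticulation; haplotype clusters that
#' cannot be connected within \code{jMax} remain separate subnetworks.
#'
#' @slot nodes data.frame with columns \code{hap_id}, \code{sequence},
#'   \code{multiplicity}.
#' @slot popCounts integer matrix, haplotypes x populations.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{steps},
#'   \code{intermediates}.
#' @slot jMax integer connection limit in mutational steps.
#' @slot alpha parsimony confidence level used to derive \code{jMax}
#'   (NA when \code{jMax} was supplied directly).
#' @slot L alignment length (bp).
#' @aliases ParsimonyNetwork-class
#' @seealso [buildNetwork()], [parsimonyConnectionLimit()], [asIgraph()].
#' @exportClass ParsimonyNetwork
setClass("ParsimonyNetwork",
         representation(nodes = "data.frame", popCounts = "matrix",
                        edges = "data.frame", jMax = "integer",
                        alpha = "numeric", L = "integer"))

setValidity("ParsimonyNetwork", function(object) {
    msg <- character()
    if (nrow(object@edges) &&
        any(object@edges$steps > object@jMax))
        msg <- c(msg, "every edge must satisfy steps <= jMax")
    if (nrow(object@nodes) &&
        !identical(nrow(object@nodes), nrow(object@popCounts)))
        msg <- c(msg, "popCounts rows must match nodes")
    if (length(msg)) msg else TRUE
})

#' @describeIn ParsimonyNetwork Summary of nodes, edges and subnetworks.
#' @param object a \code{ParsimonyNetwork}.
#' @export
setMethod("show", "ParsimonyNetwork", function(object) {
    cat(sprintf("ParsimonyNetwork: %d haplotypes (%d sequences), %d edges\n",
                nrow(object@nodes), sum(object@nodes$multiplicity),
                nrow(object@edges)))
    cat(sprintf("connection limit jMax = %d steps (alpha = %s, L = %d bp)\n",
                object@jMax,
                ifelse(is.na(object@alpha), "supplied", format(object@alpha)),
                object@L))
    comp <- networkComponents(object)
    cat(sprintf("subnetworks: %d\n", length(unique(comp))))
    invisible(NULL)
})
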