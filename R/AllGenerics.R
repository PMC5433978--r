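#' Accessors for SnpExperiment
#'
#' \code{dosage} returns the sites x samples alt-allele dosage matrix;
#' \code{populations} the per-sample population labels; \code{geneIds} and
#' \code{effectClasses} the per-site annotation; \code{pooledMaf} the pooled
#' minor allele frequency over all non-missing calls.
#'
#' @param x a [SnpExperiment-class].
#' @return \code{dosage}: integer matrix; \code{populations}: named character
#'   vector; \code{geneIds}, \code{effectClasses}: character vectors;
#'   \code{pooledMaf}: numeric vector in [0, 0.5].
#' @name snp-accessors
NULL

#' @rdname snp-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname snp-accessors
#' @export
setMethod("dosage", "SnpExperiment", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname snp-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname snp-accessors
#' @export
setMethod("populations", "SnpExperiment", function(x) {
    p <- SummarizedExperiment::colData(x)$population
    names(p) <- colnames(x)
    p
})

#' @rdname snp-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname snp-accessors
#' @export
setMethod("geneIds", "SnpExperiment", function(x)
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$gene_id)

#' @rdname snp-accessors
#' @export
setGeneric("effectClasses", function(x) standardGeneric("effectClasses"))
#' @rdname snp-accessors
#' @export
setMethod("effectClasses", "SnpExperiment", function(x)
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$effect)

#' @rdname snp-accessors
#' @export
setGeneric("pooledMaf", function(x) standardGeneric("pooledMaf"))
#' @rdname snp-accessors
#' @export
setMethod("pooledMaf", "SnpExperiment", function(x) {
    d <- dosage(x)
    called <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * called)
    pmin(p, 1 - p)
})

#' Per-scaffold SNP counts and densities
#'
#' Tabulates, for every scaffold with a known length, the number of SNPs in
#' \code{x} and the SNP density (count / length, SNPs per bp). Used to pick
#' scaffolds comparable to a target scaffold via double ranking
#' (see [selectComparableScaffolds()]).
#'
#' @param x a [SnpExperiment-class].
#' @param scaffoldLengths named numeric vector of scaffold lengths in bp
#'   (e.g. from [readScaffoldLengths()]); must cover every scaffold in
#'   \code{x}.
#' @return data.frame with columns \code{scaffold}, \code{length},
#'   \code{n_snps}, \code{density}.
#' @export
setGeneric("scaffoldInfo", function(x, scaffoldLengths)
    standardGeneric("scaffoldInfo"))
#' @rdname scaffoldInfo
#' @export
setMethod("scaffoldInfo", "SnpExperiment", function(x, scaffoldLengths) {
    sc <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(x)))
    miss <- setdiff(unique(sc), names(scaffoldLengths))
    if (length(miss))
        stop("scaffolds missing from length table: ",
             paste(head(miss, 5), collapse = ", "))
    cnt <- table(sc)
    scaff <- names(scaffoldLengths)
    n <- as.integer(ifelse(scaff %in% names(cnt), cnt[scaff], 0L))
    data.frame(scaffold = scaff,
               length = unname(as.numeric(scaffoldLengths)),
               n_snps = n,
               density = n / unname(as.numeric(scaffoldLengths)),
               stringsAsFactors = FALSE)
})
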