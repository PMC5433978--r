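writeTestVcf <- function(records, samples, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, records), path)
}

test_that("readSnpVcf keeps biallelic SNPs and drops indels/multi-allelics", {
    path <- withr::local_tempfile(fileext = ".vcf")
    gt <- "0/0\t0/1\t1/1\t0/0"
    recs <- c(paste("sc1", 10, ".", "A", "G", ".", "PASS", ".", "GT", gt, sep = "\t"),
              paste("sc1", 20, ".", "A", "AT", ".", "PASS", ".", "GT", gt, sep = "\t"),
              paste("sc1", 30, ".", "C", "T", ".", "PASS", ".", "GT", gt, sep = "\t"),
              paste("sc1", 40, ".", "CTT", "C", ".", "PASS", ".", "GT", gt, sep = "\t"),
              paste("sc1", 50, ".", "G", "A,T", ".", "PASS", ".", "GT", gt, sep = "\t"),
              paste("sc1", 60, ".", "G", "C", ".", "PASS", ".", "GT", gt, sep = "\t"))
    writeTestVcf(recs, c("a1", "a2", "b1", "b2"), path)
    pm <- c(a1 = "p1", a2 = "p1", b1 = "p2", b2 = "p2")
    x <- suppressMessages(readSnpVcf(path, pm, minCalledPerPop = 1))
    expect_equal(nrow(x), 3L)
    expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(x)),
                 c(10L, 30L, 60L))
    expect_equal(unname(dosage(x)[1, ]), c(0L, 1L, 2L, 0L))
})

test_that("sites with too few calls in one population are dropped", {
    path <- withr::local_tempfile(fileext = ".vcf")
    recs <- c(paste("sc1", 10, ".", "A", "G", ".", ".", ".", "GT",
                    "0/0\t0/1\t./.\t./.", sep = "\t"),
              paste("sc1", 20, ".", "A", "G", ".", ".", ".", "GT",
                    "0/0\t0/1\t1/1\t0/1", sep = "\t"))
    writeTestVcf(recs, c("a1", "a2", "b1", "b2"), path)
    pm <- c(a1 = "p1", a2 = "p1", b1 = "p2", b2 = "p2")
    x <- suppressMessages(readSnpVcf(path, pm, minCalledPerPop = 1))
    expect_equal(nrow(x), 1L)
    expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(x)), 20L)
})

test_that("a VCF sample absent from the population map is an error", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeTestVcf(paste("sc1", 10, ".", "A", "G", ".", ".", ".", "GT",
                       "0/0\t1/1", sep = "\t"), c("a1", "zz"), path)
    expect_error(readSnpVcf(path, c(a1 = "p1"), 1), "zz")
})

test_that("write -> read round-trips a 1000-site synthetic table losslessly", {
    sim <- simulateSnpDataset(nSnps = 1000, nScaffolds = 10, seed = 11)
    x <- sim$experiment
    td <- withr::local_tempdir()
    p <- writeDataset(sim, file.path(td, "rt"))
    x2 <- readSnpVcf(p[["vcf"]], readPopMap(p[["popmap"]]))
    x2 <- attachAnnotations(x2, readAnnotationTable(p[["annotations"]]))
    expect_identical(dosage(x2), dosage(x))
    expect_identical(
        GenomicRanges::start(SummarizedExperiment::rowRanges(x2)),
        GenomicRanges::start(SummarizedExperiment::rowRanges(x)))
    expect_identical(geneIds(x2), geneIds(x))
    expect_identical(effectClasses(x2), effectClasses(x))
    expect_identical(populations(x2), populations(x))
    # and a second write is byte-identical
    writeSnpVcf(x2, file.path(td, "again.vcf"))
    expect_identical(readLines(file.path(td, "again.vcf"))[-2],
                     readLines(p[["vcf"]])[-2])
})

test_that("MAF filter matches brute-force per-site recomputation", {
    sim <- simulateSnpDataset(nSnps = 400, nScaffolds = 5, seed = 5)
    x <- sim$experiment
    d <- dosage(x)
    bruteMaf <- apply(d, 1, function(g) {
        g <- g[!is.na(g)]
        p <- sum(g) / (2 * length(g))
        min(p, 1 - p)
    })
    y <- suppressMessages(filterMaf(x, 0.05))
    expect_equal(nrow(y), sum(bruteMaf >= 0.05))
    expect_identical(dosage(y), d[bruteMaf >= 0.05, , drop = FALSE])
    # threshold 0 is the identity
    expect_identical(dosage(filterMaf(x, 0)), d)
})

test_that("one alt allele among 30 called alleles is dropped at MAF 0.05", {
    d <- matrix(0L, nrow = 1, ncol = 15)
    d[1, 1] <- 1L
    x <- makeSnp(d, rep(c("p1", "p2"), c(7, 8)))
    expect_equal(pooledMaf(x), 1 / 30)
    expect_equal(nrow(suppressMessages(filterMaf(x, 0.05))), 0L)
})

test_that("annotation join marks unmatched sites unannotated", {
    d <- matrix(1L, nrow = 3, ncol = 4)
    x <- makeSnp(d, c("p1", "p1", "p2", "p2"),
                 position = c(10L, 20L, 30L))
    ann <- data.frame(scaffold = "sc1", position = c(10L, 30L),
                      gene_id = c("gA", "gB"),
                      effect = c("synonymous", "nonsynonymous"))
    y <- attachAnnotations(x, ann)
    expect_equal(geneIds(y), c("gA", NA, "gB"))
    expect_equal(effectClasses(y), c("synonymous", "other", "nonsynonymous"))
    # empty annotation table: everything unannotated
    y0 <- attachAnnotations(x, ann[0, ])
    expect_true(all(is.na(geneIds(y0))))
    # duplicate keys error
    expect_error(attachAnnotations(x, ann[c(1, 1), ]), "duplicate")
})

test_that("filters commute and preserve site order and coordinates", {
    sim <- simulateSnpDataset(nSnps = 300, nScaffolds = 4, seed = 9)
    x <- sim$experiment
    rr <- SummarizedExperiment::rowRanges(x)
    ann <- data.frame(
        scaffold = as.character(GenomicRanges::seqnames(rr)),
        position = GenomicRanges::start(rr),
        gene_id = geneIds(x), effect = effectClasses(x))[c(TRUE, FALSE), ]
    a <- suppressMessages(attachAnnotations(filterMaf(x, 0.1), ann))
    b <- suppressMessages(filterMaf(attachAnnotations(x, ann), 0.1))
    expect_identical(dosage(a), dosage(b))
    expect_identical(geneIds(a), geneIds(b))
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(a))
    sc <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(a)))
    expect_true(all(unlist(lapply(split(pos, sc), function(p)
        diff(p) > 0))))
})

test_that("validity rejects malformed experiments", {
    d <- matrix(1L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
    expect_error(SnpExperiment(d, c("sc1", "sc1"), c(10L, 10L),
                               c("A", "A"), c("G", "G"),
                               c(s1 = "p1", s2 = "p2")),
                 "strictly increasing")
    expect_error(SnpExperiment(d, c("sc1", "sc1"), c(10L, 20L),
                               c("A", "C"), c("A", "G"),
                               c(s1 = "p1", s2 = "p2")),
                 "differ")
})

test_that("snpEff-style ANN strings map onto the three-way effect class", {
    ann <- c("G|synonymous_variant|LOW|geneX|x|x",
             "T|missense_variant|MODERATE|geneY|x|x",
             "T|intron_variant|MODIFIER|geneZ|x|x",
             NA)
    got <- parseSnpEffAnn(ann)
    expect_equal(got$gene_id, c("geneX", "geneY", "geneZ", NA))
    expect_equal(got$effect,
                 c("synonymous", "nonsynonymous", "other", "other"))
})
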