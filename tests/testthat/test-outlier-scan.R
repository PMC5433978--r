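fakeWindows <- function(k, meanFst, chrom = NULL) {
    n <- length(k)
    data.frame(CHROM = if (is.null(chrom)) sprintf("sc%03d", seq_len(n))
                       else chrom,
               BIN_START = 1L, BIN_END = 10000L,
               N_VARIANTS = as.integer(k), MEAN_FST = meanFst,
               stringsAsFactors = FALSE)
}

test_that("the null pool holds exactly the defined per-SNP FST values", {
    st <- data.frame(fst = c(0.1, NA, 0.3, NA, NA, -0.05, 0.2, 0.9, 0, 0.4))
    pool <- buildNullPool(st, B = 100, seed = 1)
    expect_equal(length(pool$fst), 7L)
    expect_error(buildNullPool(data.frame(fst = NA_real_), B = 10, seed = 1),
                 "no defined")
})

test_that("a constant pool gives p = 1 for any window at that value", {
    pool <- buildNullPool(data.frame(fst = rep(0.25, 50)), B = 2000, seed = 3)
    bt <- windowBootstrap(fakeWindows(c(1, 4, 9), rep(0.25, 3)), pool)
    expect_equal(bt$P_EMPIRICAL, rep(1, 3))
    expect_false(any(bt$SIGNIFICANT))
})

test_that("two-point pool recovers the enumerated tail probability", {
    # pool = {0, 1} equally; k = 2; observed mean 1.0: only the draw (1,1)
    # of the 4 equiprobable draws reaches it, so p -> 0.25
    pool <- buildNullPool(data.frame(fst = rep(c(0, 1), 500)),
                          B = 100000, seed = 9)
    bt <- windowBootstrap(fakeWindows(2, 1.0), pool)
    mcSe <- sqrt(0.25 * 0.75 / pool$B)
    expect_lt(abs(bt$P_EMPIRICAL - 0.25), 4 * mcSe)
})

test_that("same seed reproduces identical p-values; window order is irrelevant", {
    set.seed(1)
    st <- data.frame(fst = rnorm(500, 0.01, 0.08))
    w <- fakeWindows(sample(1:8, 20, replace = TRUE),
                     runif(20, -0.05, 0.3))
    pool <- buildNullPool(st, B = 5000, seed = 77)
    b1 <- windowBootstrap(w, pool)
    b2 <- windowBootstrap(w[sample(nrow(w)), ], pool)
    expect_identical(b1$EXCEEDANCES, b2$EXCEEDANCES)
    b3 <- windowBootstrap(w, pool, sharedNulls = FALSE)
    b4 <- windowBootstrap(w[rev(seq_len(nrow(w))), ], pool,
                          sharedNulls = FALSE)
    expect_identical(b3$EXCEEDANCES, b4$EXCEEDANCES)
})

test_that("raising an observed mean can never gain exceedances", {
    set.seed(5)
    pool <- buildNullPool(data.frame(fst = rnorm(300, 0, 0.1)),
                          B = 3000, seed = 12)
    means <- seq(-0.1, 0.4, by = 0.05)
    bt <- windowBootstrap(fakeWindows(rep(3, length(means)), means), pool)
    ord <- order(bt$MEAN_FST)
    expect_true(all(diff(bt$EXCEEDANCES[ord]) <= 0))
})

test_that("significance means zero exceedances and p below the 1/B floor", {
    pool <- buildNullPool(data.frame(fst = runif(100)), B = 1000, seed = 2)
    bt <- windowBootstrap(fakeWindows(c(2, 3), c(2, 0.1)), pool)
    expect_true(bt$SIGNIFICANT[bt$MEAN_FST == 2])
    sig <- bt[bt$SIGNIFICANT, ]
    expect_true(all(sig$P_EMPIRICAL < 1 / pool$B))
    expect_true(all(bt$P_EMPIRICAL[!bt$SIGNIFICANT] >= 1 / pool$B))
    expect_true(all(bt$P_UPPER == (bt$EXCEEDANCES + 1) / (pool$B + 1)))
})

test_that("lower-tail scanning flags depressed windows", {
    pool <- buildNullPool(data.frame(fst = runif(200, 0.2, 0.8)),
                          B = 2000, seed = 4)
    bt <- windowBootstrap(fakeWindows(c(3, 3), c(0.05, 0.5)), pool,
                          lowerTail = TRUE)
    expect_true(bt$SIGNIFICANT[bt$MEAN_FST == 0.05])
    expect_false(bt$SIGNIFICANT[bt$MEAN_FST == 0.5])
})

test_that("top-fraction selection uses the ceiling and positional tie-break", {
    st <- data.frame(scaffold = "sc1", position = 1:200,
                     fst = rep(0.5, 200), gene_id = NA, effect = "other")
    top <- topFractionSnps(st, 0.005)
    expect_equal(nrow(top), 1L)           # ceiling(1.0) of 200 * 0.005
    expect_equal(top$position, 1L)        # all tied: positional order wins
    # ties broken by (scaffold, position) ascending, verified against a
    # brute-force stable sort
    set.seed(8)
    st2 <- data.frame(scaffold = sample(c("a", "b"), 100, replace = TRUE),
                      position = sample.int(1000, 100),
                      fst = sample(c(0.1, 0.5, 0.9), 100, replace = TRUE),
                      gene_id = NA, effect = "other")
    top2 <- topFractionSnps(st2, 0.2)
    ord <- st2[order(-st2$fst, st2$scaffold, st2$position), ]
    expect_equal(top2$position, ord$position[1:20])
    expect_equal(attr(top2, "fst_range"), range(top2$fst))
})

test_that("per-gene counts split by effect and group unannotated sites", {
    top <- data.frame(
        gene_id = c("A", "A", "A", "B", NA),
        effect = c("synonymous", "nonsynonymous", "synonymous",
                   "other", "synonymous"))
    gc <- perGeneCounts(top)
    expect_equal(gc$gene_id, c("A", "(unannotated)", "B"))
    expect_equal(gc$count, c(3L, 1L, 1L))
    expect_equal(gc$synonymous[1], 2L)
    expect_equal(gc$nonsynonymous[1], 1L)
    expect_equal(gc$count, gc$synonymous + gc$nonsynonymous + gc$other)
    expect_equal(nrow(perGeneCounts(top[0, ])), 0L)
})

test_that("comparable-scaffold selection reproduces the double ranking", {
    # constructed interior case: density order tracks length order, so the
    # median-length target is interior in both rankings -> untruncated bands
    ordInfo <- data.frame(scaffold = sprintf("t%02d", 1:30),
                          length = seq(2e6, by = -1e4, length.out = 30))
    ordInfo$n_snps <- round(ordInfo$length * 1e-3) + 1:30
    ordInfo$density <- ordInfo$n_snps / ordInfo$length
    sel <- selectComparableScaffolds(ordInfo, "t15")
    expect_equal(nrow(sel), 9L)                         # 2*4 + 1
    expect_true("t15" %in% sel$scaffold)
    # randomised fixtures against the double-ranking oracle
    set.seed(15)
    info <- data.frame(scaffold = sprintf("s%02d", 1:30),
                       length = sample.int(2e6, 30),
                       n_snps = sample.int(500, 30))
    info$density <- info$n_snps / info$length
    target <- info$scaffold[order(-info$length)][15]   # interior in length
    sel2 <- selectComparableScaffolds(info, target)
    expect_true(target %in% sel2$scaffold)
    expect_setequal(sel2$scaffold, oracleComparable(info, target, 10, 4))
    # target at the top of the length ranking: band truncates to 11
    longest <- info$scaffold[which.max(info$length)]
    byLen <- info[order(-info$length, info$scaffold), ]
    kept <- byLen[1:11, ]     # 10 below + itself
    selL <- selectComparableScaffolds(info, longest, 10, 99)
    expect_setequal(selL$scaffold, kept$scaffold)
    expect_error(selectComparableScaffolds(info, "nope"), "not in")
})

test_that("bootstrap p-values are calibrated under an exchangeable null", {
    set.seed(71)
    poolVals <- rnorm(5000, 0.01, 0.08)
    nWin <- 500; B <- 10000
    k <- sample(2:10, nWin, replace = TRUE)
    obs <- vapply(k, function(kk) mean(sample(poolVals, kk, replace = TRUE)),
                  0)
    pool <- buildNullPool(data.frame(fst = poolVals), B = B, seed = 99)
    bt <- windowBootstrap(fakeWindows(k, obs), pool, sharedNulls = FALSE)
    frac <- mean(bt$P_EMPIRICAL < 0.05)
    se <- sqrt(0.05 * 0.95 / nWin)
    expect_lt(abs(frac - 0.05), 3 * se)
})
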