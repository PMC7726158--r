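mkTrack2 <- function(pos, score, chrom = "LG1") {
    gr <- GenomicRanges::GRanges(rep(chrom, length(pos)),
                                 IRanges::IRanges(pos, width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        rho = rep(1, length(pos)), lrt = rep(0, length(pos)),
        p = rep(1, length(pos)), score = score)
    scoreTrack("ref", gr)
}

test_that("mapScores assigns sites by half-open-boundary overlap", {
    ## sites at 1-based positions 11, 12, 13 with scores 1, 2, 3
    tr <- mkTrack2(11:13, c(1, 2, 3))
    iv <- GenomicRanges::GRanges("LG1", IRanges::IRanges(11, 13))
    fs <- mapScores(tr, iv, "x")
    expect_equal(regionScores(fs), 2)
    expect_equal(pooledScores(fs), c(1, 2, 3))
    ## a site just before the interval is not assigned
    before <- mkTrack2(10, 9)
    expect_true(is.na(regionScores(mapScores(before, iv, "x"))))
    ## unmapped intervals flagged and excluded from pooled scores
    two <- GenomicRanges::GRanges("LG1", IRanges::IRanges(c(11, 50),
                                                          c(13, 60)))
    fs2 <- mapScores(tr, two, "x")
    expect_equal(unmappedIntervals(fs2), 2L)
    expect_equal(pooledScores(fs2), c(1, 2, 3))
    ## sites may belong to several overlapping intervals
    ovl <- GenomicRanges::GRanges("LG1", IRanges::IRanges(c(11, 12),
                                                          c(12, 13)))
    fs3 <- mapScores(tr, ovl, "x")
    expect_equal(regionScores(fs3), c(1.5, 2.5))
})

test_that("scoreEcdf is a right-continuous ECDF ending at one", {
    e <- scoreEcdf(c(1, 1, 2))
    expect_equal(e$value, c(1, 2))
    expect_equal(e$fraction, c(2 / 3, 1))
    expect_equal(scoreEcdf(5), data.frame(value = 5, fraction = 1))
    expect_error(scoreEcdf(numeric(0)), "non-empty")
    ## shift monotonicity: ECDF of x + 1 lies right of ECDF of x
    set.seed(2)
    x <- rnorm(100)
    e0 <- scoreEcdf(x); e1 <- scoreEcdf(x + 1)
    shared <- intersect(e0$value, e1$value)
    for (v in shared)
        expect_gte(e0$fraction[match(v, e0$value)],
                   e1$fraction[match(v, e1$value)])
})

test_that("welchT matches the textbook formula and stats::t.test", {
    x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
    w <- welchT(x, y)
    ## closed form: means 2.5/3.5, s^2 = 5/3 each, se = sqrt(5/6)
    expect_equal(w$t, -1 / sqrt(5 / 6), tolerance = 1e-12)
    expect_equal(w$df, 6, tolerance = 1e-12)
    tt <- t.test(x, y)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    ## random samples against stats::t.test
    set.seed(8)
    for (i in 1:10) {
        a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = 2)
        w <- welchT(a, b); tt <- t.test(a, b)
        expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
        expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
        expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    }
    ## antisymmetry and degenerate cases
    w1 <- welchT(x, y); w2 <- welchT(y, x)
    expect_equal(w1$t, -w2$t); expect_equal(w1$p, w2$p)
    wEq <- welchT(x, x)
    expect_equal(wEq$t, 0); expect_equal(wEq$p, 1)
    expect_error(welchT(c(1, 1), c(2, 2)), "zero variance")
    expect_error(welchT(1, c(1, 2)), ">= 2")
})

test_that("lengthMatchedSample respects the tolerance and falls back", {
    ar <- GenomicRanges::GRanges("LG1",
        IRanges::IRanges(c(1, 400, 900), width = c(295, 300, 800)))
    targets <- GenomicRanges::GRanges("LG1",
        IRanges::IRanges(c(2000, 3000), width = c(300, 500)))
    set.seed(1)
    draws <- replicate(50, suppressWarnings(
        lengthMatchedSample(ar, targets)))
    ## first target (300 bp, tol 30): draws only from the 295/300 ARs
    expect_true(all(draws[1, ] %in% c(1L, 2L)))
    expect_setequal(unique(draws[1, ]), c(1L, 2L))
    ## second target (500 bp, tol 50): no AR within tolerance; nearest is 300
    expect_warning(lengthMatchedSample(ar, targets[2]), "nearest")
    expect_true(all(draws[2, ] == 2L))
    expect_error(lengthMatchedSample(ar[0], targets), "non-empty")
})

test_that("resampling is reproducible and seed-sensitive", {
    set.seed(99)
    pos <- 1:2000
    tr <- mkTrack2(pos, rnorm(2000))
    ar <- GenomicRanges::GRanges("LG1",
        IRanges::IRanges(seq(1, 1801, by = 100), width = 80))
    targets <- GenomicRanges::GRanges("LG1",
        IRanges::IRanges(c(301, 901), width = 80))
    r1 <- runResampling(tr, ar, targets, nIter = 20L, seed = 5L)
    r2 <- runResampling(tr, ar, targets, nIter = 20L, seed = 5L)
    expect_identical(r1@tests, r2@tests)
    expect_identical(nSignificant(r1), nSignificant(r2))
    r3 <- runResampling(tr, ar, targets, nIter = 20L, seed = 6L)
    expect_false(identical(r1@tests$t, r3@tests$t))
    ## single iteration works; invalid inputs rejected
    one <- runResampling(tr, ar, targets, nIter = 1L, seed = 2L)
    expect_equal(one@nIter, 1L)
    expect_error(runResampling(tr, ar, targets, nIter = 0L), "nIter")
    expect_error(runResampling(tr, ar, targets, alpha = 1.5), "alpha")
    ## unmapped target is a hard error naming the interval
    badTargets <- GenomicRanges::GRanges("LG1",
        IRanges::IRanges(c(301, 5000), width = 80))
    expect_error(runResampling(tr, ar, badTargets, nIter = 2L), "2")
})
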