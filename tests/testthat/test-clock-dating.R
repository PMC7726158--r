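test_that("lognormal moment inversion matches closed forms and sampling", {
    ## sigma^2 = ln 2 when mean == sd == 1
    ls <- lognormalFromRealMoments(1, 1)
    expect_equal(ls$sigma^2, log(2), tolerance = 1e-14)
    ## degenerate limit: sd -> 0 gives sigma -> 0, mu -> ln(mean)
    ls0 <- lognormalFromRealMoments(10, 1e-9)
    expect_lt(ls0$sigma, 1e-9)
    expect_equal(ls0$mu, log(10), tolerance = 1e-9)
    ## the study calibration: draws reproduce the real-space moments
    ls45 <- lognormalFromRealMoments(45.5, 0.5)
    set.seed(1)
    x <- rlnorm(1e6, ls45$mu, ls45$sigma)
    expect_equal(mean(x), 45.5, tolerance = 3 * 0.5 / sqrt(1e6) / 45.5)
    expect_equal(sd(x), 0.5, tolerance = 0.01)
    expect_error(lognormalFromRealMoments(-1, 1), "positive")
    ## the prior object enforces its own invariants
    cp <- calibrationPrior(c("a", "b"), 45.5, 0.5)
    expect_true(validObject(cp))
})

test_that("prior-only sampling recovers the calibration density", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 6e4, seed = 2L)
    res <- runClockMCMC(character(0), topo, calib, cfg)
    root <- tmrca(res, topo$tip.label)
    ## loose Monte-Carlo band at this desk-scale chain; the acceptance test
    ## re-checks with a longer run and tighter error bars
    expect_equal(root$mean, 45.5, tolerance = 0.02)
    expect_equal(sd(root$samples), 0.5, tolerance = 0.1)
    ## quantile-quantile agreement with the analytic lognormal
    ls <- lognormalFromRealMoments(45.5, 0.5)
    qs <- seq(0.1, 0.9, by = 0.1)
    expect_equal(unname(quantile(root$samples, qs)),
                 qlnorm(qs, ls$mu, ls$sigma), tolerance = 0.01)
})

test_that("posterior samples always respect the topology's age order", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 5000, seed = 3L)
    res <- runClockMCMC(character(0), topo, calib, cfg)
    ages <- ageSamples(res)
    ## node ids: 6 root, 7, 8, 9 nested in the caterpillar topology
    expect_true(all(ages[, "6"] > ages[, "7"]))
    expect_true(all(ages[, "7"] > ages[, "8"]))
    expect_true(all(ages[, "8"] > ages[, "9"]))
    expect_true(all(ages > 0))
})

test_that("the chain is deterministic given a seed", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 5000, seed = 7L)
    r1 <- runClockMCMC(character(0), topo, calib, cfg)
    r2 <- runClockMCMC(character(0), topo, calib, cfg)
    expect_identical(ageSamples(r1), ageSamples(r2))
    expect_identical(r1@lambda, r2@lambda)
})

test_that("acceptance rates sit in the workable band after tuning", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    m <- substModel("HKY", c(0.3, 0.2, 0.2, 0.3), kappa = 2)
    seqs <- simulateClockSequences(topo, c("6" = 45.5, "7" = 40, "8" = 35,
                                           "9" = 30), 0.002, 800L, m,
                                   seed = 4L)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 3e4, seed = 9L)
    res <- runClockMCMC(seqs, topo, calib, cfg)
    expect_true(all(res@acceptance > 0.1 & res@acceptance < 0.9))
})

test_that("tmrca summarizes the right node and nests below the root", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 5000, seed = 5L)
    res <- runClockMCMC(character(0), topo, calib, cfg)
    root <- tmrca(res, topo$tip.label)
    pairRoot <- tmrca(res, c("Oniloticus", "Pnyererei"))  # MRCA is the root
    expect_identical(root$samples, pairRoot$samples)
    sisters <- tmrca(res, c("Mzebra", "Pnyererei"))
    expect_true(all(sisters$samples <= root$samples))
    expect_error(tmrca(res, c("Mzebra", "nope")), "unknown")
})

test_that("sequence data pull the focal split toward its true age", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    m <- substModel("HKY", c(0.3, 0.2, 0.2, 0.3), kappa = 2)
    truth <- c("6" = 45.5, "7" = 36, "8" = 22, "9" = 9)
    seqs <- simulateClockSequences(topo, truth, 0.002, 2000L, m, seed = 12L)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 4e4, seed = 13L)
    res <- runClockMCMC(seqs, topo, calib, cfg)
    for (nd in c("7", "8", "9")) {
        est <- mean(ageSamples(res)[, nd])
        expect_lt(abs(est - truth[[nd]]) / truth[[nd]], 0.25)
    }
})

test_that("configuration and input validation catch bad settings", {
    topo <- cichlidTopo()
    calib <- calibrationPrior(topo$tip.label, 45.5, 0.5)
    expect_error(datingConfig(), "clockRate")
    expect_error(datingConfig(clockRate = 0.002, chainLength = 10), ">= 1000")
    expect_error(datingConfig(clockRate = 0.002, burnin = 1), "burnin")
    ## non-monophyletic calibration in the caterpillar topology
    badCal <- calibrationPrior(c("Oniloticus", "Mzebra"), 45.5, 0.5)
    cfg <- datingConfig(clockRate = 0.002, chainLength = 1000, seed = 1L)
    expect_error(runClockMCMC(character(0), topo, badCal, cfg),
                 "monophyletic")
    ## unequal sequence lengths
    seqs <- c(Oniloticus = "ACGT", Nbrichardi = "ACG", Aburtoni = "ACGT",
              Mzebra = "ACGT", Pnyererei = "ACGT")
    expect_error(runClockMCMC(seqs, topo, calib, cfg), "equal")
})
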