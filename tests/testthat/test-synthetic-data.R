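test_that("rate 0 regions are identical across taxa; generation is pure", {
    tr <- tree4()
    m <- revModel()
    reg <- data.frame(label = c("frozen", "neutral"),
                      length = c(500L, 500L), rate = c(0, 1),
                      codon = FALSE)
    plan <- regionPlan(reg, tr, m, seed = 3L, blockSize = 400L)
    sim <- simulateAlignment(plan)
    ## frozen region: every taxon equals the reference over [1, 500]
    seqs <- vapply(sim$blocks, function(b) b@text[1], "")
    whole <- lapply(seq_len(4), function(i)
        paste(vapply(sim$blocks, function(b) b@text[i], ""), collapse = ""))
    frozen <- substr(unlist(whole), 1, 500)
    expect_true(all(frozen == frozen[1]))
    neutral <- substr(unlist(whole), 501, 1000)
    expect_false(all(neutral == neutral[1]))
    ## same plan, same alignment; different seed differs
    sim2 <- simulateAlignment(plan)
    expect_identical(lapply(sim$blocks, slot, "text"),
                     lapply(sim2$blocks, slot, "text"))
    plan3 <- regionPlan(reg, tr, m, seed = 4L, blockSize = 400L)
    expect_false(identical(simulateAlignment(plan3)$blocks[[1]]@text,
                           sim$blocks[[1]]@text))
})

test_that("manifest intervals tile the genome and round-trip as JSON", {
    plan <- regionPlan(data.frame(label = c("a", "b", "c"),
                                  length = c(120L, 300L, 90L),
                                  rate = c(1, 0.5, 2), codon = FALSE),
                       tree4(), revModel(), seed = 1L)
    sim <- simulateAlignment(plan)
    reg <- sim$manifest$regions
    expect_equal(reg$start[1], 0)
    expect_equal(reg$end[nrow(reg)], sim$manifest$genomeLength)
    expect_equal(reg$start[-1], reg$end[-nrow(reg)])  # exact tiling
    path <- tempfile(fileext = ".json")
    writeManifest(sim$manifest, path)
    back <- readManifest(path)
    expect_equal(back$regions, reg)
    expect_equal(back$genomeLength, sim$manifest$genomeLength)
    expect_equal(ape::read.tree(text = back$tree)$edge.length,
                 tree4()$edge.length)
})

test_that("pairwise divergence matches the Jukes-Cantor expectation", {
    ## two taxa, total path t: P(diff) = (3/4)(1 - exp(-4t/3))
    tr <- tree2()   # t = 0.3
    jc <- jcModel()
    plan <- regionPlan(data.frame(label = "x", length = 10000L, rate = 1,
                                  codon = FALSE), tr, jc, seed = 8L)
    sim <- simulateAlignment(plan)
    a <- strsplit(sim$blocks[[1]]@text[1], "")[[1]]
    b <- strsplit(sim$blocks[[1]]@text[2], "")[[1]]
    pDiff <- mean(a != b)
    pExp <- 0.75 * (1 - exp(-4 * 0.3 / 3))
    expect_lt(abs(pDiff - pExp), 3 * sqrt(pExp * (1 - pExp) / 10000))
})

test_that("long neutral regions converge to the stationary composition", {
    m <- revModel()
    plan <- regionPlan(data.frame(label = "x", length = 50000L, rate = 1,
                                  codon = FALSE), tree4(), m, seed = 5L)
    sim <- simulateAlignment(plan)
    anc <- table(factor(strsplit(sim$blocks[[1]]@text[1], "")[[1]],
                        levels = c("A", "C", "G", "T")))
    chi <- suppressWarnings(chisq.test(as.numeric(anc),
                                       p = unname(modelPi(m))))
    expect_gt(chi$p.value, 0.01)
})

test_that("codon-structured regions exclude stop codons in the reference", {
    plan <- regionPlan(data.frame(label = "CDS", length = 3000L, rate = 0,
                                  codon = TRUE), tree4(), revModel(),
                       seed = 6L)
    sim <- simulateAlignment(plan)
    ## rate 0: tips equal the ancestor, so tip codons are ancestral codons
    ref <- strsplit(sim$blocks[[1]]@text[1], "")[[1]]
    codons <- apply(matrix(ref, nrow = 3), 2, paste, collapse = "")
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
})

test_that("clock sequence simulation matches the JC distance oracle", {
    topo <- tree2()
    jc <- jcModel()
    ## two taxa split at T = 25 MY, rate 0.004/MY: path = 2 * 0.1 subs/site
    seqs <- simulateClockSequences(topo, c("3" = 25), 0.004, 20000L, jc,
                                   seed = 10L)
    x <- strsplit(as.character(seqs[["a"]]), "")[[1]]
    y <- strsplit(as.character(seqs[["b"]]), "")[[1]]
    p <- mean(x != y)
    dJC <- -0.75 * log(1 - 4 * p / 3)       # standard JC distance estimator
    expect_lt(abs(dJC - 0.2), 3 * sqrt(0.2 / 20000) * 2)
    ## clock rate 0: identical tips; bad ages rejected
    same <- simulateClockSequences(topo, c("3" = 25), 0, 100L, jc, seed = 2L)
    expect_identical(as.character(same[["a"]]), as.character(same[["b"]]))
    topo4 <- tree4()
    expect_error(simulateClockSequences(topo4,
        c("5" = 10, "6" = 20, "7" = 5), 0.01, 10L, jc), "older")
})

test_that("the default cichlid scenario mirrors the study design", {
    plan <- defaultCichlidScenario(seed = 42L)
    expect_length(plan@taxa, 5L)
    expect_setequal(plan@taxa, c("Oniloticus", "Nbrichardi", "Aburtoni",
                                 "Mzebra", "Pnyererei"))
    reg <- plan@regions
    expect_equal(sum(reg$label == "nORF-intergenic"), 9L)
    expect_equal(sum(reg$label == "nORF-intronic"), 27L)
    expect_gte(sum(reg$label == "AR"), 200L)
    expect_equal(unique(reg$rate[reg$label == "CDS"]), 0.3)
    expect_equal(unique(reg$rate[reg$label == "AR"]), 1)
    expect_equal(unique(reg$rate[reg$label == "nORF-intergenic"]), 2)
    expect_equal(unique(reg$rate[reg$label == "nORF-intronic"]), 0.5)
    expect_true(all(reg$codon == (reg$label == "CDS")))
    ## clock-consistent branch lengths: root-to-tip path equal for all tips
    depths <- ape::node.depth.edgelength(plan@tree)[1:5]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-12)
    expect_equal(max(depths), 45.5 * 0.002, tolerance = 1e-12)
})
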