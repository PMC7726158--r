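## Shared fixtures: small trees, models and MAF builders used across tests.

suppressPackageStartupMessages(library(GenomicRanges))

jcModel <- function() substModel("HKY", pi = rep(0.25, 4), kappa = 1)

revModel <- function()
    substModel("REV", pi = c(0.31, 0.19, 0.20, 0.30),
               rates = c(1.4, 4.5, 1.1, 0.9, 4.2, 1.0))

tree2 <- function() ape::read.tree(text = "(a:0.1,b:0.2);")
tree3 <- function() ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.4);")
tree4 <- function()
    ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.1);")
tree5 <- function()
    ape::read.tree(text = paste0("(e:0.25,(d:0.2,(c:0.15,",
                                 "(a:0.1,b:0.1):0.05):0.05):0.05);"))

## a tiny two-block, three-species MAF file written to a temp path
writeTinyMaf <- function(path = tempfile(fileext = ".maf")) {
    writeLines(c(
        "##maf version=1",
        "",
        "a score=0",
        "s ref.LG1 10 8 + 1000 ACGT-ACGT",
        "s sp2.c1   5 9 + 2000 ACGTTACGT",
        "s sp3.c2   0 7 - 1500 ACG--ACGT",
        "",
        "a score=0",
        "s ref.LG1 50 4 + 1000 CCCC",
        "s sp2.c1  40 4 + 2000 CTCC"), path)
    path
}

## deterministic all-taxa column matrix simulated under a model/tree
simColumns <- function(tree, model, n, scale = 1, seed = 1L) {
    reg <- data.frame(label = "x", length = as.integer(n), rate = scale,
                      codon = FALSE)
    plan <- regionPlan(reg, tree, model, seed = seed, blockSize = n + 1L)
    sim <- simulateAlignment(plan)
    b <- sim$blocks[[1]]
    m <- matrix(unlist(strsplit(b@text, ""), use.names = FALSE),
                nrow = blockRows(b), byrow = TRUE)
    rownames(m) <- blockSpecies(b)
    m
}

## the five-cichlid topology used by dating tests (unit branch lengths;
## dating ignores them)
cichlidTopo <- function()
    ape::read.tree(text = paste0(
        "(Oniloticus:1,(Nbrichardi:1,(Aburtoni:1,",
        "(Mzebra:1,Pnyererei:1):1):1):1);"))

## Independent closed-form oracle for HKY transition probabilities
## (standard analytic solution, written directly from the generator).
hkyClosedForm <- function(pi, kappa, t) {
    names(pi) <- c("A", "C", "G", "T")
    ## normalization factor so branch lengths are expected substitutions/site
    beta <- 1 / (2 * (pi["A"] + pi["G"]) * (pi["C"] + pi["T"]) +
                 2 * kappa * (pi["A"] * pi["G"] + pi["C"] * pi["T"]))
    P <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
    piY <- pi["C"] + pi["T"]; piR <- pi["A"] + pi["G"]
    for (i in names(pi)) for (j in names(pi)) {
        pij <- pi[j]
        group <- if (j %in% c("A", "G")) piR else piY
        e2 <- exp(-beta * t)
        e3 <- exp(-beta * t * (1 + group * (kappa - 1)))
        P[i, j] <- if (i == j) {
            pij + pij * (1 / group - 1) * e2 + ((group - pij) / group) * e3
        } else if ((i %in% c("A", "G")) == (j %in% c("A", "G"))) {
            ## transition within purines or pyrimidines
            pij + pij * (1 / group - 1) * e2 - (pij / group) * e3
        } else {
            pij * (1 - e2)
        }
    }
    P
}
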