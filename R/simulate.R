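## Synthetic-data generator: multi-species alignments with region-wise rate
## multipliers (and codon-structured CDS so 4D extraction finds genuinely
## neutral sites), plus strict-clock sequence sets with known node ages.
## Everything is a pure function of (plan, seed).

.STOPS <- c("TAA", "TAG", "TGA")

## Sample child states from parent states given a transition matrix,
## vectorized over sites by parent state.
.evolveStates <- function(parent, P) {
    child <- integer(length(parent))
    for (s in 1:4) {
        idx <- which(parent == s)
        if (length(idx))
            child[idx] <- sample.int(4, length(idx), replace = TRUE,
                                     prob = P[s, ])
    }
    child
}

## Ancestral sequence for one region (integer states 1..4). Codon-structured
## regions rejection-sample each codon to avoid stop codons.
.ancestralRegion <- function(len, pi, codon) {
    if (!codon)
        return(sample.int(4, len, replace = TRUE, prob = pi))
    nCodon <- len / 3L
    out <- integer(len)
    for (k in seq_len(nCodon)) {
        repeat {
            cod <- sample.int(4, 3L, replace = TRUE, prob = pi)
            if (!paste(BASES[cod], collapse = "") %in% .STOPS) break
        }
        out[(3L * k - 2L):(3L * k)] <- cod
    }
    out
}

## Per-site rate multipliers for one region. In codon-structured regions the
## third position of 4-fold-family codons (judged on the ancestral codon)
## evolves neutrally (rho = 1); everything else at the region's rho.
.regionRates <- function(anc, rho, codon) {
    rates <- rep(rho, length(anc))
    if (codon) {
        i1 <- seq(1L, length(anc), by = 3L)
        prefix <- paste0(BASES[anc[i1]], BASES[anc[i1 + 1L]])
        third <- i1[prefix %in% .FOURFOLD_PREFIX] + 2L
        rates[third] <- 1
    }
    rates
}

#' Simulate a multi-species alignment from a region plan
#'
#' Draws an ancestral sequence from the model's stationary frequencies
#' (codon-structured regions avoid stop codons), evolves it down the tree by
#' sampling child states from `P(branch x region rho)` site-wise, and emits
#' the result as MAF blocks over a single synthetic reference chromosome
#' (split at `blockSize` to exercise block-boundary handling), BED-style
#' feature sets per label, and a ground-truth manifest.
#'
#' @param plan a [RegionPlan-class].
#' @return list with `blocks` (list of [MafBlock-class]), `features` (named
#'   list of `GRanges` per label), and `manifest` (regions table, tree,
#'   model parameters, seed).
#' @export
simulateAlignment <- function(plan) {
    validObject(plan)
    set.seed(plan@seed)
    reg <- plan@regions
    model <- plan@model
    pi <- unname(model@pi)
    L <- sum(reg$length)

    ## ancestral states and per-site rates
    anc <- integer(L); rates <- numeric(L)
    off <- 0L
    starts <- integer(nrow(reg))
    for (r in seq_len(nrow(reg))) {
        len <- reg$length[r]
        a <- .ancestralRegion(len, pi, reg$codon[r])
        anc[(off + 1L):(off + len)] <- a
        rates[(off + 1L):(off + len)] <- .regionRates(a, reg$rate[r],
                                                      reg$codon[r])
        starts[r] <- off
        off <- off + len
    }

    ## evolve down the tree (preorder), caching P per (edge, rho)
    tree <- reorder.phylo(plan@tree, "postorder")
    nTip <- Ntip(tree)
    preorder <- rev(seq_len(nrow(tree$edge)))
    states <- vector("list", nTip + tree$Nnode)
    states[[nTip + 1L]] <- anc
    uniqRates <- sort(unique(rates))
    for (e in preorder) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        childStates <- integer(L)
        for (u in uniqRates) {
            idx <- which(rates == u)
            t <- tree$edge.length[e] * u
            if (t == 0) {
                childStates[idx] <- states[[pa]][idx]
            } else {
                P <- transitionMatrix(model, t)
                childStates[idx] <- .evolveStates(states[[pa]][idx], P)
            }
        }
        states[[ch]] <- childStates
    }

    ## emit MAF blocks (reference = first taxon, forward strand, no gaps)
    taxa <- plan@taxa
    tipSeq <- lapply(taxa, function(tx)
        BASES[states[[match(tx, tree$tip.label)]]])
    names(tipSeq) <- taxa
    cuts <- unique(c(seq(0L, L, by = plan@blockSize), L))
    blocks <- lapply(seq_len(length(cuts) - 1L), function(i) {
        s <- cuts[i]; e <- cuts[i + 1L]
        txt <- vapply(taxa, function(tx)
            paste(tipSeq[[tx]][(s + 1L):e], collapse = ""), "")
        mafBlock(src = paste0(taxa, ".", plan@chrom),
                 start = rep(s, length(taxa)),
                 size = rep(e - s, length(taxa)),
                 strand = rep("+", length(taxa)),
                 srcSize = rep(L, length(taxa)), text = txt)
    })

    ## features: 1-based closed GRanges per label
    gr <- GRanges(plan@chrom,
                  IRanges(start = starts + 1L, width = reg$length),
                  strand = ifelse(reg$codon, "+", "*"))
    mcols(gr)$label <- reg$label
    if (any(reg$codon)) mcols(gr)$frame <- ifelse(reg$codon, 0L, NA_integer_)
    features <- lapply(split(seq_along(gr), reg$label), function(i) gr[i])

    manifest <- list(
        chrom = plan@chrom, genomeLength = L,
        regions = data.frame(label = reg$label, start = starts,
                             end = starts + reg$length, rate = reg$rate,
                             codon = reg$codon),
        tree = ape::write.tree(plan@tree),
        model = list(kind = model@kind, pi = as.numeric(model@pi),
                     rates = as.numeric(model@rates)),
        seed = plan@seed)
    list(blocks = blocks, features = features, manifest = manifest)
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest manifest list from [simulateAlignment()].
#' @param path JSON path.
#' @return `path` invisibly / the manifest list.
#' @export
writeManifest <- function(manifest, path) {
    write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    m <- read_json(path, simplifyVector = TRUE)
    m$regions <- as.data.frame(m$regions)
    m
}

#' Simulate strict-clock sequences with known node ages
#'
#' Evolves `length` sites down a fixed topology with branch lengths
#' `clockRate x (parent age - child age)` under the given model.
#'
#' @param topology rooted `phylo`.
#' @param nodeAges numeric vector of internal-node ages (MY), named by ape
#'   node id (root is `Ntip + 1`).
#' @param clockRate substitutions/site/MY.
#' @param length number of sites (>= 1).
#' @param model a [SubstModel-class].
#' @param seed integer seed.
#' @return `DNAStringSet` of tip sequences, names = tip labels.
#' @export
simulateClockSequences <- function(topology, nodeAges, clockRate, length,
                                   model, seed = 1L) {
    if (length < 1) stop("length must be >= 1")
    nTip <- Ntip(topology)
    age <- function(nd) if (nd <= nTip) 0 else nodeAges[as.character(nd)]
    for (e in seq_len(nrow(topology$edge))) {
        if (age(topology$edge[e, 1]) < age(topology$edge[e, 2]))
            stop("child older than parent in nodeAges")
    }
    set.seed(seed)
    tree <- reorder.phylo(topology, "postorder")
    states <- vector("list", nTip + tree$Nnode)
    states[[nTip + 1L]] <- sample.int(4, length, replace = TRUE,
                                      prob = unname(model@pi))
    for (e in rev(seq_len(nrow(tree$edge)))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        t <- clockRate * (age(pa) - age(ch))
        states[[ch]] <- if (t == 0) states[[pa]]
            else .evolveStates(states[[pa]], transitionMatrix(model, t))
    }
    seqs <- vapply(seq_len(nTip), function(i)
        paste(BASES[states[[i]]], collapse = ""), "")
    DNAStringSet(setNames(seqs, tree$tip.label))
}

#' The default five-cichlid synthetic scenario
#'
#' A ready-made [RegionPlan-class] emulating the study system: a 5-taxon tree
#' (Nile tilapia reference plus four haplochromine-lineage cichlids) with
#' strict-clock-derived branch lengths (node ages 45.5/30/18/8 MY at a
#' neutral rate of 0.002 substitutions/site/MY), REV model with fish-like
#' AT-rich frequencies, and a genome of 12 three-intron genes
#' (codon-structured CDS at rho 0.3, UTRs at 0.7, introns at 0.9),
#' 220 ancestral repeats and intergenic background at rho 1,
#' 9 nORF-intergenic regions at rho 2 and 27 nORF-intronic regions at
#' rho 0.5 (the mapped region counts of the study).
#'
#' @param seed integer seed (controls AR/nORF length draws and, downstream,
#'   the simulated alignment).
#' @return A [RegionPlan-class].
#' @export
defaultCichlidScenario <- function(seed = 42L) {
    taxa <- c("Oniloticus", "Nbrichardi", "Aburtoni", "Mzebra", "Pnyererei")
    rate <- 0.002                      # subs/site/MY
    ages <- c(root = 45.5, n2 = 30, n3 = 18, n4 = 8)
    nwk <- sprintf(
        "(Oniloticus:%f,(Nbrichardi:%f,(Aburtoni:%f,(Mzebra:%f,Pnyererei:%f):%f):%f):%f);",
        ages["root"] * rate, ages["n2"] * rate, ages["n3"] * rate,
        ages["n4"] * rate, ages["n4"] * rate,
        (ages["n3"] - ages["n4"]) * rate,
        (ages["n2"] - ages["n3"]) * rate,
        (ages["root"] - ages["n2"]) * rate)
    tree <- ape::read.tree(text = nwk)
    model <- substModel("REV", pi = c(0.31, 0.19, 0.20, 0.30),
                        rates = c(1.4, 4.5, 1.1, 0.9, 4.2, 1.0))
    set.seed(seed)
    rows <- list()
    addRegion <- function(label, len, rho, codon = FALSE)
        rows[[length(rows) + 1L]] <<-
            data.frame(label = label, length = as.integer(len),
                       rate = rho, codon = codon)
    spacer <- function() addRegion("intergenic",
                                   sample(150:400, 1L), 1)
    ## 12 genes, 3 introns each; 27 of the 36 introns host a nORF-intronic
    intronSlot <- 0L
    for (g in seq_len(12L)) {
        spacer()
        addRegion("5UTR", 200, 0.7)
        addRegion("CDS", 900, 0.3, codon = TRUE)
        for (i in 1:3) {
            intronSlot <- intronSlot + 1L
            if (intronSlot <= 27L) {
                addRegion("intron", 450, 0.9)
                addRegion("nORF-intronic", sample(seq(200, 800, by = 2), 1L),
                          0.5)
                addRegion("intron", 450, 0.9)
            } else {
                addRegion("intron", 900, 0.9)
            }
            if (i < 3) addRegion("CDS", 600, 0.3, codon = TRUE)
        }
        addRegion("CDS", 900, 0.3, codon = TRUE)
        addRegion("3UTR", 400, 0.7)
    }
    ## ancestral-repeat zone: 220 ARs with a lognormal length distribution
    arLens <- pmax(80L, pmin(2000L, round(rlnorm(220, log(300), 0.5))))
    for (al in arLens) {
        spacer()
        addRegion("AR", al, 1)
    }
    ## 9 nORF-intergenic regions at rho = 2
    for (k in seq_len(9L)) {
        spacer()
        addRegion("nORF-intergenic", sample(seq(300, 1200, by = 2), 1L), 2)
    }
    spacer()
    regionPlan(do.call(rbind, rows), tree, model, seed = seed)
}
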