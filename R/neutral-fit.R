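## Neutral-model construction: extract four-fold-degenerate (4D) columns from
## CDS annotations over the alignment, then fit a REV model by maximum
## likelihood on a fixed topology.

## third-position 4D codon families: CTN GTN TCN CCN ACN GCN CGN GGN
.FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

## Per-block lookup tables for one reference species:
## forward-strand 0-based position of every non-gap reference character, and
## the block column that holds it.
.refIndex <- function(block, refSpecies) {
    i <- referenceRow(block, refSpecies)
    chars <- strsplit(block@text[i], "")[[1]]
    nonGap <- which(chars != "-")
    off <- seq_along(nonGap) - 1L
    pos <- if (block@strand[i] == "+") block@start[i] + off
           else block@srcSize[i] - block@start[i] - 1L - off
    list(row = i, chrom = blockChrom(block)[i], pos = pos, col = nonGap,
         minus = block@strand[i] == "-")
}

#' Extract four-fold-degenerate alignment columns
#'
#' Walks reference-species CDS intervals codon by codon (minus-strand CDS are
#' read reverse-complemented; `frame` metadata, if present, trims the leading
#' out-of-phase bases) and emits the alignment column at the third codon
#' position whenever the reference codon belongs to a 4-fold-degenerate
#' family (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN). Degeneracy is judged from
#' the reference codon only. Codons with a reference gap, an ambiguous
#' reference base, or positions spanning two blocks are dropped.
#'
#' @param blocks list of [MafBlock-class] (filtered and sorted).
#' @param cds CDS intervals (`GRanges`, 1-based closed) with strand and an
#'   optional integer `frame` metadata column (0, 1 or 2).
#' @param refSpecies reference species id.
#' @param taxa taxa to report in columns; defaults to the union of species
#'   across blocks. Taxa absent from a block are reported as missing.
#' @return character matrix (taxa x 4D sites) of observed states, with the
#'   source positions in `colnames` as `chrom:pos` (0-based third-position
#'   coordinate).
#' @export
extract4dColumns <- function(blocks, cds, refSpecies, taxa = NULL) {
    if (is.null(taxa))
        taxa <- unique(unlist(lapply(blocks, blockSpecies)))
    idx <- lapply(blocks, .refIndex, refSpecies = refSpecies)
    charMats <- lapply(blocks, .blockCharMatrix)
    ## map: chrom -> (pos -> c(block, col)); built as environment of vectors
    posKey <- unlist(lapply(seq_along(blocks), function(bi)
        paste0(idx[[bi]]$chrom, ":", idx[[bi]]$pos)))
    posBlock <- unlist(lapply(seq_along(blocks), function(bi)
        rep(bi, length(idx[[bi]]$pos))))
    posCol <- unlist(lapply(seq_along(blocks), function(bi) idx[[bi]]$col))
    lookup <- setNames(seq_along(posKey), posKey)

    outCols <- list(); outNames <- character(0)
    for (k in seq_along(cds)) {
        iv <- cds[k]
        p0 <- start(iv) - 1L; p1 <- end(iv) - 1L       # 0-based closed
        minus <- as.character(strand(iv)) == "-"
        frame <- if (!is.null(mcols(iv)$frame)) mcols(iv)$frame else 0L
        coding <- if (minus) seq(p1, p0) else seq(p0, p1)
        if (frame > 0L) coding <- coding[-seq_len(frame)]
        nc <- length(coding)
        if (nc %% 3L != 0L) {
            warning(sprintf("CDS interval %d: length %d not divisible by 3; truncating partial codon",
                            k, nc))
            coding <- coding[seq_len(nc - nc %% 3L)]
        }
        if (!length(coding)) next
        chrom <- as.character(seqnames(iv))
        hit <- lookup[paste0(chrom, ":", coding)]
        codStart <- seq(1L, length(coding), by = 3L)
        for (cs in codStart) {
            h <- hit[cs:(cs + 2L)]
            if (anyNA(h)) next                         # unaligned position
            bi <- posBlock[h]
            if (length(unique(bi)) != 1L) next         # codon straddles blocks
            b <- bi[1L]
            cols <- posCol[h]
            refRow <- idx[[b]]$row
            bases <- charMats[[b]][refRow, cols]
            ## orient into coding direction: reference row stored on some
            ## strand; base at a forward position read as complement when the
            ## CDS (or the ref row) flips orientation
            if (idx[[b]]$minus) bases <- .COMP[bases]  # forward-strand bases
            if (minus) bases <- .COMP[bases]           # coding-strand bases
            if (anyNA(bases) || any(!bases %in% BASES)) next
            if (!paste(bases[1:2], collapse = "") %in% .FOURFOLD_PREFIX) next
            ## emit the stored alignment column at the third position
            colStates <- setNames(rep("-", length(taxa)), taxa)
            sp <- blockSpecies(blocks[[b]])
            present <- sp %in% taxa
            colStates[sp[present]] <- charMats[[b]][present, cols[3L]]
            outCols[[length(outCols) + 1L]] <- colStates
            outNames <- c(outNames, paste0(chrom, ":", coding[cs + 2L]))
        }
    }
    if (!length(outCols)) {
        out <- matrix(character(0), nrow = length(taxa), ncol = 0,
                      dimnames = list(taxa, NULL))
        return(out)
    }
    out <- do.call(cbind, outCols)
    rownames(out) <- taxa
    colnames(out) <- outNames
    out
}

## Root-edge tying: for a reversible model only the sum of the two branches
## incident to the root is identifiable (pulley principle), so the fitter
## estimates the sum and reports it split 50:50.
.rootEdges <- function(tree) which(tree$edge[, 1] == Ntip(tree) + 1L)

#' Fit a neutral REV model by maximum likelihood
#'
#' Maximizes the pruning likelihood of the supplied columns jointly over
#' branch lengths and the six REV exchangeabilities (one fixed to 1 for
#' identifiability) on a fixed topology. Stationary frequencies are set
#' empirically from the observed base counts. The two root-adjacent branch
#' lengths are estimated through their sum and reported split equally.
#' Optimization is multi-start quasi-Newton (BFGS) on log-transformed
#' parameters; branch lengths are floored at 1e-8.
#'
#' @param columns character matrix (taxa x sites), e.g. from
#'   [extract4dColumns()].
#' @param topology rooted `phylo`; its branch lengths (if any) seed the first
#'   start.
#' @param minColumns fit refuses fewer columns than this floor.
#' @param nStarts number of optimizer starts.
#' @param reltol relative log-likelihood convergence tolerance.
#' @return A [NeutralModel-class].
#' @export
fitNeutralModel <- function(columns, topology, minColumns = 100L,
                            nStarts = 3L, reltol = 1e-6) {
    columns <- .columnMatrix(columns)
    if (ncol(columns) < minColumns)
        stop(sprintf("need at least %d columns, got %d", minColumns,
                     ncol(columns)))
    taxa <- rownames(columns)
    if (!setequal(taxa, topology$tip.label))
        stop("column taxa must match the topology's tip labels")

    ## empirical base frequencies from the columns themselves
    obs <- table(factor(toupper(columns), levels = BASES))
    if (any(obs == 0)) obs <- obs + 1          # guard degenerate input
    piHat <- as.numeric(obs) / sum(obs)

    cc <- .compressColumns(columns)
    po <- reorder.phylo(topology, "postorder")
    nEdge <- nrow(po$edge)
    rootE <- .rootEdges(po)
    freeE <- setdiff(seq_len(nEdge), rootE)
    tieRoot <- length(rootE) == 2L
    nBr <- length(freeE) + if (tieRoot) 1L else length(rootE)

    elenFromPar <- function(bl) {
        elen <- numeric(nEdge)
        elen[freeE] <- bl[seq_along(freeE)]
        if (tieRoot) elen[rootE] <- bl[nBr] / 2
        else elen[rootE] <- bl[(length(freeE) + 1L):nBr]
        pmax(elen, 1e-8)
    }
    tipsEnc <- NULL  # filled once tree tip order known
    negLL <- function(par) {
        ## keep the search inside a sane box (branch lengths <= ~150 subs/
        ## site, exchangeabilities within 1e-6..1e6 of the fixed one)
        if (any(par > 14) || any(par < -21)) return(1e10)
        bl <- exp(par[seq_len(nBr)])
        rates <- c(exp(par[(nBr + 1L):(nBr + 5L)]), 1)
        if (any(!is.finite(bl)) || any(!is.finite(rates))) return(1e10)
        m <- try(substModel("REV", piHat, rates = rates), silent = TRUE)
        if (inherits(m, "try-error")) return(1e10)
        e <- m@eig
        ll <- .pruneLogLikCpp(po$edge, Ntip(po), Ntip(po) + po$Nnode,
                              elenFromPar(bl), tipsEnc, unname(m@pi),
                              e$lambda, e$A, e$B, 1.0)
        val <- -sum(cc$counts * ll)
        if (!is.finite(val)) 1e10 else val
    }
    perm <- match(po$tip.label, rownames(cc$columns))
    tipsEnc <- .encodeStates(cc$columns)[perm, , drop = FALSE]

    ## starting points
    startBl <- if (!is.null(po$edge.length) && all(po$edge.length > 0)) {
        bl0 <- numeric(nBr)
        bl0[seq_along(freeE)] <- po$edge.length[freeE]
        bl0[nBr] <- sum(po$edge.length[rootE])
        bl0
    } else rep(0.1, nBr)
    starts <- list(c(log(startBl), rep(0, 5)))
    if (nStarts > 1) {
        set.seed(ncol(columns) %% 1000003L + 7L)  # deterministic extra starts
        for (s in seq_len(nStarts - 1L))
            starts[[s + 1L]] <- c(log(startBl) + rnorm(nBr, 0, 0.5),
                                  rnorm(5, 0, 0.3))
    }
    best <- NULL
    for (st in starts) {
        fit <- optim(st, negLL, method = "BFGS",
                     control = list(maxit = 500, reltol = reltol))
        if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (best$value >= 1e10)
        stop("neutral-model optimization failed to find a finite optimum")

    bl <- exp(best$par[seq_len(nBr)])
    rates <- c(exp(best$par[(nBr + 1L):(nBr + 5L)]), 1)
    model <- substModel("REV", piHat, rates = rates)
    fitted <- po
    fitted$edge.length <- elenFromPar(bl)
    ## return in the caller's edge order
    out <- topology
    m <- match(paste(topology$edge[, 1], topology$edge[, 2]),
               paste(po$edge[, 1], po$edge[, 2]))
    out$edge.length <- fitted$edge.length[m]
    new("NeutralModel", tree = out, model = model,
        nSitesFit = ncol(columns), logLik = -best$value)
}
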