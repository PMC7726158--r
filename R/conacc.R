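## Base-wise CONACC scoring: all-branches likelihood-ratio test of a single
## rate-scale parameter rho against the neutral model. Positive scores mark
## conservation (rho < 1), negative scores acceleration (rho > 1); the
## magnitude is -log10 of the chi-square(1) upper-tail p-value of the LRT.

.conaccFromLrt <- function(rho, lrt, cap = 20) {
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    sc <- ifelse(rho < 1, -log10(p), log10(p))
    sc[rho == 1 | lrt == 0] <- 0
    pmin(pmax(sc, -cap), cap)
}

#' All-branches likelihood-ratio test for one or more columns
#'
#' For each column, finds the rate scale `rho` in `[0, rhoMax]` that
#' maximizes the pruning likelihood with every neutral branch multiplied by
#' `rho`, forms the LRT statistic `2 (logL(rho_hat) - logL(1))`, and converts
#' it to a p-value from the chi-square(1) upper tail (no boundary-mixture
#' correction) and a signed CONACC score capped at `|score| <= cap`.
#'
#' Columns with fewer than `minPresent` non-missing states are returned as
#' `NA` rows (unscoreable, not an error).
#'
#' @param neutral a [NeutralModel-class].
#' @param columns character matrix (taxa x sites) or one named column.
#' @param rhoMax upper bound of the rho search (default 20).
#' @param tol optimization tolerance on rho.
#' @param minPresent minimum non-missing taxa for a column to be scored.
#' @param cap cap on `|score|` so p-value underflow stays finite.
#' @return data.frame with columns `rho`, `lrt`, `p`, `score`.
#' @export
siteLRT <- function(neutral, columns, rhoMax = 20, tol = 1e-6,
                    minPresent = 2L, cap = 20) {
    columns <- .columnMatrix(columns)
    tree <- neutralTree(neutral)
    model <- neutralModel(neutral)
    td <- .treeData(tree, rownames(columns))
    tips <- .encodeStates(columns)[td$perm, , drop = FALSE]
    nPresent <- colSums(tips != 0L)
    out <- data.frame(rho = rep(NA_real_, ncol(tips)), lrt = NA_real_,
                      p = NA_real_, score = NA_real_)
    ok <- nPresent >= minPresent
    if (any(ok)) {
        e <- model@eig
        res <- .rhoLrtCpp(td$edge, td$nTip, td$nNodeTotal, td$elen,
                          tips[, ok, drop = FALSE], unname(model@pi),
                          e$lambda, e$A, e$B, rhoMax, tol)
        rho <- res[, 1]
        lrt <- pmax(2 * (res[, 2] - res[, 3]), 0)
        out$rho[ok] <- rho
        out$lrt[ok] <- lrt
        out$p[ok] <- pchisq(lrt, df = 1, lower.tail = FALSE)
        out$score[ok] <- .conaccFromLrt(rho, lrt, cap)
    }
    out
}

#' Score a whole alignment base-wise against a neutral model
#'
#' Scores every alignment column at which the reference species has a residue
#' and at least `minPresent` taxa are non-missing, anchoring each score to
#' the reference forward-strand coordinate. Unscored positions are absent
#' from the returned track. Blocks lacking the reference species are skipped
#' with a warning.
#'
#' @param neutral a [NeutralModel-class].
#' @param blocks list of [MafBlock-class] (filtered/sorted).
#' @param refSpecies reference species anchoring coordinates.
#' @param minPresent minimum non-missing taxa per column (default 2).
#' @param rhoMax,tol,cap passed to [siteLRT()].
#' @return A [ScoreTrack-class].
#' @export
scoreAlignment <- function(neutral, blocks, refSpecies, minPresent = 2L,
                           rhoMax = 20, tol = 1e-6, cap = 20) {
    taxa <- neutralTree(neutral)$tip.label
    chroms <- character(0); pos <- integer(0)
    res <- list()
    for (b in blocks) {
        if (!refSpecies %in% blockSpecies(b)) {
            warning("skipping block without reference species '",
                    refSpecies, "'")
            next
        }
        ri <- .refIndex(b, refSpecies)
        chars <- .blockCharMatrix(b)
        sp <- blockSpecies(b)
        cols <- matrix("-", nrow = length(taxa), ncol = length(ri$col),
                       dimnames = list(taxa, NULL))
        keep <- sp %in% taxa
        cols[sp[keep], ] <- chars[keep, ri$col, drop = FALSE]
        sc <- siteLRT(neutral, cols, rhoMax = rhoMax, tol = tol,
                      minPresent = minPresent, cap = cap)
        scored <- !is.na(sc$score)
        if (!any(scored)) next
        res[[length(res) + 1L]] <- sc[scored, , drop = FALSE]
        chroms <- c(chroms, rep(ri$chrom, sum(scored)))
        pos <- c(pos, ri$pos[scored])
    }
    if (!length(res)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(rho = numeric(0), lrt = numeric(0),
                               p = numeric(0), score = numeric(0))
        return(new("ScoreTrack", refSpecies = refSpecies, sites = gr))
    }
    d <- do.call(rbind, res)
    gr <- GRanges(chroms, IRanges(start = pos + 1L, width = 1L))  # 1-based
    mcols(gr) <- DataFrame(rho = d$rho, lrt = d$lrt, p = d$p, score = d$score)
    o <- order(as.character(seqnames(gr)), start(gr))
    if (anyDuplicated(paste(chroms, pos)))
        stop("duplicate reference positions across blocks")
    scoreTrack(refSpecies, gr[o])
}
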