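## Accessors and show methods.

#' Species ids of a MAF block
#'
#' The species part of each row's `src` field (text before the first dot;
#' the whole field when there is no dot).
#'
#' @param x a [MafBlock-class].
#' @return character vector of species ids, one per row.
#' @export
blockSpecies <- function(x) sub("\\..*$", "", x@src)

#' Chromosome names of a MAF block
#'
#' @param x a [MafBlock-class].
#' @return character vector of per-row chromosome names.
#' @export
blockChrom <- function(x) {
    hasDot <- grepl(".", x@src, fixed = TRUE)
    ifelse(hasDot, sub("^[^.]*\\.", "", x@src), x@src)
}

#' Width (number of columns) of a MAF block
#'
#' @param x a [MafBlock-class].
#' @return integer block width.
#' @export
blockWidth <- function(x) nchar(x@text[1L])

#' Number of rows of a MAF block
#'
#' @param x a [MafBlock-class].
#' @return integer row count.
#' @export
blockRows <- function(x) length(x@src)

#' Forward-strand start of a row
#'
#' Converts a MAF strand-relative start to the forward strand.
#'
#' @param x a [MafBlock-class].
#' @param i row index (default 1).
#' @return 0-based forward-strand start of row `i`.
#' @export
forwardStart <- function(x, i = 1L) {
    if (x@strand[i] == "+") x@start[i]
    else x@srcSize[i] - x@start[i] - x@size[i]
}

setMethod("show", "MafBlock", function(object) {
    cat(sprintf("MafBlock: %d rows x %d columns\n", blockRows(object),
                blockWidth(object)))
    cat("  species:", paste(blockSpecies(object), collapse = ", "), "\n")
})

#' Stationary frequencies of a substitution model
#'
#' @param x a [SubstModel-class].
#' @return named numeric of base frequencies (A, C, G, T).
#' @export
modelPi <- function(x) x@pi

#' Rate matrix of a substitution model
#'
#' @param x a [SubstModel-class].
#' @return the normalized 4x4 instantaneous rate matrix.
#' @export
modelQ <- function(x) x@Q

#' Exchangeabilities of a substitution model
#'
#' @param x a [SubstModel-class].
#' @return the six symmetric rates (AC, AG, AT, CG, CT, GT).
#' @export
modelRates <- function(x) x@rates

setMethod("show", "SubstModel", function(object) {
    cat(sprintf("SubstModel (%s)\n", object@kind))
    cat("  pi:", paste(sprintf("%s=%.4f", c("A", "C", "G", "T"), object@pi),
                       collapse = " "), "\n")
    if (object@kind == "HKY")
        cat(sprintf("  kappa: %.4f\n", object@kappa))
    else
        cat("  rates:", paste(sprintf("%.4f", object@rates), collapse = " "),
            "\n")
})

#' Tree of a neutral model
#'
#' @param x a [NeutralModel-class].
#' @return the `phylo` tree with fitted branch lengths.
#' @export
neutralTree <- function(x) x@tree

#' Substitution model of a neutral model
#'
#' @param x a [NeutralModel-class].
#' @return the fitted [SubstModel-class].
#' @export
neutralModel <- function(x) x@model

setMethod("show", "NeutralModel", function(object) {
    cat(sprintf("NeutralModel: %d taxa, fitted on %d 4D columns, logLik %.2f\n",
                Ntip(object@tree), object@nSitesFit, object@logLik))
})

#' Scored sites of a track
#'
#' @param x a [ScoreTrack-class].
#' @return width-1 `GRanges` with `rho`, `lrt`, `p`, `score` columns.
#' @export
trackSites <- function(x) x@sites

#' Signed CONACC scores of a track
#'
#' @param x a [ScoreTrack-class].
#' @return numeric vector of per-site scores.
#' @export
trackScores <- function(x) mcols(x@sites)$score

setMethod("show", "ScoreTrack", function(object) {
    cat(sprintf("ScoreTrack (%s): %d scored sites on %d chrom(s)\n",
                object@refSpecies, length(object@sites),
                length(unique(as.character(seqnames(object@sites))))))
})

#' Per-interval mean scores of a mapped feature class
#'
#' @param x a [FeatureScores-class].
#' @return numeric vector (NA for unmapped intervals).
#' @export
regionScores <- function(x) x@regionScore

#' Pooled per-site scores of a mapped feature class
#'
#' @param x a [FeatureScores-class].
#' @return numeric vector of all site scores in the class.
#' @export
pooledScores <- function(x) unlist(x@siteScores, use.names = FALSE)

#' Indices of intervals with no scored sites
#'
#' @param x a [FeatureScores-class].
#' @return integer vector of unmapped interval indices.
#' @export
unmappedIntervals <- function(x) which(is.na(x@regionScore))

setMethod("show", "FeatureScores", function(object) {
    cat(sprintf("FeatureScores '%s': %d intervals (%d unmapped), %d sites\n",
                object@label, length(object@intervals),
                length(unmappedIntervals(object)),
                length(pooledScores(object))))
})

#' Count of significant resampling iterations
#'
#' @param x a [ResamplingResult-class].
#' @return integer count of iterations with `p < alpha`.
#' @export
nSignificant <- function(x) x@nSignificant

setMethod("show", "ResamplingResult", function(object) {
    cat(sprintf(
        "ResamplingResult: %d/%d iterations significant at alpha = %g\n",
        object@nSignificant, object@nIter, object@alpha))
})

#' Posterior age samples of a dating run
#'
#' @param x a [DatingResult-class].
#' @return matrix of retained samples x internal node ages (MY).
#' @export
ageSamples <- function(x) x@ages

setMethod("show", "DatingResult", function(object) {
    cat(sprintf(
        "DatingResult: %d retained samples, %d internal nodes\n",
        nrow(object@ages), ncol(object@ages)))
    cat("  acceptance:",
        paste(sprintf("%s=%.2f", names(object@acceptance), object@acceptance),
              collapse = " "), "\n")
})

setMethod("show", "RegionPlan", function(object) {
    cat(sprintf("RegionPlan: %d regions, %d taxa, %d bp total on %s\n",
                nrow(object@regions), length(object@taxa),
                sum(object@regions$length), object@chrom))
})

setMethod("show", "CalibrationPrior", function(object) {
    cat(sprintf(
        "CalibrationPrior on MRCA(%s): mean %.3f MY, sd %.3f MY (lognormal)\n",
        paste(object@taxa, collapse = ","), object@meanReal, object@sdReal))
})
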