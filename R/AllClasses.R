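setOldClass("phylo")

## ---------------------------------------------------------------------------
## MafBlock: one alignment paragraph of a MAF file. Rows are parallel vectors;
## `src` keeps the raw MAF source field ("species.chrom"), coordinates keep
## MAF semantics (0-based start on the row's own strand).
## ---------------------------------------------------------------------------

#' MafBlock: one block of a multiple alignment (MAF semantics)
#'
#' Rows are stored as parallel vectors in MAF order. Starts are 0-based
#' offsets on the strand of the row (MAF convention); `text` holds the gapped
#' sequence over `A,C,G,T,N,-`.
#'
#' @slot src character, raw MAF source fields (usually `species.chrom`).
#' @slot start numeric, 0-based strand-relative starts.
#' @slot size numeric, ungapped lengths.
#' @slot strand character, `+` or `-` per row.
#' @slot srcSize numeric, full source-sequence lengths.
#' @slot text character, gapped row sequences (equal widths).
#'
#' @export
setClass("MafBlock",
    representation(src = "character", start = "numeric", size = "numeric",
                   strand = "character", srcSize = "numeric",
                   text = "character"))

setValidity("MafBlock", function(object) {
    n <- length(object@src)
    lens <- c(length(object@start), length(object@size),
              length(object@strand), length(object@srcSize),
              length(object@text))
    if (any(lens != n))
        return("row fields must have equal length")
    if (n == 0L)
        return("a MAF block needs at least one row")
    w <- unique(nchar(object@text))
    if (length(w) != 1L)
        return("all row texts must have equal width")
    if (!all(object@strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    if (any(object@start < 0) || any(object@size < 0))
        return("coordinates must be non-negative")
    ungapped <- nchar(gsub("-", "", object@text, fixed = TRUE))
    if (any(ungapped != object@size))
        return(sprintf("row %d: size does not match non-gap character count",
                       which(ungapped != object@size)[1L]))
    if (any(object@start + object@size > object@srcSize))
        return("row extends past its source length")
    TRUE
})

#' Construct a MafBlock
#'
#' @param src raw MAF source names (`species.chrom`).
#' @param start 0-based strand-relative starts.
#' @param size ungapped lengths.
#' @param strand `+`/`-` per row.
#' @param srcSize source sequence lengths.
#' @param text gapped sequences (equal width).
#' @return A [MafBlock-class] object.
#' @export
mafBlock <- function(src, start, size, strand, srcSize, text)
    new("MafBlock", src = src, start = as.numeric(start),
        size = as.numeric(size), strand = strand,
        srcSize = as.numeric(srcSize), text = toupper(text))

## ---------------------------------------------------------------------------
## SubstitutionModel
## ---------------------------------------------------------------------------

#' SubstModel: reversible nucleotide substitution model (REV/GTR or HKY85)
#'
#' The rate matrix is normalized to one expected substitution per site per
#' unit branch length, so fitted branch lengths are in substitutions/site.
#' Base order is (A, C, G, T) throughout the package.
#'
#' @slot kind `"REV"` or `"HKY"`.
#' @slot pi stationary base frequencies (A, C, G, T).
#' @slot rates the six symmetric exchangeabilities (AC, AG, AT, CG, CT, GT);
#'   for HKY these are derived from `kappa`.
#' @slot kappa transition/transversion ratio (`NA` for REV).
#' @slot Q normalized 4x4 instantaneous rate matrix.
#' @slot eig eigendecomposition used for transition probabilities:
#'   `lambda`, and matrices `A`, `B` with `P(t) = A diag(exp(lambda t)) B`.
#'
#' @export
setClass("SubstModel",
    representation(kind = "character", pi = "numeric", rates = "numeric",
                   kappa = "numeric", Q = "matrix", eig = "list"))

setValidity("SubstModel", function(object) {
    if (!object@kind %in% c("REV", "HKY"))
        return("kind must be 'REV' or 'HKY'")
    pi <- object@pi
    if (length(pi) != 4L || any(pi <= 0))
        return("pi must be 4 positive frequencies")
    if (abs(sum(pi) - 1) > 1e-12)
        return("pi must sum to 1 within 1e-12")
    Q <- object@Q
    if (any(abs(rowSums(Q)) > 1e-12))
        return("Q rows must sum to 0 within 1e-12")
    db <- pi * Q - t(pi * Q)          # pi_i Q_ij - pi_j Q_ji
    if (max(abs(db)) > 1e-10)
        return("Q must satisfy detailed balance within 1e-10")
    if (abs(-sum(pi * diag(Q)) - 1) > 1e-12)
        return("Q must be normalized to 1 expected substitution/unit time")
    TRUE
})

## ---------------------------------------------------------------------------
## NeutralModel: tree + model + bookkeeping from the 4D fit
## ---------------------------------------------------------------------------

#' NeutralModel: fitted neutral substitution model
#'
#' @slot tree rooted `phylo` with branch lengths in substitutions/site.
#' @slot model the fitted [SubstModel-class].
#' @slot nSitesFit number of 4D columns used in the fit.
#' @slot logLik log-likelihood at the fitted parameters.
#'
#' @export
setClass("NeutralModel",
    representation(tree = "phylo", model = "SubstModel",
                   nSitesFit = "integer", logLik = "numeric"))

setValidity("NeutralModel", function(object) {
    if (is.null(object@tree$edge.length))
        return("tree must carry branch lengths")
    if (any(object@tree$edge.length < 0) ||
        any(!is.finite(object@tree$edge.length)))
        return("branch lengths must be finite and >= 0")
    if (anyDuplicated(object@tree$tip.label))
        return("taxon labels must be unique")
    TRUE
})

## ---------------------------------------------------------------------------
## ScoreTrack: per-site CONACC scores anchored to reference coordinates
## ---------------------------------------------------------------------------

#' ScoreTrack: base-wise CONACC score track
#'
#' Sites are held as width-1 `GRanges` (1-based, Bioconductor convention)
#' with metadata columns `rho` (fitted rate scale), `lrt`, `p` and `score`
#' (the signed CONACC statistic). Unscored positions are simply absent.
#'
#' @slot refSpecies the reference species anchoring the coordinates.
#' @slot sites width-1 `GRanges` with `rho`, `lrt`, `p`, `score` columns.
#'
#' @export
setClass("ScoreTrack",
    representation(refSpecies = "character", sites = "GRanges"))

setValidity("ScoreTrack", function(object) {
    gr <- object@sites
    need <- c("rho", "lrt", "p", "score")
    if (!all(need %in% colnames(mcols(gr))))
        return("sites need metadata columns rho, lrt, p, score")
    if (length(gr) && any(width(gr) != 1L))
        return("all sites must have width 1")
    if (length(gr)) {
        bychr <- split(start(gr), as.character(seqnames(gr)))
        if (any(vapply(bychr, function(x) is.unsorted(x, strictly = TRUE),
                       logical(1))))
            return("positions must be strictly increasing within chrom")
        if (any(!is.finite(mcols(gr)$score)))
            return("scores must be finite")
    }
    TRUE
})

#' Construct a ScoreTrack
#'
#' @param refSpecies reference species name.
#' @param sites width-1 `GRanges` with `rho`, `lrt`, `p`, `score` columns.
#' @return A [ScoreTrack-class].
#' @export
scoreTrack <- function(refSpecies, sites)
    new("ScoreTrack", refSpecies = refSpecies, sites = sort(sites))

## ---------------------------------------------------------------------------
## FeatureScores: per-interval score lists for one feature class
## ---------------------------------------------------------------------------

#' FeatureScores: site scores mapped onto one feature class
#'
#' @slot label feature-class name.
#' @slot intervals the intervals of the class (`GRanges`).
#' @slot siteScores list of numeric vectors, one per interval.
#' @slot regionScore per-interval mean of site scores (`NA` when unmapped).
#'
#' @export
setClass("FeatureScores",
    representation(label = "character", intervals = "GRanges",
                   siteScores = "list", regionScore = "numeric"))

setValidity("FeatureScores", function(object) {
    n <- length(object@intervals)
    if (length(object@siteScores) != n || length(object@regionScore) != n)
        return("siteScores and regionScore must match the interval count")
    TRUE
})

## ---------------------------------------------------------------------------
## ResamplingResult
## ---------------------------------------------------------------------------

#' ResamplingResult: length-matched AR resampling outcome
#'
#' @slot nIter number of iterations.
#' @slot alpha significance level per iteration.
#' @slot tests data.frame with one row per iteration: `t`, `df`, `p`.
#' @slot nSignificant count of iterations with `p < alpha`.
#' @slot seed seed the run was made from.
#'
#' @export
setClass("ResamplingResult",
    representation(nIter = "integer", alpha = "numeric",
                   tests = "data.frame", nSignificant = "integer",
                   seed = "integer"))

setValidity("ResamplingResult", function(object) {
    if (object@nSignificant < 0L || object@nSignificant > object@nIter)
        return("nSignificant must lie in [0, nIter]")
    if (nrow(object@tests) != object@nIter)
        return("tests must have one row per iteration")
    if (nrow(object@tests) && any(object@tests$df <= 0))
        return("per-iteration df must be > 0")
    TRUE
})

## ---------------------------------------------------------------------------
## CalibrationPrior
## ---------------------------------------------------------------------------

#' CalibrationPrior: lognormal fossil calibration on an MRCA age
#'
#' Parameterized by real-space moments; `mu`/`sigma` are the log-space
#' parameters such that the lognormal's real-space mean and sd equal
#' `meanReal` and `sdReal`.
#'
#' @slot taxa taxon labels whose MRCA is calibrated.
#' @slot meanReal real-space mean age (MY).
#' @slot sdReal real-space standard deviation (MY).
#' @slot mu log-space location.
#' @slot sigma log-space scale.
#'
#' @export
setClass("CalibrationPrior",
    representation(taxa = "character", meanReal = "numeric",
                   sdReal = "numeric", mu = "numeric", sigma = "numeric"))

setValidity("CalibrationPrior", function(object) {
    m <- object@meanReal; s <- object@sdReal
    if (m <= 0 || s <= 0) return("real-space moments must be positive")
    sig2 <- log(1 + (s / m)^2)
    if (abs(object@sigma^2 - sig2) > 1e-12)
        return("sigma^2 must equal ln(1 + (sd/mean)^2)")
    if (abs(object@mu - (log(m) - sig2 / 2)) > 1e-12)
        return("mu must equal ln(mean) - sigma^2/2")
    TRUE
})

## ---------------------------------------------------------------------------
## DatingResult
## ---------------------------------------------------------------------------

#' DatingResult: posterior samples from the strict-clock MCMC
#'
#' @slot ages matrix of retained samples x internal nodes (ages in MY);
#'   column names are ape node ids.
#' @slot lambda retained Yule birth-rate samples.
#' @slot logPost retained log-posterior trace.
#' @slot acceptance per-operator acceptance rates.
#' @slot topology the fixed rooted topology (`phylo`).
#' @slot config the configuration list the run used.
#'
#' @export
setClass("DatingResult",
    representation(ages = "matrix", lambda = "numeric", logPost = "numeric",
                   acceptance = "numeric", topology = "phylo",
                   config = "list"))

setValidity("DatingResult", function(object) {
    if (length(object@ages) && any(object@ages <= 0))
        return("all sampled ages must be positive")
    TRUE
})

## ---------------------------------------------------------------------------
## RegionPlan
## ---------------------------------------------------------------------------

#' RegionPlan: blueprint for the synthetic alignment simulator
#'
#' @slot regions data.frame with columns `label`, `length`, `rate`,
#'   `codon` (logical: codon-structured region).
#' @slot taxa taxon labels (first one is the synthetic reference).
#' @slot tree rooted `phylo` with branch lengths in substitutions/site.
#' @slot model generating [SubstModel-class].
#' @slot seed integer seed.
#' @slot chrom name of the synthetic reference chromosome.
#' @slot blockSize maximum MAF block width emitted.
#'
#' @export
setClass("RegionPlan",
    representation(regions = "data.frame", taxa = "character",
                   tree = "phylo", model = "SubstModel", seed = "integer",
                   chrom = "character", blockSize = "integer"))

setValidity("RegionPlan", function(object) {
    r <- object@regions
    need <- c("label", "length", "rate", "codon")
    if (!all(need %in% names(r)))
        return("regions needs columns label, length, rate, codon")
    if (any(r$length < 1)) return("region lengths must be >= 1")
    if (any(r$rate < 0)) return("rate multipliers must be >= 0")
    if (any(r$codon & r$length %% 3 != 0))
        return("codon-structured regions must have length divisible by 3")
    if (length(object@taxa) < 2) return("at least two taxa required")
    if (!setequal(object@taxa, object@tree$tip.label))
        return("taxa must match the tree's tip labels")
    TRUE
})

#' Construct a RegionPlan
#'
#' @param regions data.frame with `label`, `length`, `rate`, `codon`.
#' @param tree rooted `phylo` with branch lengths (substitutions/site).
#' @param model generating [SubstModel-class].
#' @param seed integer seed.
#' @param chrom synthetic chromosome name.
#' @param blockSize maximum emitted MAF block width (exercises
#'   block-boundary handling downstream).
#' @return A [RegionPlan-class].
#' @export
regionPlan <- function(regions, tree, model, seed, chrom = "synChr1",
                       blockSize = 10000L)
    new("RegionPlan", regions = regions, taxa = tree$tip.label, tree = tree,
        model = model, seed = as.integer(seed), chrom = chrom,
        blockSize = as.integer(blockSize))
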