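## Mapping per-site scores onto feature classes, distribution comparison
## (ECDF + Welch t-test) and the length-matched ancestral-repeat resampling
## significance procedure.

#' Map a score track onto a feature class
#'
#' Every scored site is assigned to every interval it overlaps (sites may
#' belong to several classes); intervals with no scored site are flagged
#' unmapped and excluded from distributions.
#'
#' @param track a [ScoreTrack-class].
#' @param features intervals of one feature class (`GRanges`).
#' @param label feature-class name.
#' @return A [FeatureScores-class].
#' @export
mapScores <- function(track, features, label = "feature") {
    gr <- trackSites(track)
    hits <- findOverlaps(gr, features, ignore.strand = TRUE)
    sc <- split(mcols(gr)$score[queryHits(hits)],
                factor(subjectHits(hits), levels = seq_along(features)))
    siteScores <- lapply(sc, as.numeric)
    names(siteScores) <- NULL
    regionScore <- vapply(siteScores,
                          function(x) if (length(x)) mean(x) else NA_real_,
                          numeric(1))
    new("FeatureScores", label = label, intervals = features,
        siteScores = siteScores, regionScore = regionScore)
}

#' Right-continuous empirical cumulative distribution
#'
#' @param scores non-empty numeric vector.
#' @return data.frame with sorted unique `value` and cumulative `fraction`
#'   (final fraction is 1).
#' @export
scoreEcdf <- function(scores) {
    if (!length(scores)) stop("scores must be non-empty")
    v <- sort(unique(scores))
    data.frame(value = v,
               fraction = cumsum(tabulate(match(sort(scores), v))) /
                   length(scores))
}

#' Welch two-sample t-test
#'
#' Location test allowing unequal variances:
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided Student-t p-value.
#'
#' @param x,y numeric samples of length >= 2; at least one must have nonzero
#'   variance.
#' @return list with `t`, `df`, `p`.
#' @export
welchT <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (nx < 2L || ny < 2L) stop("both samples need >= 2 observations")
    vx <- var(x); vy <- var(y)
    if (vx == 0 && vy == 0) stop("both samples have zero variance")
    se2x <- vx / nx; se2y <- vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
    p <- 2 * pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

#' Draw one length-matched AR interval per target
#'
#' For each target interval, draws uniformly among AR intervals whose length
#' is within `max(tolBp, tolFrac * target length)` of the target's length;
#' when no AR is within tolerance the nearest-length AR is used and a warning
#' is issued. Draws are with replacement across targets.
#'
#' @param ar ancestral-repeat intervals (`GRanges`), non-empty.
#' @param targets target intervals (`GRanges`).
#' @param tolBp absolute length tolerance floor in bp (default 20).
#' @param tolFrac relative length tolerance (default 0.1).
#' @return integer vector: for each target, the index of the drawn AR.
#' @export
lengthMatchedSample <- function(ar, targets, tolBp = 20, tolFrac = 0.1) {
    if (!length(ar)) stop("AR set must be non-empty")
    arLen <- width(ar)
    vapply(width(targets), function(L) {
        tol <- max(tolBp, tolFrac * L)
        ok <- which(abs(arLen - L) <= tol)
        if (!length(ok)) {
            warning(sprintf(
                "no length-matched AR for target of length %d; using nearest", L))
            which.min(abs(arLen - L))
        } else if (length(ok) == 1L) ok else sample(ok, 1L)
    }, integer(1))
}

#' Length-matched AR resampling significance procedure
#'
#' Per iteration: draw one length-matched AR per target, pool the per-site
#' scores of the drawn ARs, and Welch-t test them against the pooled per-site
#' scores of the targets; count iterations with `p < alpha`. Per-iteration
#' RNG substreams are derived from `seed` by counter, so the result is
#' reproducible and independent of iteration order.
#'
#' @param track a [ScoreTrack-class].
#' @param ar AR intervals (`GRanges`).
#' @param targets target (nORF) intervals (`GRanges`); every target must
#'   contain at least one scored site.
#' @param nIter number of iterations (the study used 10000).
#' @param alpha per-iteration significance level (default 0.05).
#' @param seed integer seed.
#' @param tolBp,tolFrac length-match tolerance, see [lengthMatchedSample()].
#' @return A [ResamplingResult-class].
#' @export
runResampling <- function(track, ar, targets, nIter = 10000L, alpha = 0.05,
                          seed = 1L, tolBp = 20, tolFrac = 0.1) {
    if (nIter < 1L) stop("nIter must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    tgt <- mapScores(track, targets, "targets")
    bad <- unmappedIntervals(tgt)
    if (length(bad))
        stop("target interval(s) without scored sites: ",
             paste(bad, collapse = ", "))
    tgtScores <- pooledScores(tgt)
    arMap <- mapScores(track, ar, "AR")
    arScores <- arMap@siteScores

    ## counter-derived substream seeds
    set.seed(as.integer(seed %% .Machine$integer.max))
    subSeeds <- sample.int(.Machine$integer.max - 1L, nIter)

    t <- df <- p <- numeric(nIter)
    for (i in seq_len(nIter)) {
        set.seed(subSeeds[i])
        drawn <- lengthMatchedSample(ar, targets, tolBp, tolFrac)
        pool <- unlist(arScores[drawn], use.names = FALSE)
        if (length(pool) < 2L)
            stop("drawn AR pool has fewer than 2 scored sites")
        w <- welchT(pool, tgtScores)
        t[i] <- w$t; df[i] <- w$df; p[i] <- w$p
    }
    new("ResamplingResult", nIter = as.integer(nIter), alpha = alpha,
        tests = data.frame(t = t, df = df, p = p),
        nSignificant = sum(p < alpha), seed = as.integer(seed))
}
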