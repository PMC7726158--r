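## Strict-molecular-clock Bayesian divergence-time estimation on a fixed
## rooted topology. Likelihood: pruning on the clock tree with branch lengths
## clock_rate x (parent age - child age) x rate multiplier. Prior: Yule
## density on node ages (birth rate sampled under an exponential hyperprior)
## times a real-space-moment lognormal calibration density on one MRCA age.
## Metropolis-Hastings over node ages (+ birth rate), with a whole-tree age
## scaler; step sizes auto-tuned during burn-in.

#' Lognormal parameters from real-space moments
#'
#' Moment inversion: `sigma^2 = ln(1 + (sd/mean)^2)`,
#' `mu = ln(mean) - sigma^2/2`, so the lognormal's real-space mean and sd
#' equal the inputs.
#'
#' @param meanReal real-space mean (> 0).
#' @param sdReal real-space standard deviation (> 0).
#' @return list with `mu` and `sigma`.
#' @examples
#' lognormalFromRealMoments(45.5, 0.5)
#' @export
lognormalFromRealMoments <- function(meanReal, sdReal) {
    if (meanReal <= 0 || sdReal <= 0)
        stop("real-space mean and sd must be positive")
    sigma2 <- log(1 + (sdReal / meanReal)^2)
    list(mu = log(meanReal) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Build a lognormal fossil calibration on an MRCA
#'
#' @param taxa taxon labels whose most recent common ancestor is calibrated.
#' @param meanReal real-space mean age (MY).
#' @param sdReal real-space sd (MY).
#' @return A [CalibrationPrior-class].
#' @export
calibrationPrior <- function(taxa, meanReal, sdReal) {
    ls <- lognormalFromRealMoments(meanReal, sdReal)
    new("CalibrationPrior", taxa = taxa, meanReal = meanReal,
        sdReal = sdReal, mu = ls$mu, sigma = ls$sigma)
}

#' Strict-clock dating configuration
#'
#' @param clockRate substitution rate in substitutions/site/MY (required; the
#'   rate is fixed, as a strict clock demands).
#' @param chainLength MCMC iterations (single-parameter moves); default 1e6.
#' @param burnin burn-in fraction in `[0, 1)`.
#' @param thin keep every `thin`-th post-burn-in state; `NA` picks a value
#'   retaining at most `maxRetained` samples.
#' @param maxRetained cap on retained samples when `thin` is `NA`.
#' @param kappa HKY transition/transversion ratio (fixed).
#' @param sampleBirthRate sample the Yule birth rate (default) or fix it.
#' @param birthRate fixed birth rate when `sampleBirthRate = FALSE`, and the
#'   initial value otherwise (1/MY).
#' @param birthRateHyperRate rate of the exponential hyperprior on the birth
#'   rate (broad default 0.01/MY).
#' @param rateMultiplier optional per-locus rate multiplier on clock branch
#'   lengths (default 1).
#' @param seed integer seed.
#' @return list of validated settings.
#' @export
datingConfig <- function(clockRate, chainLength = 1e6, burnin = 0.1,
                         thin = NA, maxRetained = 10000L, kappa = 2,
                         sampleBirthRate = TRUE, birthRate = 0.05,
                         birthRateHyperRate = 0.01, rateMultiplier = 1,
                         seed = 1L) {
    if (missing(clockRate) || clockRate <= 0)
        stop("clockRate (substitutions/site/MY) must be supplied and positive")
    if (chainLength < 1000) stop("chainLength must be >= 1000")
    if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
    if (kappa <= 0) stop("kappa must be positive")
    if (rateMultiplier <= 0) stop("rateMultiplier must be positive")
    list(clockRate = clockRate, chainLength = as.integer(chainLength),
         burnin = burnin, thin = thin, maxRetained = as.integer(maxRetained),
         kappa = kappa, sampleBirthRate = isTRUE(sampleBirthRate),
         birthRate = birthRate, birthRateHyperRate = birthRateHyperRate,
         rateMultiplier = rateMultiplier, seed = as.integer(seed))
}

## children list per internal node, and parent per node
.topoMaps <- function(tree) {
    nTip <- Ntip(tree)
    nNode <- tree$Nnode
    parent <- integer(nTip + nNode)
    children <- vector("list", nTip + nNode)
    for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        parent[ch] <- pa
        children[[pa]] <- c(children[[pa]], ch)
    }
    nKids <- lengths(children[(nTip + 1L):(nTip + nNode)])
    list(parent = parent, children = children, nTip = nTip, nNode = nNode,
         root = nTip + 1L, nKids = nKids)
}

## Yule log density (up to a constant): (n-1) log(lambda) - lambda * total
## branch duration. Total duration = sum over internal nodes of
## nChildren * age minus the ages of all non-root internal nodes.
.logYule <- function(ages, lambda, tm) {
    dur <- sum(tm$nKids * ages) - sum(ages) + ages[1L]   # index 1 = root
    (tm$nTip - 1) * log(lambda) - lambda * dur
}

#' Run the strict-clock dating MCMC
#'
#' Samples internal node ages (and, by default, the Yule birth rate) of a
#' fixed rooted topology. Supplying a zero-column alignment makes the
#' likelihood constant, which turns the run into prior-only sampling — the
#' mechanism used to check calibration recovery.
#'
#' @param sequences named character vector or `DNAStringSet` of aligned
#'   sequences (equal lengths; length 0 for a prior-only run), names matching
#'   the topology's tip labels.
#' @param topology rooted binary `phylo`; branch lengths are ignored.
#' @param calibration a [CalibrationPrior-class]; its taxa must be
#'   monophyletic in `topology` (their MRCA is the calibrated node).
#' @param config list from [datingConfig()].
#' @return A [DatingResult-class].
#' @export
runClockMCMC <- function(sequences, topology, calibration, config) {
    if (is(sequences, "DNAStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    taxa <- topology$tip.label
    if (length(sequences)) {
        if (!setequal(names(sequences), taxa))
            stop("sequence names must match the topology's tip labels")
        lens <- nchar(sequences)
        if (length(unique(lens)) != 1L)
            stop("sequences must be aligned (equal lengths)")
        sequences <- sequences[taxa]
    }
    nTip <- Ntip(topology)
    tm <- .topoMaps(topology)

    ## calibrated node
    calNode <- if (length(calibration@taxa) == 1L)
        stop("calibration needs >= 2 taxa")
    else if (setequal(calibration@taxa, taxa)) tm$root
    else getMRCA(topology, calibration@taxa)
    desc <- function(nd) {       # tip set under a node
        if (nd <= nTip) return(taxa[nd])
        unlist(lapply(tm$children[[nd]], desc))
    }
    if (!setequal(desc(calNode), calibration@taxa))
        stop("calibration taxa are not monophyletic in the topology")
    calIdx <- calNode - nTip

    ## pattern-compressed data (empirical frequencies, HKY)
    priorOnly <- !length(sequences) || unique(nchar(sequences))[1] == 0L
    if (!priorOnly) {
        mat <- do.call(rbind, strsplit(toupper(sequences), ""))
        rownames(mat) <- taxa
        cc <- .compressColumns(mat)
        obs <- table(factor(mat[mat %in% BASES], levels = BASES))
        piHat <- (as.numeric(obs) + 1) / (sum(obs) + 4)
        model <- substModel("HKY", piHat, kappa = config$kappa)
        po <- reorder.phylo(topology, "postorder")
        perm <- match(po$tip.label, rownames(cc$columns))
        tipsEnc <- .encodeStates(cc$columns)[perm, , drop = FALSE]
        e <- model@eig
        pa <- po$edge[, 1] - nTip
        ch <- po$edge[, 2]
        chInt <- ifelse(ch > nTip, ch - nTip, NA_integer_)
        tipEdge <- ch <= nTip
        rm0 <- config$clockRate * config$rateMultiplier
        piU <- unname(model@pi)
        logLik <- function(ages) {
            aCh <- numeric(length(ch))
            aCh[!tipEdge] <- ages[chInt[!tipEdge]]
            elen <- rm0 * (ages[pa] - aCh)
            ll <- .pruneLogLikCpp(po$edge, nTip, nTip + po$Nnode, elen,
                                  tipsEnc, piU, e$lambda, e$A, e$B, 1.0)
            sum(cc$counts * ll)
        }
    } else {
        logLik <- function(ages) 0
    }

    logPrior <- function(ages, lambda) {
        lp <- .logYule(ages, lambda, tm) +
            dlnorm(ages[calIdx], calibration@mu, calibration@sigma, log = TRUE)
        if (config$sampleBirthRate)
            lp <- lp + log(config$birthRateHyperRate) -
                config$birthRateHyperRate * lambda
        lp
    }

    ## initial state: calibrated node at its prior mean, others spaced by
    ## node depth below the root
    set.seed(config$seed)
    depth <- integer(tm$nNode)        # root = 0, children deeper
    ord <- integer(0)
    stack <- tm$root
    while (length(stack)) {
        nd <- stack[length(stack)]; stack <- stack[-length(stack)]
        ord <- c(ord, nd)
        for (kid in tm$children[[nd]])
            if (kid > nTip) {
                depth[kid - nTip] <- depth[nd - nTip] + 1L
                stack <- c(stack, kid)
            }
    }
    rootAge0 <- calibration@meanReal
    ages <- rootAge0 * (1 - depth / (max(depth) + 1))
    lambda <- config$birthRate

    validAges <- function(ages) {
        for (nd in seq_len(tm$nNode) + nTip) {
            for (ch in tm$children[[nd]]) {
                aCh <- if (ch <= nTip) 0 else ages[ch - nTip]
                if (ages[nd - nTip] <= aCh) return(FALSE)
            }
        }
        all(ages > 0)
    }
    stopifnot(validAges(ages))

    curLL <- logLik(ages)
    lp <- curLL + logPrior(ages, lambda)

    nIter <- config$chainLength
    burnIter <- floor(config$burnin * nIter)
    thin <- config$thin
    if (is.na(thin))
        thin <- max(1L, floor((nIter - burnIter) / config$maxRetained))
    keepIdx <- seq(burnIter + thin, nIter, by = thin)
    kept <- matrix(NA_real_, length(keepIdx), tm$nNode,
                   dimnames = list(NULL, as.character(seq_len(tm$nNode) + nTip)))
    keptLambda <- numeric(length(keepIdx))
    keptLp <- numeric(length(keepIdx))
    kPtr <- 0L

    ## operators: 1 root slide, 2 internal slide, 3 tree scale, 4 lambda walk
    nOps <- if (config$sampleBirthRate) 4L else 3L
    acc <- att <- numeric(4)
    stepRoot <- calibration@sdReal * 2
    stepScale <- 0.1
    stepLambda <- 0.5
    internals <- setdiff(seq_len(tm$nNode) + nTip, tm$root)

    childMax <- function(ages, nd) {
        mx <- 0
        for (ch in tm$children[[nd]])
            mx <- max(mx, if (ch <= nTip) 0 else ages[ch - nTip])
        mx
    }

    for (it in seq_len(nIter)) {
        op <- sample.int(nOps, 1L)
        if (op == 1L) {                      # root age random walk
            att[1] <- att[1] + 1
            prop <- ages
            prop[tm$root - nTip] <- ages[tm$root - nTip] +
                rnorm(1, 0, stepRoot)
            if (prop[tm$root - nTip] > childMax(ages, tm$root)) {
                llNew <- logLik(prop)
                lpNew <- llNew + logPrior(prop, lambda)
                if (log(runif(1)) < lpNew - lp) {
                    ages <- prop; lp <- lpNew; curLL <- llNew
                    acc[1] <- acc[1] + 1
                }
            }
        } else if (op == 2L && length(internals)) {  # internal uniform slide
            att[2] <- att[2] + 1
            nd <- if (length(internals) == 1L) internals
                  else internals[sample.int(length(internals), 1L)]
            lo <- childMax(ages, nd)
            hi <- ages[tm$parent[nd] - nTip]
            prop <- ages
            prop[nd - nTip] <- runif(1, lo, hi)   # symmetric: bounds unchanged
            llNew <- logLik(prop)
            lpNew <- llNew + logPrior(prop, lambda)
            if (log(runif(1)) < lpNew - lp) {
                ages <- prop; lp <- lpNew; curLL <- llNew
                acc[2] <- acc[2] + 1
            }
        } else if (op == 3L) {               # whole-tree age scale
            att[3] <- att[3] + 1
            s <- exp(runif(1, -stepScale, stepScale))
            prop <- ages * s
            llNew <- logLik(prop)
            lpNew <- llNew + logPrior(prop, lambda)
            ## Jacobian of scaling all nNode ages
            if (log(runif(1)) < lpNew - lp + tm$nNode * log(s)) {
                ages <- prop; lp <- lpNew; curLL <- llNew
                acc[3] <- acc[3] + 1
            }
        } else {                             # lambda log walk; likelihood
            att[4] <- att[4] + 1             # does not depend on lambda
            lNew <- lambda * exp(rnorm(1, 0, stepLambda))
            lpNew <- curLL + logPrior(ages, lNew)
            if (log(runif(1)) < lpNew - lp + log(lNew) - log(lambda)) {
                lambda <- lNew; lp <- lpNew; acc[4] <- acc[4] + 1
            }
        }
        ## crude step-size tuning during burn-in
        if (it <= burnIter && it %% 500L == 0L) {
            if (att[1] > 0) {
                r <- acc[1] / att[1]
                stepRoot <- stepRoot * if (r > 0.4) 1.3 else if (r < 0.2) 0.7 else 1
            }
            if (att[3] > 0) {
                r <- acc[3] / att[3]
                stepScale <- stepScale * if (r > 0.4) 1.3 else if (r < 0.2) 0.7 else 1
            }
            acc[] <- 0; att[] <- 0
        }
        if (kPtr < length(keepIdx) && it == keepIdx[kPtr + 1L]) {
            kPtr <- kPtr + 1L
            kept[kPtr, ] <- ages
            keptLambda[kPtr] <- lambda
            keptLp[kPtr] <- lp
        }
    }
    rates <- ifelse(att > 0, acc / att, NA_real_)
    names(rates) <- c("rootSlide", "nodeSlide", "treeScale", "lambdaWalk")
    new("DatingResult", ages = kept, lambda = keptLambda, logPost = keptLp,
        acceptance = rates[seq_len(nOps)], topology = topology,
        config = config)
}

#' Posterior summary of the tMRCA of a taxon pair
#'
#' @param result a [DatingResult-class].
#' @param taxa character vector of two (or more) taxon labels.
#' @return list with `mean`, `median`, `ci` (95% credible interval) and the
#'   raw `samples`.
#' @export
tmrca <- function(result, taxa) {
    topo <- result@topology
    if (!all(taxa %in% topo$tip.label))
        stop("unknown taxa: ",
             paste(setdiff(taxa, topo$tip.label), collapse = ", "))
    node <- if (setequal(taxa, topo$tip.label)) Ntip(topo) + 1L
            else getMRCA(topo, taxa)
    samples <- result@ages[, as.character(node)]
    list(mean = mean(samples), median = median(samples),
         ci = unname(quantile(samples, c(0.025, 0.975))),
         samples = samples)
}
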