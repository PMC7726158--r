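## Reversible nucleotide substitution models (REV/GTR and HKY85).
##
## Base order is (A, C, G, T) everywhere. Q is built from exchangeabilities
## and stationary frequencies, normalized so -sum(pi * diag(Q)) == 1, and
## diagonalized through the symmetrized matrix diag(sqrt(pi)) Q diag(1/sqrt(pi))
## whose spectrum is real for any reversible model.

BASES <- c("A", "C", "G", "T")

## order of the 6 exchangeabilities: AC, AG, AT, CG, CT, GT
.pairIdx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

.buildQ <- function(pi, rates) {
    Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    for (k in seq_len(6)) {
        i <- .pairIdx[k, 1]; j <- .pairIdx[k, 2]
        Q[i, j] <- rates[k] * pi[j]
        Q[j, i] <- rates[k] * pi[i]
    }
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))          # expected substitutions per unit time
    Q / mu
}

.eigQ <- function(pi, Q) {
    d <- sqrt(pi)
    S <- diag(d) %*% Q %*% diag(1 / d)
    S <- (S + t(S)) / 2               # kill round-off asymmetry
    e <- eigen(S, symmetric = TRUE)
    ## the spectrum of a reversible generator is <= 0 with 0 attained at the
    ## stationary vector; round-off can leave tiny positive values that blow
    ## up exp(lambda * t) at large t, so clamp
    e$values <- pmin(e$values, 0)
    list(lambda = e$values,
         A = diag(1 / d) %*% e$vectors,
         B = t(e$vectors) %*% diag(d))
}

#' Build a reversible substitution model
#'
#' Constructs a REV (general time-reversible) or HKY85 model from stationary
#' frequencies and either six exchangeabilities or a transition/transversion
#' ratio. The rate matrix is normalized to one expected substitution per site
#' per unit branch length. HKY with `kappa = 1` collapses to F81, and with
#' uniform frequencies to Jukes-Cantor.
#'
#' @param kind `"REV"` or `"HKY"`.
#' @param pi stationary base frequencies in order (A, C, G, T); rescaled to
#'   sum to 1.
#' @param rates for REV: six positive exchangeabilities in order
#'   (AC, AG, AT, CG, CT, GT).
#' @param kappa for HKY: transition/transversion ratio (> 0).
#' @return A [SubstModel-class].
#' @examples
#' jc <- substModel("HKY", pi = rep(0.25, 4), kappa = 1)
#' transitionMatrix(jc, 0.1)
#' @export
substModel <- function(kind = c("REV", "HKY"), pi, rates = NULL,
                       kappa = NULL) {
    kind <- match.arg(kind)
    if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0))
        stop("pi must be 4 positive frequencies")
    pi <- pi / sum(pi)
    if (kind == "REV") {
        if (is.null(rates) || length(rates) != 6L || any(rates <= 0))
            stop("REV needs 6 positive exchangeabilities")
        kappa <- NA_real_
    } else {
        if (is.null(kappa) || length(kappa) != 1L || kappa <= 0)
            stop("HKY needs a positive kappa")
        ## transitions: A<->G (pair 2) and C<->T (pair 5)
        rates <- c(1, kappa, 1, 1, kappa, 1)
    }
    Q <- .buildQ(pi, rates)
    new("SubstModel", kind = kind, pi = setNames(pi, BASES),
        rates = setNames(rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
        kappa = as.numeric(kappa), Q = Q, eig = .eigQ(pi, Q))
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed from the model's symmetric eigendecomposition.
#'
#' @param model a [SubstModel-class].
#' @param t branch length (expected substitutions/site), finite and >= 0.
#' @return 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
transitionMatrix <- function(model, t) {
    if (length(t) != 1L || !is.finite(t) || t < 0)
        stop("t must be a single finite value >= 0")
    e <- model@eig
    P <- e$A %*% (exp(e$lambda * t) * e$B)
    P[P < 0] <- 0
    dimnames(P) <- list(BASES, BASES)
    P
}

## ---------------------------------------------------------------------------
## Plain-text serialization (key-value file) for NeutralModel
## ---------------------------------------------------------------------------

#' Write a neutral model to a key-value text file
#'
#' Human-readable serialization: model kind, frequencies, parameters and the
#' tree in newick (branch lengths in substitutions/site).
#'
#' @param nm a [NeutralModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNeutralModel <- function(nm, path) {
    m <- nm@model
    lines <- c(
        paste("kind:", m@kind),
        paste("pi:", paste(format(m@pi, digits = 17), collapse = " ")),
        if (m@kind == "REV")
            paste("rates:", paste(format(m@rates, digits = 17),
                                  collapse = " "))
        else paste("kappa:", format(m@kappa, digits = 17)),
        paste("nsites:", nm@nSitesFit),
        paste("loglik:", format(nm@logLik, digits = 17)),
        paste("tree:", ape::write.tree(nm@tree)))
    writeLines(lines, path)
    invisible(path)
}

#' Read a neutral model written by [writeNeutralModel()]
#'
#' @param path file path.
#' @return A [NeutralModel-class].
#' @export
readNeutralModel <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, ": ", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    val <- function(k) kv[[match(k, keys)]][2L]
    kind <- val("kind")
    pi <- as.numeric(strsplit(val("pi"), " +")[[1]])
    tree <- ape::read.tree(text = val("tree"))
    model <- if (kind == "REV")
        substModel("REV", pi,
                   rates = as.numeric(strsplit(val("rates"), " +")[[1]]))
    else substModel("HKY", pi, kappa = as.numeric(val("kappa")))
    new("NeutralModel", tree = tree, model = model,
        nSitesFit = as.integer(val("nsites")),
        logLik = as.numeric(val("loglik")))
}
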