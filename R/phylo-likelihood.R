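## Felsenstein-pruning likelihood of alignment columns. The hot loop lives in
## src/phylo.cpp; this file owns tree/state preparation and the R interface.

## Encode A,C,G,T -> 1..4; gaps, N and anything else -> 0 (missing).
.encodeStates <- function(x) {
    x <- toupper(x)
    m <- match(x, BASES)
    m[is.na(m)] <- 0L
    out <- matrix(as.integer(m), nrow = NROW(x))
    rownames(out) <- rownames(x)
    out
}

## Postorder pieces the C++ kernel needs, with tip rows aligned to `taxa`.
.treeData <- function(tree, taxa) {
    if (is.null(tree$edge.length))
        stop("tree must carry branch lengths")
    if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length)))
        stop("branch lengths must be finite and >= 0")
    po <- reorder.phylo(tree, "postorder")
    perm <- match(po$tip.label, taxa)
    if (anyNA(perm))
        stop("taxa missing from column data: ",
             paste(po$tip.label[is.na(perm)], collapse = ", "))
    list(edge = po$edge, elen = po$edge.length, nTip = Ntip(po),
         nNodeTotal = Ntip(po) + po$Nnode, perm = perm)
}

.columnMatrix <- function(columns) {
    if (is.null(dim(columns)))
        columns <- matrix(columns, ncol = 1L,
                          dimnames = list(names(columns), NULL))
    if (is.null(rownames(columns)))
        stop("columns must have taxon rownames")
    columns
}

#' Log-likelihood of alignment columns under a substitution model
#'
#' Exact pruning computation of `log P(column | tree, model)` with every
#' branch length multiplied by `scale`. Missing states (`-`, `N`) are
#' marginalized. `scale = 0` is the analytic no-substitution limit.
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param model a [SubstModel-class].
#' @param columns character matrix (taxa x sites, rownames = taxon labels)
#'   or a single named character vector for one column.
#' @param scale rate multiplier applied to all branches (>= 0).
#' @return numeric vector of per-column log-likelihoods.
#' @examples
#' jc <- substModel("HKY", rep(0.25, 4), kappa = 1)
#' tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
#' columnLogLik(tr, jc, c(a = "A", b = "A"))
#' @export
columnLogLik <- function(tree, model, columns, scale = 1) {
    if (length(scale) != 1L || !is.finite(scale) || scale < 0)
        stop("scale must be a single finite value >= 0")
    columns <- .columnMatrix(columns)
    td <- .treeData(tree, rownames(columns))
    tips <- .encodeStates(columns)[td$perm, , drop = FALSE]
    e <- model@eig
    .pruneLogLikCpp(td$edge, td$nTip, td$nNodeTotal, td$elen, tips,
                    unname(model@pi), e$lambda, e$A, e$B, scale)
}

#' Total log-likelihood over independent columns
#'
#' Sum of [columnLogLik()] over the supplied columns, optionally weighted by
#' per-column counts (pattern compression).
#'
#' @inheritParams columnLogLik
#' @param counts optional per-column multiplicities.
#' @return a single log-likelihood.
#' @export
totalLogLik <- function(tree, model, columns, scale = 1, counts = NULL) {
    columns <- .columnMatrix(columns)
    if (ncol(columns) == 0L)
        stop("columns must be non-empty")
    ll <- columnLogLik(tree, model, columns, scale)
    if (is.null(counts)) sum(ll) else sum(counts * ll)
}

## Collapse duplicate columns into unique patterns with counts.
.compressColumns <- function(columns) {
    key <- apply(columns, 2L, paste, collapse = "")
    tab <- table(key)
    idx <- match(names(tab), key)
    list(columns = columns[, idx, drop = FALSE],
         counts = as.numeric(tab))
}
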