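## MAF 1.0 reading, writing, filtering and sorting.

#' Read a MAF file
#'
#' Parses MAF 1.0 (`##maf` header, `a`/`s` lines) into a list of
#' [MafBlock-class] objects. Coordinates are kept exactly as stored
#' (0-based, strand-relative). Lines other than `a`/`s`/comments (e.g. `i`,
#' `q`, `e`) are ignored.
#'
#' @param path MAF file path.
#' @return list of [MafBlock-class].
#' @export
readMaf <- function(path) {
    lines <- readLines(path)
    blocks <- list()
    cur <- NULL
    flush <- function(cur, blocks) {
        if (!is.null(cur) && length(cur$src))
            blocks[[length(blocks) + 1L]] <-
                mafBlock(cur$src, cur$start, cur$size, cur$strand,
                         cur$srcSize, cur$text)
        blocks
    }
    for (ln in seq_along(lines)) {
        line <- lines[ln]
        if (!nzchar(line) || startsWith(line, "#")) next
        tag <- substr(line, 1L, 1L)
        if (tag == "a") {
            blocks <- flush(cur, blocks)
            cur <- list(src = character(), start = numeric(),
                        size = numeric(), strand = character(),
                        srcSize = numeric(), text = character())
        } else if (tag == "s") {
            f <- strsplit(trimws(line), "[ \t]+")[[1]]
            if (length(f) != 7L)
                stop(sprintf("malformed 's' line at line %d: expected 7 fields, got %d",
                             ln, length(f)))
            if (is.null(cur))
                stop(sprintf("'s' line outside any block at line %d", ln))
            cur$src <- c(cur$src, f[2])
            cur$start <- c(cur$start, as.numeric(f[3]))
            cur$size <- c(cur$size, as.numeric(f[4]))
            cur$strand <- c(cur$strand, f[5])
            cur$srcSize <- c(cur$srcSize, as.numeric(f[6]))
            cur$text <- c(cur$text, f[7])
        }
        ## other line types ignored
    }
    flush(cur, blocks)
}

#' Write MAF blocks to a file
#'
#' @param blocks list of [MafBlock-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(blocks, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##maf version=1 scoring=none", con)
    writeLines("", con)
    for (b in blocks) {
        writeLines("a score=0", con)
        writeLines(sprintf("s %s %d %d %s %d %s", b@src, as.integer(b@start),
                           as.integer(b@size), b@strand,
                           as.integer(b@srcSize), b@text), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Filter MAF blocks by row count and strip gap-only columns
#'
#' Drops blocks with fewer than `minRows` rows, then deletes columns in which
#' every remaining row has a gap. Row sizes are unchanged by construction
#' (gap-only columns carry no residues).
#'
#' @param blocks list of [MafBlock-class].
#' @param minRows minimum rows a block must have (pipeline default 5).
#' @return filtered list of [MafBlock-class] (possibly empty).
#' @export
filterMaf <- function(blocks, minRows = 5L) {
    if (minRows < 1L) stop("minRows must be >= 1")
    kept <- Filter(function(b) blockRows(b) >= minRows, blocks)
    lapply(kept, function(b) {
        chars <- .blockCharMatrix(b)
        gapOnly <- colSums(chars != "-") == 0L
        if (!any(gapOnly)) return(b)
        chars <- chars[, !gapOnly, drop = FALSE]
        txt <- apply(chars, 1L, paste, collapse = "")
        mafBlock(b@src, b@start, b@size, b@strand, b@srcSize, txt)
    })
}

## rows x columns character matrix of a block's texts
.blockCharMatrix <- function(b) {
    matrix(unlist(strsplit(b@text, ""), use.names = FALSE),
           nrow = blockRows(b), byrow = TRUE)
}

#' Sort MAF blocks by reference position
#'
#' Stable sort by (reference chromosome, reference forward-strand start),
#' chromosomes ordered lexicographically.
#'
#' @param blocks list of [MafBlock-class].
#' @param refSpecies reference species id; every block must contain it.
#' @return sorted list of [MafBlock-class].
#' @export
sortMaf <- function(blocks, refSpecies) {
    idx <- vapply(blocks, function(b) {
        i <- match(refSpecies, blockSpecies(b))
        if (is.na(i)) NA_integer_ else i
    }, integer(1))
    if (anyNA(idx))
        stop("block(s) ", paste(which(is.na(idx)), collapse = ", "),
             " lack reference species '", refSpecies, "'")
    chrom <- mapply(function(b, i) blockChrom(b)[i], blocks, idx)
    fstart <- mapply(function(b, i) forwardStart(b, i), blocks, idx)
    blocks[order(chrom, fstart)]   # order() is stable
}

#' Reference row index of a block
#'
#' @param block a [MafBlock-class].
#' @param refSpecies reference species id.
#' @return integer row index (first match), or error if absent.
#' @export
referenceRow <- function(block, refSpecies) {
    i <- match(refSpecies, blockSpecies(block))
    if (is.na(i))
        stop("block lacks reference species '", refSpecies, "'")
    i
}
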