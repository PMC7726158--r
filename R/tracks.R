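## Genome-track plumbing: fixedStep WIG writing, WIG -> BED conversion,
## BED feature IO, interval complement and fractional-overlap intersection.
## In memory everything is GRanges (1-based closed, Bioconductor convention);
## BED and WIG conventions are applied at the file boundary only.

#' Write a score track as fixedStep WIG
#'
#' One `fixedStep` stanza (step 1) per run of consecutive scored positions;
#' unscored positions fall between stanzas and are never written as
#' placeholders.
#'
#' @param track a [ScoreTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWig <- function(track, path) {
    gr <- trackSites(track)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("track type=wiggle_0 name=conacc", con)
    if (length(gr) == 0L) return(invisible(path))
    key <- paste(as.character(seqnames(gr)), start(gr))
    if (anyDuplicated(key))
        stop("duplicate scored positions in track")
    for (chr in unique(as.character(seqnames(gr)))) {
        g <- gr[as.character(seqnames(gr)) == chr]
        pos <- start(g)                      # 1-based, WIG convention
        sc <- mcols(g)$score
        run <- cumsum(c(1L, diff(pos) != 1L))
        for (r in split(seq_along(pos), run)) {
            writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                               chr, pos[r[1L]]), con)
            writeLines(format(sc[r], digits = 9, trim = TRUE,
                              scientific = FALSE), con)
        }
    }
    invisible(path)
}

#' Convert a fixedStep WIG file to per-site BED-style records
#'
#' Each scored site becomes a width-1 interval; the BED (0-based half-open)
#' start of a record is the WIG position minus 1; the returned `GRanges` uses
#' the 1-based convention, so `start(gr) - 1` is the BED start.
#'
#' @param path fixedStep WIG file (step must be 1).
#' @return width-1 `GRanges` with a `score` metadata column, in file order.
#' @export
wigToBed <- function(path) {
    lines <- trimws(readLines(path))
    keep <- nzchar(lines) & !startsWith(lines, "track") &
        !startsWith(lines, "#")
    lineNo <- which(keep)
    lines <- lines[keep]
    if (any(startsWith(lines, "variableStep")))
        stop("variableStep WIG is not supported (fixedStep only)")
    isHead <- startsWith(lines, "fixedStep")
    if (length(lines) && !isHead[1L] && any(!isHead))
        stop(sprintf("score value before any fixedStep header (line %d)",
                     lineNo[1L]))
    stanza <- cumsum(isHead)
    parseHead <- function(h) {
        kv <- strsplit(strsplit(h, "[ \t]+")[[1]][-1], "=", fixed = TRUE)
        keys <- vapply(kv, `[`, "", 1L)
        vals <- vapply(kv, `[`, "", 2L)
        step <- if ("step" %in% keys) as.integer(vals[keys == "step"]) else 1L
        if (step != 1L) stop("only step=1 fixedStep WIG is supported")
        list(chrom = vals[keys == "chrom"],
             start = as.integer(vals[keys == "start"]))
    }
    heads <- lapply(lines[isHead], parseHead)
    vals <- suppressWarnings(as.numeric(lines[!isHead]))
    if (anyNA(vals) || any(!is.finite(vals)))
        stop(sprintf("non-finite score at line %d",
                     lineNo[!isHead][which(!is.finite(vals))[1L]]))
    nPer <- tabulate(stanza[!isHead], nbins = sum(isHead))
    chrom <- rep(vapply(heads, `[[`, "", "chrom"), nPer)
    pos <- unlist(lapply(seq_along(heads), function(i)
        heads[[i]]$start + seq_len(nPer[i]) - 1L), use.names = FALSE)
    gr <- GRanges(chrom, IRanges(start = pos, width = 1L))
    mcols(gr)$score <- vals
    gr
}

#' Read features from a BED file
#'
#' Thin wrapper over `rtracklayer::import` that returns a sorted `GRanges`
#' (BED 0-based half-open converted to the 1-based closed convention).
#'
#' @param path BED3/BED6 file.
#' @param label optional feature-class label stored in `mcols()$label`.
#' @return sorted `GRanges`.
#' @export
readFeatureBed <- function(path, label = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    gr <- sort(gr, ignore.strand = TRUE)
    if (!is.null(label)) mcols(gr)$label <- label
    gr
}

#' Write features to a BED file
#'
#' @param gr a `GRanges`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeFeatureBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    d <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    stringsAsFactors = FALSE)
    setNames(as.numeric(d$length), d$chrom)
}

#' Complement of a feature set within chromosome bounds
#'
#' Overlapping inputs are merged first ("not annotated" means the complement
#' of the union); per chromosome the result is the set complement within
#' `[1, length]`, so the union of input and output tiles every chromosome.
#'
#' @param gr feature intervals (`GRanges`).
#' @param chromSizes named vector of chromosome lengths; must cover every
#'   chromosome in `gr`.
#' @return sorted, disjoint `GRanges` of unannotated intervals.
#' @export
complementIntervals <- function(gr, chromSizes) {
    chrs <- unique(as.character(seqnames(gr)))
    miss <- setdiff(chrs, names(chromSizes))
    if (length(miss))
        stop("chromSizes lacks: ", paste(miss, collapse = ", "))
    merged <- reduce(gr, ignore.strand = TRUE)
    for (chr in chrs) {
        mx <- max(end(merged[as.character(seqnames(merged)) == chr]))
        if (mx > chromSizes[chr])
            stop(sprintf("interval end %d exceeds length of %s (%d)",
                         mx, chr, as.integer(chromSizes[chr])))
    }
    whole <- GRanges(names(chromSizes),
                     IRanges(1L, as.integer(chromSizes)))
    out <- GenomicRanges::setdiff(whole, merged, ignore.strand = TRUE)
    sort(out[as.character(seqnames(out)) %in% names(chromSizes)])
}

#' Keep intervals of `a` covered by `b` at a minimum overlap fraction
#'
#' Returns the intervals of `a` whose total overlap with the union of `b`
#' is at least `minFrac` of their own length (the ancestral-repeat rule:
#' repeat-masked intervals retained when >= 80% covered by the conserved
#' alignment track).
#'
#' @param a candidate intervals (`GRanges`).
#' @param b covering intervals (`GRanges`).
#' @param minFrac minimum covered fraction of each `a` interval, in (0, 1].
#' @return the retained subset of `a`.
#' @export
intersectMinOverlap <- function(a, b, minFrac = 0.8) {
    if (minFrac <= 0 || minFrac > 1)
        stop("minFrac must be in (0, 1]")
    bm <- reduce(b, ignore.strand = TRUE)
    hits <- findOverlaps(a, bm, ignore.strand = TRUE)
    ov <- width(pintersect(a[queryHits(hits)], bm[subjectHits(hits)],
                           ignore.strand = TRUE))
    cov <- rep(0, length(a))
    agg <- tapply(ov, queryHits(hits), sum)
    cov[as.integer(names(agg))] <- agg
    a[cov >= minFrac * width(a) - 1e-9]
}
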