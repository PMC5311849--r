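#' Stream a SNPTEST v2 GEN file in chunks
#'
#' Each GEN line carries 5 leading fields (snp id, rs id, position,
#' allele A, allele B) followed by 3 probabilities per individual.  The
#' file is read in bounded chunks so that memory scales with the chunk
#' size and the number of individuals, never with the file length; the
#' genome-wide driver [runBurdenScan()] relies on this.
#'
#' @param path path to the GEN file.
#' @param nIndividuals number of individuals expected (from the paired
#'   sample file); enforced on every line.
#' @param callback function called once per chunk with a list holding
#'   `snpID`, `rsID`, `position`, `alleleA`, `alleleB`, the probability
#'   matrices `pAA`, `pAB`, `pBB` (variants x individuals) and `line`
#'   (1-based line numbers).  A callback returning `FALSE` stops reading.
#' @param chunkSize lines per chunk.
#' @return invisibly, the number of variant lines read.
#' @export
readGenChunks <- function(path, nIndividuals, callback, chunkSize = 2000L) {
    if (!file.exists(path)) stopData("GEN file not found: ", path)
    nf <- 5L + 3L * nIndividuals
    con <- file(path, open = "r")
    on.exit(close(con))
    lineNo <- 0L
    total <- 0L
    repeat {
        lines <- readLines(con, n = chunkSize)
        if (!length(lines)) break
        keep <- nzchar(trimws(lines))
        lns <- lineNo + seq_along(lines)
        lineNo <- lineNo + length(lines)
        lines <- lines[keep]; lns <- lns[keep]
        if (!length(lines)) next
        sp <- strsplit(trimws(lines), "[ \t]+")
        bad <- which(lengths(sp) != nf)
        if (length(bad)) {
            got <- lengths(sp)[bad[1]]
            stopData("GEN file line ", lns[bad[1]], ": expected ", nf,
                     " fields, got ", got, " (sample file has ",
                     nIndividuals, " individuals; this line carries ",
                     "probabilities for ", max(0L, (got - 5L)) %/% 3L, ")")
        }
        m <- matrix(unlist(sp), nrow = length(sp), byrow = TRUE)
        pos <- suppressWarnings(as.integer(m[, 3]))
        if (anyNA(pos))
            stopData("GEN file line ", lns[which(is.na(pos))[1]],
                     ": non-integer position '", m[which(is.na(pos))[1], 3],
                     "'")
        probs <- suppressWarnings(
            matrix(as.numeric(m[, -(1:5), drop = FALSE]), nrow = nrow(m)))
        if (anyNA(probs)) {
            i <- which(rowSums(is.na(probs)) > 0)[1]
            stopData("GEN file line ", lns[i], ": non-numeric probability")
        }
        if (any(probs < -1e-9 | probs > 1 + 1e-9)) {
            i <- which(rowSums(probs < -1e-9 | probs > 1 + 1e-9) > 0)[1]
            stopData("GEN file line ", lns[i],
                     ": genotype probability outside [0, 1]")
        }
        idx <- 3L * (seq_len(nIndividuals) - 1L)
        pAA <- probs[, idx + 1L, drop = FALSE]
        pAB <- probs[, idx + 2L, drop = FALSE]
        pBB <- probs[, idx + 3L, drop = FALSE]
        s <- pAA + pAB + pBB
        if (any(s > 1.02)) {
            i <- which(rowSums(s > 1.02) > 0)[1]
            stopData("GEN file line ", lns[i], ": genotype probabilities sum",
                     " to more than 1.02 (corrupt triplet)")
        }
        total <- total + nrow(m)
        res <- callback(list(snpID = m[, 1], rsID = m[, 2], position = pos,
                             alleleA = m[, 4], alleleB = m[, 5],
                             pAA = pAA, pAB = pAB, pBB = pBB, line = lns))
        if (identical(res, FALSE)) break
    }
    invisible(total)
}

#' Read a whole SNPTEST v2 GEN file
#'
#' Convenience loader over [readGenChunks()]; suitable for region-sized
#' files (the genome-wide driver streams instead).
#'
#' @inheritParams readGenChunks
#' @param sampleIDs optional individual identifiers for the columns.
#' @return a [GenotypeProbs-class] with variants in file order.
#' @export
readGenFile <- function(path, nIndividuals, sampleIDs = NULL) {
    acc <- new.env(parent = emptyenv())
    acc$chunks <- list()
    readGenChunks(path, nIndividuals, function(ch) {
        acc$chunks[[length(acc$chunks) + 1L]] <- ch
        TRUE
    })
    ch <- acc$chunks
    if (!length(ch))
        return(GenotypeProbs(matrix(0, 0, nIndividuals),
                             matrix(0, 0, nIndividuals),
                             matrix(0, 0, nIndividuals),
                             character(0), character(0), integer(0),
                             character(0), character(0),
                             sampleIDs = sampleIDs))
    GenotypeProbs(
        pAA = do.call(rbind, lapply(ch, `[[`, "pAA")),
        pAB = do.call(rbind, lapply(ch, `[[`, "pAB")),
        pBB = do.call(rbind, lapply(ch, `[[`, "pBB")),
        snpID = unlist(lapply(ch, `[[`, "snpID")),
        rsID = unlist(lapply(ch, `[[`, "rsID")),
        position = unlist(lapply(ch, `[[`, "position")),
        alleleA = unlist(lapply(ch, `[[`, "alleleA")),
        alleleB = unlist(lapply(ch, `[[`, "alleleB")),
        sampleIDs = sampleIDs)
}

#' Read a genomic-region file
#'
#' Whitespace-delimited, three columns (region name, start, end) or four
#' (leading chromosome).  Coordinates are 1-based and inclusive on both
#' ends; a variant belongs to a region iff start <= position <= end.
#' Overlapping regions are legal and a variant may enter several regions.
#'
#' @param path path to the region file.
#' @return a [GenomicRanges::GRanges] in file order, names = region
#'   names; seqnames are `"unknown"` for the 3-column dialect.
#' @export
readRegionFile <- function(path) {
    if (!file.exists(path)) stopData("region file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sp <- strsplit(trimws(lines), "[ \t]+")
    lens <- lengths(sp)
    if (length(sp) && !all(lens %in% c(3L, 4L)))
        stopData("region file line ", which(!lens %in% c(3L, 4L))[1],
                 ": expected 3 columns (name start end) or 4 (chrom first)")
    if (length(sp) && length(unique(lens)) > 1)
        stopData("region file mixes 3- and 4-column rows")
    hasChrom <- length(sp) && lens[1] == 4L
    nm <- vapply(sp, function(f) f[1 + hasChrom], "")
    chrom <- if (hasChrom) vapply(sp, `[[`, "", 1) else
        rep("unknown", length(sp))
    startTok <- vapply(sp, function(f) f[2 + hasChrom], "")
    endTok <- vapply(sp, function(f) f[3 + hasChrom], "")
    start <- suppressWarnings(as.integer(startTok))
    end <- suppressWarnings(as.integer(endTok))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stopData("region file line ", bad[1], ": non-integer position in '",
                 paste(sp[[bad[1]]], collapse = " "), "'")
    rev <- which(start > end)
    if (length(rev))
        stopData("region '", nm[rev[1]], "': start (", start[rev[1]],
                 ") exceeds end (", end[rev[1]], ")")
    if (any(!nzchar(nm)))
        stopData("region file line ", which(!nzchar(nm))[1],
                 ": empty region name")
    gr <- GRanges(seqnames = chrom, ranges = IRanges(start = start, end = end))
    names(gr) <- nm
    gr
}

#' Read a plain-text identifier list
#'
#' One identifier per line; blank lines ignored; duplicates collapse.
#'
#' @param path path to the list file.
#' @return a character vector of unique identifiers (empty file gives an
#'   empty, no-op filter).
#' @export
readIDList <- function(path) {
    if (!file.exists(path)) stopData("ID list not found: ", path)
    ids <- trimws(readLines(path))
    unique(ids[nzchar(ids)])
}
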