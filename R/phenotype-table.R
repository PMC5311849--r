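#' Construct a PhenotypeTable
#'
#' @param data a data.frame or DataFrame of numeric columns, one row per
#'   individual, with row names giving the individual identifiers.
#' @param colTypes character vector of SNPTEST type codes
#'   (`0`, `D`, `C`, `P`, `B`), one per column.
#' @return a [PhenotypeTable-class] object.
#' @examples
#' pt <- PhenotypeTable(
#'     data.frame(missing = c(0, 0), tg = c(1.2, -0.4),
#'                row.names = c("id1", "id2")),
#'     colTypes = c("0", "P"))
#' sampleIDs(pt)
#' @export
PhenotypeTable <- function(data, colTypes) {
    df <- S4Vectors::DataFrame(data, check.names = FALSE)
    rownames(df) <- rownames(data)
    new("PhenotypeTable", data = df, colTypes = as.character(colTypes))
}

#' @rdname PhenotypeTable-class
#' @export
setMethod("sampleIDs", "PhenotypeTable", function(x) rownames(x@data))

#' @rdname PhenotypeTable-class
#' @export
setMethod("colTypes", "PhenotypeTable", function(x) {
    structure(x@colTypes, names = colnames(x@data))
})

#' @rdname PhenotypeTable-class
#' @param columns optional character vector of column names to extract.
#' @export
setMethod("phenoValues", "PhenotypeTable", function(x, columns = NULL) {
    if (is.null(columns)) columns <- colnames(x@data)
    missing <- setdiff(columns, colnames(x@data))
    if (length(missing))
        stopUsage("phenotype(s) not present in sample file: ",
                  paste(missing, collapse = ", "))
    m <- as.matrix(as.data.frame(x@data[, columns, drop = FALSE]))
    rownames(m) <- rownames(x@data)
    m
})

#' @rdname PhenotypeTable-class
#' @export
setMethod("length", "PhenotypeTable", function(x) nrow(x@data))

#' @rdname PhenotypeTable-class
#' @param i index (logical, integer or character) over individuals.
#' @export
setMethod("[", "PhenotypeTable", function(x, i) {
    initialize(x, data = x@data[i, , drop = FALSE], colTypes = x@colTypes)
})

setMethod("show", "PhenotypeTable", function(object) {
    cat("PhenotypeTable with", nrow(object@data), "individuals and",
        ncol(object@data), "columns\n")
    tp <- colTypes(object)
    cat("  columns:", paste0(names(tp), " (", tp, ")", collapse = ", "), "\n")
    nmiss <- sum(is.na(as.matrix(as.data.frame(object@data))))
    cat("  missing values:", nmiss, "\n")
})

#' Read a SNPTEST v2 sample file
#'
#' The first line is a header of column names, the second the SNPTEST type
#' row (`0` for identifier/metadata columns, `D`/`C` for discrete and
#' continuous covariates, `P`/`B` for continuous and binary phenotypes),
#' and each subsequent line one individual.  The first column is taken as
#' the individual identifier; the literal token `NA` marks a missing
#' value.  The conventional `missing` column is kept as metadata only and
#' never used as a filter.
#'
#' @param path path to the sample file.
#' @return a [PhenotypeTable-class]; row order is the authoritative
#'   individual order for the paired GEN file.
#' @export
readSampleFile <- function(path) {
    if (!file.exists(path)) stopData("sample file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2)
        stopData("sample file must have a header line and a type row: ", path)
    header <- .splitWS(lines[1])
    types <- .splitWS(lines[2])
    if (length(types) != length(header))
        stopData("sample file line 2: type row has ", length(types),
                 " entries for ", length(header), " columns")
    bad <- setdiff(types, .PHENO_TYPE_CODES)
    if (length(bad))
        stopData("sample file line 2: invalid type code '", bad[1],
                 "' (expected one of ",
                 paste(.PHENO_TYPE_CODES, collapse = ", "), ")")
    n <- length(lines) - 2L
    cells <- matrix(NA_character_, nrow = n, ncol = length(header))
    for (i in seq_len(n)) {
        f <- .splitWS(lines[i + 2L])
        if (length(f) != length(header))
            stopData("sample file row ", i, ": expected ", length(header),
                     " fields, got ", length(f))
        cells[i, ] <- f
    }
    ids <- cells[, 1]
    if (anyDuplicated(ids))
        stopData("duplicate individual ID in sample file: ",
                 ids[duplicated(ids)][1])
    # identifier/metadata columns (type 0) stay character; D/C/P/B are numeric
    cols <- lapply(seq_along(header)[-1], function(j) {
        raw <- cells[, j]
        raw[raw == "NA"] <- NA_character_
        if (types[j] == "0") return(raw)
        v <- suppressWarnings(as.numeric(raw))
        badNum <- which(is.na(v) & !is.na(raw))
        if (length(badNum))
            stopData("sample file row ", badNum[1], ": non-numeric value '",
                     raw[badNum[1]], "' in column '", header[j], "'")
        v
    })
    names(cols) <- header[-1]
    df <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
    rownames(df) <- ids
    pt <- PhenotypeTable(df, colTypes = types[-1])
    validObject(pt)
    pt
}
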