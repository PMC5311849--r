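# Writers for the four run outputs under a user prefix:
#   <prefix>.result  one row per region (full model) or per fitted model
#   <prefix>.betas   per-phenotype effects, only when requested
#   <prefix>.log     run details: counts, phenotypes, variants with MAFs
#   <prefix>.error   empty on success, details on failure
# Columns are tab-separated with a commented header; p-values,
# likelihoods and BICs use scientific notation with 6 significant
# digits.

.resultHeader <- paste0("#", paste(
    c("region", "start", "end", "n_variants", "n_individuals", "model",
      "loglik", "bic", "p_value", "status"), collapse = "\t"))

.betasHeader <- paste0("#", paste(
    c("region", "model", "phenotype", "beta", "se"), collapse = "\t"))

formatResultRow <- function(region, start, end, nVariants, nIndividuals,
                            model, loglik, bic, pValue, status) {
    paste(region, start, end, nVariants, nIndividuals, model,
          fmtSci(loglik), fmtSci(bic), fmtSci(pValue), status, sep = "\t")
}

#' Write the run output files
#'
#' @param prefix output path prefix; the four files are
#'   `<prefix>.result`, `<prefix>.betas` (only when `writeBetas`),
#'   `<prefix>.log` and `<prefix>.error`.
#' @param resultRows data.frame with columns region, start, end,
#'   nVariants, nIndividuals, model, loglik, bic, pValue, status.
#' @param betaRows data.frame with columns region, model, phenotype,
#'   beta, se (or `NULL`).
#' @param logLines,errorLines character vectors.
#' @param writeBetas logical; when `FALSE` no `.betas` file is created.
#' @return invisibly, the paths written.
#' @export
writeScanOutputs <- function(prefix, resultRows, betaRows = NULL,
                             logLines = character(0),
                             errorLines = character(0),
                             writeBetas = FALSE) {
    dir <- dirname(prefix)
    if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
        stopData("output prefix not writable: ", prefix)
    paths <- paste0(prefix, c(".result", ".log", ".error"))
    lines <- .resultHeader
    if (!is.null(resultRows) && nrow(resultRows)) {
        lines <- c(lines, vapply(seq_len(nrow(resultRows)), function(i) {
            r <- resultRows[i, ]
            formatResultRow(r$region, r$start, r$end, r$nVariants,
                            r$nIndividuals, r$model, r$loglik, r$bic,
                            r$pValue, r$status)
        }, ""))
    }
    writeLines(lines, paths[1])
    writeLines(logLines, paths[2])
    writeLines(errorLines, paths[3])
    if (writeBetas) {
        bpath <- paste0(prefix, ".betas")
        blines <- .betasHeader
        if (!is.null(betaRows) && nrow(betaRows)) {
            blines <- c(blines, vapply(seq_len(nrow(betaRows)), function(i) {
                b <- betaRows[i, ]
                paste(b$region, b$model, b$phenotype, fmtSci(b$beta),
                      fmtSci(b$se), sep = "\t")
            }, ""))
        }
        writeLines(blines, bpath)
        paths <- c(paths, bpath)
    }
    invisible(paths)
}
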