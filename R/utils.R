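# Condition helpers: usage errors map to CLI exit 1, data errors to exit 2.

stopUsage <- function(...) {
    stop(errorCondition(paste0(...), class = c("rvburden_usage_error",
                                               "rvburden_error")))
}

stopData <- function(...) {
    stop(errorCondition(paste0(...), class = c("rvburden_data_error",
                                               "rvburden_error")))
}

# Scientific notation with 6 significant digits, the output-file convention.
fmtSci <- function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 5))
}

fmtNum <- function(x) {
    ifelse(is.na(x), "NA", trimws(formatC(x, format = "g", digits = 6)))
}

.splitWS <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]
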