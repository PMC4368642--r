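## Tab-delimited I/O. Expression matrices: first column = series id, header
## of ZT labels, repeated labels = replicates, missing values empty or NA.
## Result tables carry run metadata in '#'-prefixed header lines so a run is
## reconstructible from its output alone.

#' Read an expression matrix TSV
#'
#' First column holds series identifiers; remaining column names are ZT
#' labels in hours (`ZT00`, `ZT04`, ..., or plain numbers; repeated labels
#' are replicates). Lines starting with `#` are metadata and are skipped.
#' Non-numeric cells (other than empty/`NA`) fail with their line number.
#'
#' @param path file path.
#' @param period period in hours for the returned grid.
#' @return list with `values` (matrix, series x samples) and `grid`
#'   ([TimeGrid-class]).
#' @export
readExpressionTSV <- function(path, period = 24) {
    raw <- read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
    if (ncol(raw) < 4L) stop("expected an id column plus >= 3 time columns")
    ids <- as.character(raw[[1L]])
    numcols <- raw[-1L]
    for (k in seq_along(numcols)) {
        v <- numcols[[k]]
        if (!is.numeric(v)) {
            bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
            if (length(bad))
                stop("non-numeric cell in column '", names(numcols)[k],
                     "', data line ", bad[1L])
            numcols[[k]] <- as.numeric(v)
        }
    }
    values <- as.matrix(numcols)
    rownames(values) <- ids
    times <- parseZTLabels(colnames(values))
    list(values = values, grid = timeGrid(times, period))
}

#' Write an expression matrix TSV
#'
#' @param values matrix, series x samples; rownames are series ids.
#' @param grid the [TimeGrid-class] labelling the columns.
#' @param path output path.
#' @param metadata named list written as `# key=value` header lines.
#' @export
writeExpressionTSV <- function(values, grid, path, metadata = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(metadata))
        writeLines(sprintf("# %s=%s", k, as.character(metadata[[k]])), con)
    df <- data.frame(id = rownames(values) %||% seq_len(nrow(values)),
                     values, check.names = FALSE)
    colnames(df) <- c("id", sprintf("ZT%g", gridTimes(grid)))
    write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results (or any) table with metadata header
#'
#' @param results data.frame.
#' @param path output path.
#' @param metadata named list written as `# key=value` lines (merged with
#'   any `"metadata"` attribute on `results`).
#' @export
writeResultsTSV <- function(results, path, metadata = list()) {
    meta <- c(attr(results, "metadata") %||% list(), metadata)
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
        writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
    write.table(format(results, digits = 15, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
}

#' Read a results table written by [writeResultsTSV()]
#'
#' @param path file path.
#' @return data.frame with a `"metadata"` attribute holding the parsed
#'   `# key=value` header lines.
#' @export
readResultsTSV <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr) {
        kv <- sub("^#\\s*", "", h)
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq > 0)
            meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
    df <- read.delim(text = lines[!grepl("^#", lines)],
                     stringsAsFactors = FALSE, check.names = FALSE)
    attr(df, "metadata") <- meta
    df
}
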