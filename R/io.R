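#' @include baselines.R
NULL

.delimFor <- function(format) if (format == "csv") "," else "\t"

#' Read a read-depth matrix from TSV/CSV
#'
#' Expects bin identifiers in the first row and sample identifiers in the
#' first column. Ragged rows, non-numeric cells and duplicate identifiers
#' are rejected with the offending coordinates in the error message.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param transpose set `TRUE` for files with bins in rows.
#' @return A [ReadDepthMatrix-class].
#' @export
readMatrix <- function(path, format = c("tsv", "csv"), transpose = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path))
        .stopInvalid("file not found: ", path)
    sep <- .delimFor(format)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        .stopInvalid("matrix file must have a header plus >= 1 data row")
    cells <- strsplit(lines, sep, fixed = TRUE)
    width <- length(cells[[1L]])
    ragged <- which(lengths(cells) != width)
    if (length(ragged))
        .stopInvalid("ragged row ", ragged[1L], ": expected ", width,
                     " fields, found ", length(cells[[ragged[1L]]]))
    header <- cells[[1L]]
    binIDs <- header[-1L]
    sampleIDs <- vapply(cells[-1L], `[`, character(1L), 1L)
    vals <- matrix(NA_real_, length(sampleIDs), length(binIDs))
    for (r in seq_along(sampleIDs)) {
        row <- suppressWarnings(as.numeric(cells[[r + 1L]][-1L]))
        bad <- which(is.na(row))
        if (length(bad))
            .stopInvalid("non-numeric cell at row '", sampleIDs[r],
                         "', column '", binIDs[bad[1L]], "' (value '",
                         cells[[r + 1L]][bad[1L] + 1L], "')")
        vals[r, ] <- row
    }
    if (anyDuplicated(sampleIDs))
        .stopInvalid("duplicate sample identifier: ",
                     sampleIDs[anyDuplicated(sampleIDs)])
    if (anyDuplicated(binIDs))
        .stopInvalid("duplicate bin identifier: ",
                     binIDs[anyDuplicated(binIDs)])
    if (transpose) {
        vals <- t(vals)
        tmp <- sampleIDs; sampleIDs <- binIDs; binIDs <- tmp
    }
    ReadDepthMatrix(vals, sampleIDs = sampleIDs, binIDs = binIDs)
}

#' Write a read-depth matrix to TSV/CSV
#'
#' Values are serialised losslessly (`%.17g`), so a write/read round trip
#' is bit-exact.
#'
#' @param B a [ReadDepthMatrix-class] or numeric matrix.
#' @param path destination file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
writeMatrix <- function(B, path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    if (!is(B, "ReadDepthMatrix")) B <- ReadDepthMatrix(.coerceMatrix(B))
    sep <- .delimFor(format)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("sample_id", B@binIDs), collapse = sep), con)
    body <- vapply(seq_len(nrow(B@values)), function(r)
        paste(c(B@sampleIDs[r], sprintf("%.17g", B@values[r, ])),
              collapse = sep), character(1L))
    writeLines(body, con)
    invisible(path)
}

#' Write the outputs of a TCP run
#'
#' Produces four files in `outputDir`: `recovered_matrix.tsv` (final X,
#' rows in recovered order), `ordering.tsv` (position, sample identifier,
#' original row index), `trace.csv` (per-iteration convergence trace) and
#' `manifest.json` (configuration, seed, package version, convergence
#' flag).
#'
#' @param result a [TCPResult-class].
#' @param outputDir directory (created if absent).
#' @param seed optional integer recorded in the manifest.
#' @param inputPath optional input file path recorded in the manifest.
#' @return invisibly, the vector of paths written.
#' @export
writeResult <- function(result, outputDir, seed = NA_integer_,
                        inputPath = NA_character_) {
    if (!is(result, "TCPResult")) .stopInvalid("'result' must be a TCPResult")
    if (!dir.exists(outputDir))
        dir.create(outputDir, recursive = TRUE)
    if (file.access(outputDir, mode = 2L) != 0L)
        stop("output directory is not writable: ", outputDir, call. = FALSE)
    mPath <- file.path(outputDir, "recovered_matrix.tsv")
    writeMatrix(result@recovered, mPath)
    arrangement <- sampleArrangement(result)@order
    oPath <- file.path(outputDir, "ordering.tsv")
    utils::write.table(
        data.frame(position = seq_along(arrangement),
                   sample_id = result@recovered@sampleIDs,
                   original_index = arrangement),
        oPath, sep = "\t", quote = FALSE, row.names = FALSE)
    tPath <- file.path(outputDir, "trace.csv")
    utils::write.csv(result@trace, tPath, row.names = FALSE)
    cfg <- result@config
    manifest <- list(
        package = "TCPermute",
        version = as.character(utils::packageVersion("TCPermute")),
        config = list(alpha = cfg@alpha, gamma = cfg@gamma,
                      maxIters = cfg@maxIters, tol = cfg@tol,
                      stallWindow = cfg@stallWindow,
                      boundary = cfg@boundary),
        seed = seed, input = inputPath,
        converged = result@converged,
        iterations = result@state@iteration)
    jPath <- file.path(outputDir, "manifest.json")
    jsonlite::write_json(manifest, jPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(mPath, oPath, tPath, jPath))
}
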