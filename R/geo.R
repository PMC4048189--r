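# Minimal GEO series-matrix ingestion (read-only, local files).
#
# A series matrix interleaves "!"-prefixed metadata lines with one
# tab-separated expression table delimited by !series_matrix_table_begin /
# !series_matrix_table_end. Values are passed through on the scale the
# caller declares; sample groups are left unassigned for the caller to
# annotate before screening.

#' Load a GEO series-matrix file
#'
#' @param accessionOrPath path to a local series-matrix file. A bare GEO
#'   accession (e.g. `"GSE45114"`) is rejected with an explicit
#'   network-disabled error: this loader never fetches.
#' @param datasetId study identifier; defaults to the `!Series_geo_accession`
#'   field when present, else the file name.
#' @param scaleFlag scale of the stored values, `"log2"` (default) or
#'   `"linear"`.
#' @return an [ExpressionDataset] with all sample groups `NA`.
#' @export
readGeoSeriesMatrix <- function(accessionOrPath, datasetId = NULL,
                                scaleFlag = c("log2", "linear")) {
  scaleFlag <- match.arg(scaleFlag)
  if (!file.exists(accessionOrPath)) {
    if (grepl("^GSE[0-9]+$", accessionOrPath))
      msError(sprintf(
        "network disabled: cannot fetch accession '%s'; supply a local series-matrix file",
        accessionOrPath), "mitoscreen_network_error")
    msError(sprintf("no such file: %s", accessionOrPath),
            "mitoscreen_io_error")
  }
  lines <- readLines(accessionOrPath, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    msError(sprintf("%s: missing or malformed series_matrix_table markers",
                    accessionOrPath), "mitoscreen_format_error")
  if (is.null(datasetId)) {
    acc <- grep("^!Series_geo_accession", lines, value = TRUE)
    datasetId <- if (length(acc)) {
      gsub('"', "", strsplit(acc[1], "\t")[[1]][2])
    } else sub("\\.[^.]*$", "", basename(accessionOrPath))
  }
  tab <- lines[(begin + 1):(end - 1)]
  con <- textConnection(tab)
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, sep = "\t",
                           na.strings = c("NA", "null", ""),
                           check.names = FALSE, stringsAsFactors = FALSE)
  colnames(raw) <- gsub('"', "", colnames(raw))
  probes <- gsub('"', "", as.character(raw[[1]]))
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probes
  ExpressionDataset(values, datasetId = datasetId,
                    group = rep(NA_character_, ncol(values)),
                    scaleFlag = scaleFlag)
}
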