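# Readers and writers for the package's TSV dialects.
#
# Matrix TSV: header "probe_id<TAB>sample1<TAB>...", one row per probe,
# "NA" for missing, UTF-8. Metadata TSV: columns sample_id, group and
# optionally pair_with.

#' Read a probe-level expression dataset
#'
#' @param matrixPath tab-delimited expression matrix; first column
#'   `probe_id`, remaining columns one per sample.
#' @param metadataPath tab-delimited sample table with columns `sample_id`,
#'   `group` (one of `tumor`, `normal_liver`, `adjacent_nontumor`) and
#'   optional `pair_with` naming the tumor sample's adjacent partner.
#' @param datasetId study identifier; defaults to the matrix file name.
#' @param scaleFlag `"log2"` (values stored as-is) or `"linear"` (values
#'   log2-transformed, non-positive intensities set missing).
#' @return an [ExpressionDataset].
#' @export
readExpressionDataset <- function(matrixPath, metadataPath,
                                  datasetId = NULL,
                                  scaleFlag = c("log2", "linear")) {
  scaleFlag <- match.arg(scaleFlag)
  if (is.null(datasetId))
    datasetId <- sub("\\.[^.]*$", "", basename(matrixPath))
  raw <- readTsv(matrixPath)
  if (ncol(raw) < 2 || colnames(raw)[1] != "probe_id")
    msError(sprintf("%s: first column must be 'probe_id'", matrixPath),
            "mitoscreen_format_error")
  probes <- as.character(raw$probe_id)
  if (anyDuplicated(probes))
    msError(sprintf("duplicate probe id '%s' in %s",
                    probes[duplicated(probes)][1], matrixPath),
            "mitoscreen_format_error")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    msError(sprintf("duplicate sample id '%s' in %s",
                    samples[duplicated(samples)][1], matrixPath),
            "mitoscreen_format_error")
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probes

  meta <- readTsv(metadataPath)
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    msError(sprintf("%s: metadata needs columns sample_id and group",
                    metadataPath), "mitoscreen_metadata_error")
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    msError(sprintf("sample(s) absent from metadata: %s",
                    paste(missing, collapse = ", ")),
            "mitoscreen_metadata_error")
  meta <- meta[match(samples, meta$sample_id), ]
  badGroup <- !is.na(meta$group) & !(meta$group %in% .SAMPLE_GROUPS)
  if (any(badGroup))
    msError(sprintf("unknown group label(s): %s",
                    paste(unique(meta$group[badGroup]), collapse = ", ")),
            "mitoscreen_metadata_error")
  pairWith <- NULL
  if ("pair_with" %in% colnames(meta)) {
    has <- !is.na(meta$pair_with) & meta$pair_with != ""
    if (any(has)) {
      pairWith <- as.character(meta$pair_with[has])
      names(pairWith) <- meta$sample_id[has]
    }
  }
  ExpressionDataset(values, datasetId = datasetId,
                    group = stats::setNames(meta$group, meta$sample_id),
                    pairWith = pairWith, scaleFlag = scaleFlag)
}

#' Write an expression dataset (or gene matrix) back to TSV
#'
#' Inverse of [readExpressionDataset()] on the stored log2 values: reading
#' the written pair back with `scaleFlag = "log2"` reproduces values, ids,
#' groups and pairing.
#'
#' @param object an [ExpressionDataset] or [GeneMatrix].
#' @param matrixPath,metadataPath output file paths.
#' @param idColumn name of the feature-id column, default `"probe_id"`.
#' @return invisibly, the two paths.
#' @export
writeExpressionDataset <- function(object, matrixPath, metadataPath,
                                   idColumn = "probe_id") {
  values <- assay(object)
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  writeTsv(df, matrixPath)
  cd <- colData(object)
  writeTsv(data.frame(sample_id = rownames(cd), group = cd$group,
                      pair_with = cd$pair_with, stringsAsFactors = FALSE),
           metadataPath)
  invisible(c(matrixPath, metadataPath))
}

#' Read a probe-to-Entrez annotation table
#'
#' @param path two-column TSV with header `probe_id`, `entrez_id`; blank or
#'   `NA` Entrez entries mark unannotated probes and are dropped.
#' @return named integer vector mapping probe id to Entrez gene id; probes
#'   without a gene are absent.
#' @export
readProbeAnnotation <- function(path) {
  ann <- readTsv(path)
  if (nrow(ann) == 0)
    return(stats::setNames(integer(0), character(0)))
  if (!all(c("probe_id", "entrez_id") %in% colnames(ann)))
    msError(sprintf("%s: annotation needs columns probe_id and entrez_id",
                    path), "mitoscreen_format_error")
  keep <- !is.na(ann$entrez_id) & ann$entrez_id != ""
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0)
    return(stats::setNames(integer(0), character(0)))
  entrez <- suppressWarnings(as.numeric(ann$entrez_id))
  if (any(is.na(entrez)) || any(entrez != floor(entrez)) || any(entrez <= 0))
    msError(sprintf("%s: non-integer entrez_id value(s)", path),
            "mitoscreen_format_error")
  dup <- duplicated(ann$probe_id) | duplicated(ann$probe_id, fromLast = TRUE)
  if (any(dup)) {
    conflict <- tapply(entrez[dup], ann$probe_id[dup],
                       function(g) length(unique(g)) > 1)
    if (any(conflict))
      msError(sprintf("probe '%s' maps to more than one gene",
                      names(conflict)[conflict][1]),
              "mitoscreen_conflict_error")
    first <- !duplicated(ann$probe_id)
    ann <- ann[first, , drop = FALSE]
    entrez <- entrez[first]
  }
  stats::setNames(as.integer(entrez), as.character(ann$probe_id))
}
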