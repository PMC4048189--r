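# Normalization and probe-to-gene collapsing.
#
# Pipeline order is fixed: log2 at read time, per-sample median
# normalization at probe level, then collapsing to Entrez genes by
# arithmetic mean on the log2 scale (the geometric mean of intensities).

.medianCenter <- function(values) {
  med <- apply(values, 2, median, na.rm = TRUE)
  if (any(is.na(med)))
    msError(sprintf("sample '%s' has no non-missing values",
                    colnames(values)[which(is.na(med))[1]]),
            "mitoscreen_all_missing_error")
  sweep(values, 2, med)
}

#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "ExpressionDataset", function(object) {
  assay(object, "exprs") <- .medianCenter(assay(object, "exprs"))
  object
})

#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "GeneMatrix", function(object) {
  assay(object, "exprs") <- .medianCenter(assay(object, "exprs"))
  object@normalized <- TRUE
  object
})

#' Collapse probes to Entrez genes
#'
#' When several probes map to the same Entrez GeneID their log2 signal
#' intensities are averaged (missing values excluded) to obtain a single
#' value per gene and sample. Unmapped probes are dropped; genes are
#' ordered by ascending Entrez id.
#'
#' @param dataset an [ExpressionDataset] in log2 units.
#' @param annotation named integer vector probe id to Entrez id, as from
#'   [readProbeAnnotation()].
#' @return a [GeneMatrix] inheriting the dataset's sample metadata.
#' @export
collapseProbes <- function(dataset, annotation) {
  stopifnot(is(dataset, "ExpressionDataset"))
  values <- assay(dataset)
  mapped <- intersect(rownames(values), names(annotation))
  if (length(mapped) == 0)
    msError("annotation maps none of the dataset's probes",
            "mitoscreen_empty_result_error")
  values <- values[mapped, , drop = FALSE]
  gene <- annotation[mapped]
  # mean over non-missing probe values per gene
  ord <- sort(unique(gene))
  sums <- rowsum(ifelse(is.na(values), 0, values), gene)
  counts <- rowsum((!is.na(values)) * 1L, gene)
  collapsed <- sums / counts          # 0/0 -> NaN where all probes missing
  collapsed[counts == 0] <- NA_real_
  collapsed <- collapsed[as.character(ord), , drop = FALSE]
  pairing <- .pairingOf(dataset)
  GeneMatrix(collapsed, datasetId = datasetId(dataset),
             group = sampleGroups(dataset),
             pairWith = if (length(pairing)) pairing else NULL,
             normalized = FALSE)
}

#' Restrict a gene matrix to a requested gene list
#'
#' Rows are returned in request order. Genes absent from the matrix are
#' kept as all-missing rows so downstream screening can record them as not
#' present. Duplicate requests are de-duplicated with a warning.
#'
#' @param gm a [GeneMatrix].
#' @param genes integer vector of Entrez ids (non-empty).
#' @return a [GeneMatrix] with one row per requested gene.
#' @export
subsetGenes <- function(gm, genes) {
  stopifnot(is(gm, "GeneMatrix"))
  genes <- as.integer(genes)
  if (length(genes) == 0)
    msError("empty gene request", "mitoscreen_empty_request_error")
  if (anyDuplicated(genes)) {
    warning("duplicate gene ids in request were de-duplicated")
    genes <- unique(genes)
  }
  values <- assay(gm)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(values),
                dimnames = list(as.character(genes), colnames(values)))
  hit <- match(as.character(genes), rownames(values))
  out[!is.na(hit), ] <- values[hit[!is.na(hit)], , drop = FALSE]
  pairing <- .pairingOf(gm)
  GeneMatrix(out, datasetId = datasetId(gm), group = sampleGroups(gm),
             pairWith = if (length(pairing)) pairing else NULL,
             normalized = isNormalized(gm))
}
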