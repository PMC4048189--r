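#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay `assay<-`
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

.SAMPLE_GROUPS <- c("tumor", "normal_liver", "adjacent_nontumor")

.validSampleMeta <- function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("group", "pair_with") %in% colnames(cd)))
    return("colData must contain 'group' and 'pair_with' columns")
  grp <- cd$group
  bad <- !is.na(grp) & !(grp %in% .SAMPLE_GROUPS)
  if (any(bad))
    msg <- c(msg, sprintf("unknown sample group(s): %s",
                          paste(unique(grp[bad]), collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample id: %s",
                          colnames(object)[duplicated(colnames(object))][1]))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate feature id: %s",
                          rownames(object)[duplicated(rownames(object))][1]))
  pw <- cd$pair_with
  has <- !is.na(pw)
  if (any(has)) {
    if (any(is.na(grp[has])) || any(grp[has] != "tumor"))
      msg <- c(msg, "pair_with may only be set on tumor samples")
    if (!all(pw[has] %in% colnames(object)[!is.na(grp) &
                                           grp == "adjacent_nontumor"]))
      msg <- c(msg, "pair_with must point at adjacent_nontumor samples")
    if (anyDuplicated(pw[has]))
      msg <- c(msg, "pairing must be injective (adjacent sample paired twice)")
  }
  msg
}

#' ExpressionDataset: one study's probe-level expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a single study's
#' probes-by-samples matrix in log2 units (linear input is log2-transformed
#' at read time, with non-positive intensities set to missing). Sample-level
#' metadata lives in `colData`: a `group` column with values `tumor`,
#' `normal_liver` or `adjacent_nontumor` (or `NA` before annotation, e.g.
#' straight from a GEO series matrix), and an optional `pair_with` column
#' joining each tumor sample to its adjacent non-tumor partner.
#'
#' @slot datasetId single character identifier for the study.
#' @slot scaleFlag the scale the raw file declared, `"log2"` or `"linear"`;
#'   stored values are always log2.
#' @export
setClass("ExpressionDataset",
         contains = "SummarizedExperiment",
         representation(datasetId = "character", scaleFlag = "character"),
         prototype(datasetId = NA_character_, scaleFlag = "log2"))

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1)
    msg <- c(msg, "datasetId must be a single string")
  if (!(object@scaleFlag %in% c("log2", "linear")))
    msg <- c(msg, "scaleFlag must be 'log2' or 'linear'")
  msg <- c(msg, .validSampleMeta(object))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   probe ids as rownames and sample ids as colnames.
#' @param datasetId study identifier.
#' @param group named (or positional) character vector of sample groups,
#'   values in `tumor`, `normal_liver`, `adjacent_nontumor`; `NA` allowed
#'   for not-yet-annotated samples.
#' @param pairWith optional named character vector mapping tumor sample ids
#'   to their paired adjacent_nontumor sample ids.
#' @param scaleFlag `"log2"` (default) or `"linear"`. Linear values are
#'   log2-transformed; values <= 0 become `NA` rather than `-Inf`.
#' @return an `ExpressionDataset`.
#' @export
ExpressionDataset <- function(values, datasetId, group,
                              pairWith = NULL, scaleFlag = c("log2", "linear")) {
  scaleFlag <- match.arg(scaleFlag)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    msError("expression matrix needs probe rownames and sample colnames",
            "mitoscreen_format_error")
  if (scaleFlag == "linear") {
    values[values <= 0] <- NA_real_
    values <- log2(values)
  }
  if (!is.null(names(group))) group <- group[colnames(values)]
  pw <- rep(NA_character_, ncol(values))
  names(pw) <- colnames(values)
  if (!is.null(pairWith)) pw[names(pairWith)] <- pairWith
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(group = unname(as.character(group)),
                        pair_with = unname(pw),
                        row.names = colnames(values)))
  new("ExpressionDataset", se, datasetId = as.character(datasetId),
      scaleFlag = scaleFlag)
}

#' GeneMatrix: gene-level (Entrez-collapsed) expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per Entrez
#' gene (rownames are the ids as character; `rowData$entrez` keeps them as
#' integers), samples and metadata inherited from the source
#' [ExpressionDataset].
#'
#' @slot datasetId study identifier carried over from the source dataset.
#' @slot normalized `TRUE` once per-sample median normalization has been
#'   applied (each column's median over non-missing entries is 0).
#' @export
setClass("GeneMatrix",
         contains = "SummarizedExperiment",
         representation(datasetId = "character", normalized = "logical"),
         prototype(datasetId = NA_character_, normalized = FALSE))

setValidity("GeneMatrix", function(object) {
  msg <- c(character(), .validSampleMeta(object))
  if (!("entrez" %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must carry an 'entrez' column")
  if (length(object@normalized) != 1 || is.na(object@normalized))
    msg <- c(msg, "normalized flag must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneMatrix
#'
#' @param values numeric genes-by-samples matrix (log2), rownames are
#'   Entrez ids.
#' @param datasetId study identifier.
#' @param group,pairWith sample metadata as in [ExpressionDataset()].
#' @param normalized logical, whether columns are already median-centred.
#' @return a `GeneMatrix`.
#' @export
GeneMatrix <- function(values, datasetId, group, pairWith = NULL,
                       normalized = FALSE) {
  values <- as.matrix(values)
  entrez <- suppressWarnings(as.integer(rownames(values)))
  if (any(is.na(entrez)) || any(entrez <= 0))
    msError("GeneMatrix rownames must be positive integer Entrez ids",
            "mitoscreen_format_error")
  if (!is.null(names(group))) group <- group[colnames(values)]
  pw <- rep(NA_character_, ncol(values))
  names(pw) <- colnames(values)
  if (!is.null(pairWith)) pw[names(pairWith)] <- pairWith
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(entrez = entrez, row.names = rownames(values)),
    colData = DataFrame(group = unname(as.character(group)),
                        pair_with = unname(pw),
                        row.names = colnames(values)))
  new("GeneMatrix", se, datasetId = as.character(datasetId),
      normalized = normalized)
}

#' Screen configuration
#'
#' Thresholds and rules of the dual overexpression gate. By default a tumor
#' sample is called overexpressed at 2-fold or more over the normal-liver
#' reference, and a gene is marked when at least 30\% of the patient
#' population carries the call; both thresholds are inclusive.
#'
#' @slot foldThreshold linear fold ratio a tumor sample must reach
#'   (inclusive) to be called overexpressed; default 2.
#' @slot freqThreshold fraction of (non-missing) tumor samples that must be
#'   called (inclusive) for a gene to pass in a dataset; default 0.30.
#' @slot minDatasetsRule cross-dataset aggregation: `"all_present"` (pass in
#'   every dataset where the gene is measured), `"majority_present"`
#'   (default; pass in more than half), or `"pooled"` (per-sample calls
#'   pooled across datasets after per-dataset normalization and reference).
#' @slot referenceStat `"mean"` (default) or `"median"` of the reference
#'   group's log2 values.
#' @slot referenceGroup `"normal_liver"` (default) or `"adjacent_nontumor"`.
#' @slot gate `"frequency"` (default; the per-sample fold threshold acts
#'   inside the frequency computation) or `"fold_and_frequency"` (also
#'   requires the dataset-level mean fold to reach `foldThreshold`).
#' @export
setClass("ScreenConfig",
         representation(foldThreshold = "numeric", freqThreshold = "numeric",
                        minDatasetsRule = "character",
                        referenceStat = "character",
                        referenceGroup = "character", gate = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@foldThreshold <= 0) msg <- c(msg, "foldThreshold must be > 0")
  if (object@freqThreshold <= 0 || object@freqThreshold > 1)
    msg <- c(msg, "freqThreshold must be in (0, 1]")
  if (!(object@minDatasetsRule %in%
        c("all_present", "majority_present", "pooled")))
    msg <- c(msg, "unknown minDatasetsRule")
  if (!(object@referenceStat %in% c("mean", "median")))
    msg <- c(msg, "referenceStat must be 'mean' or 'median'")
  if (!(object@referenceGroup %in% c("normal_liver", "adjacent_nontumor")))
    msg <- c(msg, "referenceGroup must be a non-tumor group")
  if (!(object@gate %in% c("frequency", "fold_and_frequency")))
    msg <- c(msg, "gate must be 'frequency' or 'fold_and_frequency'")
  if (length(msg)) msg else TRUE
})

#' @rdname ScreenConfig-class
#' @param foldThreshold,freqThreshold,minDatasetsRule,referenceStat,referenceGroup,gate
#'   see the class slots.
#' @return a `ScreenConfig`.
#' @export
screenConfig <- function(foldThreshold = 2, freqThreshold = 0.30,
                         minDatasetsRule = c("majority_present",
                                             "all_present", "pooled"),
                         referenceStat = c("mean", "median"),
                         referenceGroup = c("normal_liver",
                                            "adjacent_nontumor"),
                         gate = c("frequency", "fold_and_frequency")) {
  new("ScreenConfig", foldThreshold = foldThreshold,
      freqThreshold = freqThreshold,
      minDatasetsRule = match.arg(minDatasetsRule),
      referenceStat = match.arg(referenceStat),
      referenceGroup = match.arg(referenceGroup),
      gate = match.arg(gate))
}

#' Screen result
#'
#' Per gene-by-dataset fold, overexpression frequency and p-value, plus the
#' per-gene consensus marked flag, together with the [ScreenConfig] that
#' produced them so the flags can always be recomputed from the records.
#'
#' @slot stats data.frame with columns `gene`, `dataset`, `present`, `fold`,
#'   `freq`, `p_value`, `zero_variance`, `n_tumor`, `n_reference`, `passes`.
#' @slot marked data.frame with columns `gene`, `marked`, `status`
#'   (`"ok"` or `"absent"`), `n_present`, `n_passing`.
#' @slot config the [ScreenConfig] used.
#' @export
setClass("ScreenResult",
         representation(stats = "data.frame", marked = "data.frame",
                        config = "ScreenConfig"))

setValidity("ScreenResult", function(object) {
  msg <- character()
  need <- c("gene", "dataset", "present", "fold", "freq", "p_value",
            "zero_variance", "n_tumor", "n_reference", "passes")
  if (!all(need %in% colnames(object@stats)))
    msg <- c(msg, "stats is missing required columns")
  ok <- object@stats$present
  if (any(ok) && (any(object@stats$freq[ok] < 0, na.rm = TRUE) ||
                  any(object@stats$freq[ok] > 1, na.rm = TRUE)))
    msg <- c(msg, "freq must lie in [0, 1]")
  if (any(ok) && any(object@stats$fold[ok] <= 0, na.rm = TRUE))
    msg <- c(msg, "fold must be positive wherever present")
  if (!all(c("gene", "marked", "status") %in% colnames(object@marked)))
    msg <- c(msg, "marked table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' qPCR experiment
#'
#' Replicate threshold-cycle (Ct) observations for a target gene and the
#' beta-actin endogenous reference, in long format: one row per Ct replicate
#' with columns `sample_id`, `condition`, `gene_role` (`"target"` or
#' `"reference"`), `replicate`, `ct`. An observation is one
#' (sample, condition) cell; relative levels derive from replicate-mean
#' Ct differences assuming perfect doubling per cycle.
#'
#' @slot observations the long-format data.frame described above.
#' @export
setClass("QpcrExperiment", representation(observations = "data.frame"))

setValidity("QpcrExperiment", function(object) {
  obs <- object@observations
  need <- c("sample_id", "condition", "gene_role", "replicate", "ct")
  if (!all(need %in% colnames(obs)))
    return("observations need columns sample_id, condition, gene_role, replicate, ct")
  msg <- character()
  if (!all(obs$gene_role %in% c("target", "reference")))
    msg <- c(msg, "gene_role must be 'target' or 'reference'")
  if (any(!is.finite(obs$ct)) || any(obs$ct <= 0) || any(obs$ct >= 50))
    msg <- c(msg, "Ct values must lie in (0, 50)")
  key <- paste(obs$sample_id, obs$condition)
  for (k in unique(key)) {
    roles <- obs$gene_role[key == k]
    if (!all(c("target", "reference") %in% roles)) {
      msg <- c(msg, sprintf(
        "observation '%s' needs at least one target and one reference Ct", k))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname QpcrExperiment-class
#' @param observations long-format data.frame of Ct replicates.
#' @return a `QpcrExperiment`.
#' @export
QpcrExperiment <- function(observations) {
  new("QpcrExperiment", observations = as.data.frame(observations))
}
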