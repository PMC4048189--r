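# Generics and simple accessor/show methods for the core classes.

#' @name accessors
#' @title Accessors for mitoscreen classes
#' @param object an [ExpressionDataset], [GeneMatrix], [ScreenResult] or
#'   [QpcrExperiment].
#' @description Small accessors so code never reaches into slots:
#' `datasetId()` the study identifier; `scaleFlag()` the declared input
#' scale; `sampleGroups()` the named per-sample group labels;
#' `samplePairing()` the tumor-to-adjacent pairing map; `geneIds()` the
#' Entrez ids of a [GeneMatrix]; `isNormalized()` its normalization flag;
#' `screenStats()`, `markedGenes()` and `screenCfg()` the parts of a
#' [ScreenResult]; `qpcrObservations()` the Ct table of a
#' [QpcrExperiment].
NULL

#' @rdname accessors
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setGeneric("scaleFlag", function(object) standardGeneric("scaleFlag"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("samplePairing", function(object) standardGeneric("samplePairing"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("screenStats", function(object) standardGeneric("screenStats"))
#' @rdname accessors
#' @export
setGeneric("markedGenes", function(object) standardGeneric("markedGenes"))
#' @rdname accessors
#' @export
setGeneric("screenCfg", function(object) standardGeneric("screenCfg"))
#' @rdname accessors
#' @export
setGeneric("qpcrObservations",
           function(object) standardGeneric("qpcrObservations"))

#' Median-normalize expression columns
#'
#' @param object an [ExpressionDataset] or [GeneMatrix] in log2 units.
#' @return the same kind of object with every sample column centred so its
#'   median over non-missing entries is 0.
#' @export
setGeneric("medianNormalize", function(object) standardGeneric("medianNormalize"))

#' @rdname accessors
#' @export
setMethod("datasetId", "ExpressionDataset", function(object) object@datasetId)
#' @rdname accessors
#' @export
setMethod("datasetId", "GeneMatrix", function(object) object@datasetId)
#' @rdname accessors
#' @export
setMethod("scaleFlag", "ExpressionDataset", function(object) object@scaleFlag)

.groupsOf <- function(object) {
  g <- colData(object)$group
  names(g) <- colnames(object)
  g
}

.pairingOf <- function(object) {
  pw <- colData(object)$pair_with
  names(pw) <- colnames(object)
  pw[!is.na(pw)]
}

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionDataset", .groupsOf)
#' @rdname accessors
#' @export
setMethod("sampleGroups", "GeneMatrix", .groupsOf)
#' @rdname accessors
#' @export
setMethod("samplePairing", "ExpressionDataset", .pairingOf)
#' @rdname accessors
#' @export
setMethod("samplePairing", "GeneMatrix", .pairingOf)
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneMatrix", function(object) rowData(object)$entrez)
#' @rdname accessors
#' @export
setMethod("isNormalized", "GeneMatrix", function(object) object@normalized)
#' @rdname accessors
#' @export
setMethod("screenStats", "ScreenResult", function(object) object@stats)
#' @rdname accessors
#' @export
setMethod("markedGenes", "ScreenResult", function(object) object@marked)
#' @rdname accessors
#' @export
setMethod("screenCfg", "ScreenResult", function(object) object@config)
#' @rdname accessors
#' @export
setMethod("qpcrObservations", "QpcrExperiment",
          function(object) object@observations)

.groupCounts <- function(object) {
  g <- colData(object)$group
  tab <- table(factor(g, levels = .SAMPLE_GROUPS), useNA = "ifany")
  paste(names(tab)[tab > 0], tab[tab > 0], sep = ":", collapse = " ")
}

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset '%s': %d probes x %d samples (log2, read as %s)\n",
              object@datasetId, nrow(object), ncol(object), object@scaleFlag))
  cat("  groups ", .groupCounts(object), "\n", sep = "")
  if (length(.pairingOf(object)))
    cat("  ", length(.pairingOf(object)), " tumor/adjacent pairs\n", sep = "")
})

setMethod("show", "GeneMatrix", function(object) {
  cat(sprintf("GeneMatrix '%s': %d genes x %d samples%s\n",
              object@datasetId, nrow(object), ncol(object),
              if (object@normalized) " (median-normalized)" else ""))
  cat("  groups ", .groupCounts(object), "\n", sep = "")
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: fold >= %g, freq >= %g, rule=%s, ref=%s(%s), gate=%s\n",
    object@foldThreshold, object@freqThreshold, object@minDatasetsRule,
    object@referenceStat, object@referenceGroup, object@gate))
})

setMethod("show", "ScreenResult", function(object) {
  nmark <- sum(object@marked$marked)
  cat(sprintf("ScreenResult: %d genes x %d datasets, %d marked overexpressed\n",
              length(unique(object@stats$gene)),
              length(unique(object@stats$dataset)), nmark))
  show(object@config)
})

setMethod("show", "QpcrExperiment", function(object) {
  obs <- object@observations
  cat(sprintf("QpcrExperiment: %d Ct replicates, %d observations, conditions: %s\n",
              nrow(obs),
              length(unique(paste(obs$sample_id, obs$condition))),
              paste(unique(obs$condition), collapse = ", ")))
})
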