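# The dual fold/frequency overexpression screen.
#
# Definition of the gate: a tumor sample is "overexpressed" for a gene when
# its linear fold over the reference-group level is at least
# foldThreshold (inclusive); the per-dataset frequency is
# the fraction of tumor samples with non-missing values carrying that call;
# a gene is "markedly overexpressed" when the frequency reaches
# freqThreshold, aggregated across datasets by minDatasetsRule. The
# per-dataset fold summary reported alongside is 2^(mean tumor log2 - mean
# reference log2).

.refValues <- function(gm, gene, cfg) {
  values <- assay(gm)
  row <- match(as.character(as.integer(gene)), rownames(values))
  if (is.na(row)) return(NULL)
  grp <- colData(gm)$group
  ref <- values[row, !is.na(grp) & grp == cfg@referenceGroup]
  ref[!is.na(ref)]
}

#' Reference expression level of a gene
#'
#' The mean (or median, per `referenceStat`) log2 level of the gene over
#' the configured reference group, typically normal livers.
#'
#' @param gm a [GeneMatrix].
#' @param gene Entrez id.
#' @param cfg a [ScreenConfig].
#' @return the reference log2 level (scalar).
#' @export
normalReference <- function(gm, gene, cfg = screenConfig()) {
  ref <- .refValues(gm, gene, cfg)
  if (is.null(ref) || length(ref) < 2)
    msError(sprintf(
      "gene %s: fewer than 2 usable %s reference samples in dataset '%s'",
      gene, cfg@referenceGroup, datasetId(gm)),
      "mitoscreen_insufficient_reference_error")
  if (cfg@referenceStat == "median") median(ref) else mean(ref)
}

#' Per-tumor-sample fold ratios and overexpression calls
#'
#' For every tumor sample with a non-missing value, the linear fold over
#' the reference level (`2^(x - ref)`) and the call `fold >= foldThreshold`
#' (inclusive).
#'
#' @inheritParams normalReference
#' @return data.frame with columns `sample_id`, `fold`, `call`.
#' @export
sampleFoldCalls <- function(gm, gene, cfg = screenConfig()) {
  ref <- normalReference(gm, gene, cfg)
  values <- assay(gm)
  row <- match(as.character(as.integer(gene)), rownames(values))
  grp <- colData(gm)$group
  tum <- !is.na(grp) & grp == "tumor"
  x <- values[row, tum]
  x <- x[!is.na(x)]
  fold <- 2^(x - ref)
  data.frame(sample_id = names(x), fold = unname(fold),
             call = unname(fold >= cfg@foldThreshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized per-dataset summaries for a set of genes; the single
# implementation behind both geneDatasetSummary() and screenCollection().
.datasetSummaries <- function(gm, genes, cfg) {
  genes <- as.integer(genes)
  values <- assay(gm)
  grp <- colData(gm)$group
  rows <- match(as.character(genes), rownames(values))
  nG <- length(genes)
  full <- matrix(NA_real_, nG, ncol(values))
  full[!is.na(rows), ] <- values[rows[!is.na(rows)], , drop = FALSE]
  present <- rowSums(!is.na(full)) > 0
  tumMat <- full[, !is.na(grp) & grp == "tumor", drop = FALSE]
  refMat <- full[, !is.na(grp) & grp == cfg@referenceGroup, drop = FALSE]
  nTum <- rowSums(!is.na(tumMat))
  nRef <- rowSums(!is.na(refMat))
  if (any(present & nRef < 2))
    msError(sprintf(
      "gene %s: fewer than 2 usable %s reference samples in dataset '%s'",
      genes[which(present & nRef < 2)[1]], cfg@referenceGroup,
      datasetId(gm)), "mitoscreen_insufficient_reference_error")
  refLevel <- if (cfg@referenceStat == "median")
    apply(refMat, 1, median, na.rm = TRUE) else rowMeans(refMat, na.rm = TRUE)
  calls <- 2^(tumMat - refLevel) >= cfg@foldThreshold
  freq <- rowSums(calls, na.rm = TRUE) / nTum
  fold <- 2^(rowMeans(tumMat, na.rm = TRUE) - rowMeans(refMat, na.rm = TRUE))
  pval <- rep(NA_real_, nG)
  zvar <- rep(FALSE, nG)
  for (i in which(present & nTum >= 2)) {
    tt <- tTestPooled(tumMat[i, ], refMat[i, ])
    pval[i] <- tt$p_value
    zvar[i] <- tt$zero_variance
  }
  out <- data.frame(
    gene = genes, dataset = datasetId(gm), present = present,
    fold = ifelse(present, fold, NA_real_),
    freq = ifelse(present, freq, NA_real_),
    p_value = pval, zero_variance = zvar,
    n_tumor = ifelse(present, nTum, 0L),
    n_reference = ifelse(present, nRef, 0L), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-dataset summary for one gene
#'
#' @inheritParams normalReference
#' @return one-row data.frame: `gene`, `dataset`, `present`, `fold`
#'   (`2^(mean tumor - mean reference)`), `freq` (fraction of evaluable
#'   tumors called overexpressed), `p_value` (two-tailed pooled-variance
#'   Student's t on log2 values, tumor vs reference), `zero_variance`,
#'   `n_tumor`, `n_reference`. A gene absent from the dataset yields
#'   `present = FALSE` with missing statistics.
#' @export
geneDatasetSummary <- function(gm, gene, cfg = screenConfig()) {
  .datasetSummaries(gm, gene, cfg)
}

.passesGate <- function(fold, freq, cfg) {
  ok <- freq >= cfg@freqThreshold
  if (cfg@gate == "fold_and_frequency") ok <- ok & fold >= cfg@foldThreshold
  ok & !is.na(ok)
}

#' Mark markedly overexpressed genes across datasets
#'
#' Applies the consensus rule to per-gene-per-dataset summaries. Under
#' `all_present` a gene must pass in every dataset where it is measured;
#' under `majority_present` (default) in more than half of them; under
#' `pooled`, the per-sample calls are pooled over all tumors across
#' datasets (each called against its own dataset's reference after
#' per-dataset normalization) and the gate applied once. Pooled fold is the
#' tumor-count-weighted geometric mean of per-dataset folds.
#'
#' @param stats data.frame of rows from [geneDatasetSummary()].
#' @param cfg a [ScreenConfig].
#' @return a [ScreenResult].
#' @export
markOverexpressed <- function(stats, cfg = screenConfig()) {
  if (nrow(stats) == 0 || length(unique(stats$dataset)) < 1)
    msError("need summaries from at least one dataset",
            "mitoscreen_empty_result_error")
  stats$passes <- stats$present & .passesGate(stats$fold, stats$freq, cfg)
  genes <- unique(stats$gene)
  marked <- data.frame(gene = genes, marked = FALSE, status = "ok",
                       n_present = 0L, n_passing = 0L,
                       stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    rows <- stats[stats$gene == genes[i], , drop = FALSE]
    pres <- rows[rows$present, , drop = FALSE]
    marked$n_present[i] <- nrow(pres)
    marked$n_passing[i] <- sum(pres$passes)
    if (nrow(pres) == 0) {
      marked$status[i] <- "absent"
      next
    }
    marked$marked[i] <- switch(
      cfg@minDatasetsRule,
      all_present = all(pres$passes),
      majority_present = sum(pres$passes) > nrow(pres) / 2,
      pooled = {
        nEval <- pres$n_tumor
        pooledFreq <- sum(pres$freq * nEval) / sum(nEval)
        pooledFold <- 2^(sum(log2(pres$fold) * nEval) / sum(nEval))
        .passesGate(pooledFold, pooledFreq, cfg)
      })
  }
  new("ScreenResult", stats = stats, marked = marked, config = cfg)
}

#' Run the overexpression screen over a collection of datasets
#'
#' @param collection list of [GeneMatrix] objects (normalize first; see
#'   [medianNormalize()]).
#' @param genes Entrez ids to screen; default, the union of all genes
#'   present in the collection.
#' @param cfg a [ScreenConfig].
#' @return a [ScreenResult].
#' @export
screenCollection <- function(collection, genes = NULL, cfg = screenConfig()) {
  stopifnot(length(collection) >= 1)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(collection, geneIds))))
  stats <- do.call(rbind, lapply(collection, .datasetSummaries,
                                 genes = genes, cfg = cfg))
  rownames(stats) <- NULL
  markOverexpressed(stats, cfg)
}

#' Tumor versus adjacent non-tumor differential test
#'
#' Two-tailed pooled-variance Student's t on log2 values between tumor and
#' adjacent non-tumor samples of one dataset; unpaired by default, with a
#' paired variant when pairing metadata exists.
#'
#' @param gm a [GeneMatrix] with `adjacent_nontumor` samples.
#' @param gene Entrez id.
#' @param paired use the tumor-to-adjacent pairing from the metadata.
#' @return list with `p_value`, `statistic`, `df`, `zero_variance`.
#' @export
tumorVsAdjacentTest <- function(gm, gene, paired = FALSE) {
  values <- assay(gm)
  row <- match(as.character(as.integer(gene)), rownames(values))
  if (is.na(row))
    msError(sprintf("gene %s not in dataset '%s'", gene, datasetId(gm)),
            "mitoscreen_insufficient_data_error")
  grp <- colData(gm)$group
  if (paired) {
    pairing <- samplePairing(gm)
    if (length(pairing) < 2)
      msError("fewer than 2 tumor/adjacent pairs in metadata",
              "mitoscreen_insufficient_data_error")
    tum <- values[row, names(pairing)]
    adj <- values[row, unname(pairing)]
    return(tTestPooled(tum, adj, paired = TRUE))
  }
  tum <- values[row, !is.na(grp) & grp == "tumor"]
  adj <- values[row, !is.na(grp) & grp == "adjacent_nontumor"]
  tum <- tum[!is.na(tum)]; adj <- adj[!is.na(adj)]
  if (length(tum) < 2 || length(adj) < 2)
    msError("fewer than 2 usable samples in tumor or adjacent group",
            "mitoscreen_insufficient_data_error")
  tTestPooled(tum, adj)
}

.wideMatrix <- function(stats, col) {
  genes <- unique(stats$gene)
  dsets <- unique(stats$dataset)
  m <- matrix(NA_real_, length(genes), length(dsets),
              dimnames = list(as.character(genes), dsets))
  m[cbind(match(stats$gene, genes), match(stats$dataset, dsets))] <-
    ifelse(stats$present, stats[[col]], NA_real_)
  m
}

#' Export screen result tables
#'
#' Writes `fold_matrix.tsv`, `freq_matrix.tsv`, `pvalue_matrix.tsv` and
#' `padj_matrix.tsv` (genes by datasets, `NA` where a gene is absent from a
#' dataset) plus `marked_genes.tsv` with the consensus flag under the
#' configured rule and, for reference, under each aggregation rule. The
#' `padj` table holds Benjamini-Hochberg adjusted p-values per dataset; the
#' screen itself works from raw p-values, so the adjusted table is a
#' convenience only. Optionally renders a fold heat map via pheatmap.
#'
#' @param sr a [ScreenResult].
#' @param outDir output directory, created if needed.
#' @param heatmap logical; also write `fold_heatmap.png` (requires the
#'   pheatmap package).
#' @return invisibly, the paths written.
#' @export
exportScreenTables <- function(sr, outDir, heatmap = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    msError(sprintf("cannot create output directory '%s'", outDir),
            "mitoscreen_io_error")
  stats <- screenStats(sr)
  cfg <- screenCfg(sr)
  paths <- character()
  for (col in c("fold", "freq", "p_value")) {
    m <- .wideMatrix(stats, col)
    fname <- c(fold = "fold_matrix.tsv", freq = "freq_matrix.tsv",
               p_value = "pvalue_matrix.tsv")[[col]]
    p <- file.path(outDir, fname)
    writeTsv(data.frame(gene = rownames(m), m, check.names = FALSE), p)
    paths <- c(paths, p)
  }
  padj <- .wideMatrix(stats, "p_value")
  padj[] <- apply(padj, 2, p.adjust, method = "BH")
  p <- file.path(outDir, "padj_matrix.tsv")
  writeTsv(data.frame(gene = rownames(padj), padj, check.names = FALSE), p)
  paths <- c(paths, p)

  marked <- markedGenes(sr)
  for (rule in c("all_present", "majority_present", "pooled")) {
    alt <- cfg
    alt@minDatasetsRule <- rule
    marked[[paste0("marked_", rule)]] <-
      markedGenes(markOverexpressed(stats, alt))$marked
  }
  marked$fold_threshold <- cfg@foldThreshold
  marked$freq_threshold <- cfg@freqThreshold
  marked$rule <- cfg@minDatasetsRule
  p <- file.path(outDir, "marked_genes.tsv")
  writeTsv(marked, p)
  paths <- c(paths, p)

  if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
    m <- log2(.wideMatrix(stats, "fold"))
    p <- file.path(outDir, "fold_heatmap.png")
    grDevices::png(p, width = 640, height = 960)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "grey80")
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
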