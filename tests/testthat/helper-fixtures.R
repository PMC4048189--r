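# Fixture builders and independent oracles used across the suite.

# Closed-form pooled-variance two-tailed t (independent of stats::t.test).
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# A small GeneMatrix built directly from a genes-by-samples matrix.
makeGeneMatrix <- function(values, groups, datasetId = "toy",
                           pairWith = NULL, normalized = TRUE) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  names(groups) <- colnames(values)
  GeneMatrix(values, datasetId = datasetId, group = groups,
             pairWith = pairWith, normalized = normalized)
}

# One-gene GeneMatrix from explicit tumor/reference log2 value vectors.
makeOneGene <- function(tumor, reference, gene = 7272,
                        refGroup = "normal_liver", datasetId = "toy") {
  values <- matrix(c(tumor, reference), nrow = 1,
                   dimnames = list(gene, c(sprintf("t%d", seq_along(tumor)),
                                           sprintf("r%d", seq_along(reference)))))
  makeGeneMatrix(values, c(rep("tumor", length(tumor)),
                           rep(refGroup, length(reference))),
                 datasetId = datasetId)
}

# Naive per-sample double-loop screen oracle over plain matrices.
# mats: named list of genes-by-samples matrices (log2, already normalized);
# groupsList: matching list of per-sample group label vectors.
screenOracle <- function(mats, groupsList, foldThreshold = 2,
                         freqThreshold = 0.30, rule = "majority_present",
                         gate = "frequency") {
  genes <- sort(unique(unlist(lapply(mats, rownames))))
  stats <- list()
  for (d in names(mats)) {
    m <- mats[[d]]; grp <- groupsList[[d]]
    for (g in genes) {
      if (!(g %in% rownames(m)) || all(is.na(m[g, ]))) {
        stats[[length(stats) + 1]] <- data.frame(
          gene = g, dataset = d, present = FALSE, fold = NA, freq = NA)
        next
      }
      refSum <- 0; refN <- 0
      for (s in seq_along(grp)) {
        if (grp[s] == "normal_liver" && !is.na(m[g, s])) {
          refSum <- refSum + m[g, s]; refN <- refN + 1
        }
      }
      ref <- refSum / refN
      nCall <- 0; nEval <- 0; tumSum <- 0
      for (s in seq_along(grp)) {
        if (grp[s] == "tumor" && !is.na(m[g, s])) {
          nEval <- nEval + 1
          tumSum <- tumSum + m[g, s]
          if (2^(m[g, s] - ref) >= foldThreshold) nCall <- nCall + 1
        }
      }
      stats[[length(stats) + 1]] <- data.frame(
        gene = g, dataset = d, present = TRUE,
        fold = 2^(tumSum / nEval - ref), freq = nCall / nEval)
    }
  }
  stats <- do.call(rbind, stats)
  marked <- logical(length(genes)); names(marked) <- genes
  for (g in genes) {
    rows <- stats[stats$gene == g & stats$present, , drop = FALSE]
    if (nrow(rows) == 0) next
    pass <- rows$freq >= freqThreshold
    if (gate == "fold_and_frequency") pass <- pass & rows$fold >= foldThreshold
    marked[g] <- if (rule == "all_present") all(pass) else
      sum(pass) > nrow(rows) / 2
  }
  list(stats = stats, marked = marked)
}

# Random small screening instance (plain matrices + groups) for
# oracle-equivalence tests; injects some missing values and genes.
randomScreenInstance <- function(seed, nGenes = 8, nTumor = 10, nNormal = 6,
                                 nDatasets = 2) {
  set.seed(seed)
  genes <- as.character(sample(1000:9999, nGenes))
  mats <- list(); groupsList <- list()
  for (d in seq_len(nDatasets)) {
    keep <- sort(sample(nGenes, nGenes - sample(0:2, 1)))
    m <- matrix(rnorm(length(keep) * (nTumor + nNormal), 8, 1.5),
                nrow = length(keep),
                dimnames = list(genes[keep],
                                sprintf("d%ds%02d", d, seq_len(nTumor + nNormal))))
    m[sample(length(m), round(0.05 * length(m)))] <- NA
    mats[[sprintf("ds%d", d)]] <- m
    groupsList[[sprintf("ds%d", d)]] <-
      c(rep("tumor", nTumor), rep("normal_liver", nNormal))
  }
  list(mats = mats, groups = groupsList)
}

# Noiseless QpcrExperiment with a chosen number of up-regulated pairs:
# each up pair has tumor exactly `upFold` over adjacent, the rest exactly 1.
makeSurveyExperiment <- function(nUp, nTotal, upFold = 4) {
  rows <- list()
  for (i in seq_len(nTotal)) {
    fold <- if (i <= nUp) upFold else 1
    for (cond in c("tumor", "adjacent")) {
      delta <- if (cond == "tumor") 8 - log2(fold) else 8
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("pair%02d", i), condition = cond,
        gene_role = rep(c("target", "reference"), each = 3),
        replicate = rep(1:3, 2), ct = c(rep(16 + delta, 3), rep(16, 3)))
    }
  }
  QpcrExperiment(do.call(rbind, rows))
}

# Constant-Ct two-condition experiment: target sits deltaA (deltaB) cycles
# above the reference in condition A (B).
makeDeltaCtExperiment <- function(deltaA, deltaB, nObs = 3, nReps = 3) {
  rows <- list()
  for (cond in c("A", "B")) {
    delta <- if (cond == "A") deltaA else deltaB
    for (o in seq_len(nObs)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s%d", cond, o), condition = cond,
        gene_role = rep(c("target", "reference"), each = nReps),
        replicate = rep(seq_len(nReps), 2),
        ct = c(rep(16 + delta, nReps), rep(16, nReps)))
    }
  }
  QpcrExperiment(do.call(rbind, rows))
}
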