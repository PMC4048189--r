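cfgDefault <- screenConfig()

test_that("reference level is the mean (or median) over usable normals", {
  expect_equal(normalReference(makeOneGene(5, c(3, 3, 3)), 7272), 3)
  expect_equal(normalReference(makeOneGene(5, c(2, 4)), 7272), 3)
  expect_equal(normalReference(makeOneGene(5, c(2, 4)), 7272,
                               screenConfig(referenceStat = "median")), 3)
  expect_equal(normalReference(makeOneGene(5, c(5, NA, 7)), 7272), 6)
  expect_error(normalReference(makeOneGene(5, c(3, NA)), 7272),
               class = "mitoscreen_insufficient_reference_error")
})

test_that("per-sample fold calls are inclusive at the threshold", {
  gm <- makeOneGene(c(4.1, 3, 4), c(3, 3, 3))
  fc <- sampleFoldCalls(gm, 7272)
  expect_equal(fc$fold, c(2^1.1, 1, 2))
  # the fold threshold is inclusive: exactly 2-fold is a call
  expect_identical(fc$call, c(TRUE, FALSE, TRUE))
})

test_that("gene-by-dataset summary matches the closed-form pooled t", {
  gm <- makeOneGene(c(5, 5), c(3, 3))
  s <- geneDatasetSummary(gm, 7272)
  expect_equal(s$fold, 4)
  expect_equal(s$freq, 1)
  expect_true(s$zero_variance)

  gm <- makeOneGene(c(1, 2, 3), c(2, 3, 4))
  s <- geneDatasetSummary(gm, 7272)
  oracle <- pooledTOracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(oracle$t, -1.2247448714, tolerance = 1e-9)
  expect_equal(oracle$df, 4)
  expect_equal(s$p_value, 0.2878641347, tolerance = 1e-9)
  expect_equal(s$p_value, oracle$p, tolerance = 1e-12)

  # identical tumor and reference values: fold 1, flagged p = 1
  gm <- makeOneGene(c(2, 3, 4), c(2, 3, 4))
  s <- geneDatasetSummary(gm, 7272)
  expect_equal(s$fold, 1)
  expect_equal(s$p_value, 1)
  expect_true(s$zero_variance)

  # gene not measured in the dataset
  s <- geneDatasetSummary(makeOneGene(5, c(3, 3)), 999)
  expect_false(s$present)
  expect_true(is.na(s$fold))
})

statsRow <- function(gene, dataset, fold, freq, present = TRUE) {
  data.frame(gene = gene, dataset = dataset, present = present, fold = fold,
             freq = freq, p_value = 0.01, zero_variance = FALSE,
             n_tumor = 10L, n_reference = 5L)
}

test_that("consensus marking follows the aggregation rule", {
  strong <- rbind(statsRow(1, "d1", 4.0, 0.5), statsRow(1, "d2", 3.0, 0.4),
                  statsRow(1, "d3", 2.5, 0.35))
  for (rule in c("all_present", "majority_present", "pooled"))
    expect_true(markedGenes(markOverexpressed(
      strong, screenConfig(minDatasetsRule = rule)))$marked)

  lowFreq <- rbind(statsRow(1, "d1", 2.5, 0.25), statsRow(1, "d2", 2.5, 0.25),
                   statsRow(1, "d3", 2.5, 0.25))
  for (rule in c("all_present", "majority_present", "pooled"))
    expect_false(markedGenes(markOverexpressed(
      lowFreq, screenConfig(minDatasetsRule = rule)))$marked)

  twoOfThree <- rbind(statsRow(1, "d1", 4.0, 0.5), statsRow(1, "d2", 3.0, 0.4),
                      statsRow(1, "d3", 1.5, 0.1))
  expect_true(markedGenes(markOverexpressed(
    twoOfThree, screenConfig(minDatasetsRule = "majority_present")))$marked)
  expect_false(markedGenes(markOverexpressed(
    twoOfThree, screenConfig(minDatasetsRule = "all_present")))$marked)

  absent <- statsRow(1, "d1", NA, NA, present = FALSE)
  m <- markedGenes(markOverexpressed(absent, cfgDefault))
  expect_false(m$marked)
  expect_identical(m$status, "absent")
})

test_that("the dataset-level fold gate is available as an option", {
  # frequency passes but the mean fold sits below 2: gated only under
  # fold_and_frequency
  row <- statsRow(1, "d1", 1.8, 0.5)
  expect_true(markedGenes(markOverexpressed(row, cfgDefault))$marked)
  expect_false(markedGenes(markOverexpressed(
    row, screenConfig(gate = "fold_and_frequency")))$marked)
})

test_that("tumor-vs-adjacent test matches the oracle and guards group size", {
  gm <- makeOneGene(c(1, 2, 3), c(2, 3, 4), refGroup = "adjacent_nontumor")
  tt <- tumorVsAdjacentTest(gm, 7272)
  expect_equal(tt$p_value, 0.2878641347, tolerance = 1e-9)

  same <- makeOneGene(c(2, 3, 4), c(2, 3, 4), refGroup = "adjacent_nontumor")
  tt <- tumorVsAdjacentTest(same, 7272)
  expect_equal(tt$p_value, 1)
  expect_true(tt$zero_variance)

  one <- makeOneGene(c(1, 2, 3), 2, refGroup = "adjacent_nontumor")
  expect_error(tumorVsAdjacentTest(one, 7272),
               class = "mitoscreen_insufficient_data_error")
})

test_that("paired tumor-adjacent variant uses the pairing metadata", {
  values <- matrix(c(5, 6, 7, 3, 4, 5), nrow = 1,
                   dimnames = list("7272", c("t1", "t2", "t3", "a1", "a2", "a3")))
  gm <- makeGeneMatrix(values, c(rep("tumor", 3), rep("adjacent_nontumor", 3)),
                       pairWith = c(t1 = "a1", t2 = "a2", t3 = "a3"))
  tt <- tumorVsAdjacentTest(gm, 7272, paired = TRUE)
  # constant difference of 2 cycles: zero variance of differences, flagged
  expect_true(tt$zero_variance)
  expect_equal(tt$p_value, 0)
})

test_that("a naive per-sample double loop reproduces fold, freq and flags", {
  for (seed in c(1, 2, 3, 7)) {
    inst <- randomScreenInstance(seed)
    gms <- lapply(names(inst$mats), function(d)
      makeGeneMatrix(inst$mats[[d]], inst$groups[[d]], datasetId = d))
    for (rule in c("majority_present", "all_present")) {
      res <- screenCollection(gms, cfg = screenConfig(minDatasetsRule = rule))
      oracle <- screenOracle(inst$mats, inst$groups, rule = rule)
      stats <- screenStats(res)
      stats <- stats[order(stats$gene, stats$dataset), ]
      ostats <- oracle$stats[order(oracle$stats$gene, oracle$stats$dataset), ]
      expect_equal(stats$present, ostats$present)
      expect_equal(stats$fold, ostats$fold, tolerance = 1e-12)
      expect_equal(stats$freq, ostats$freq, tolerance = 1e-12)
      m <- markedGenes(res)
      expect_identical(m$marked,
                       unname(oracle$marked[as.character(m$gene)]))
    }
  }
})

test_that("per-sample offsets before normalization change no call", {
  sim <- simulateExpressionCollection(
    simConfig(seed = 5, nDatasets = 2, nGenes = 50, nTumor = 15, nNormal = 6,
              spikeGenes = 1001:1005, missingGeneRate = 0))
  run <- function(datasets) {
    gms <- lapply(datasets, function(ed)
      collapseProbes(medianNormalize(ed), sim$annotation))
    markedGenes(screenCollection(gms))
  }
  base <- run(sim$datasets)
  shifted <- lapply(sim$datasets, function(ed) {
    set.seed(99)
    SummarizedExperiment::assay(ed) <-
      sweep(SummarizedExperiment::assay(ed), 2,
            runif(ncol(ed), -4, 4), `+`)
    ed
  })
  expect_identical(run(shifted), base)
})

test_that("calls shrink weakly as either threshold rises", {
  inst <- randomScreenInstance(12, nGenes = 12, nTumor = 12, nNormal = 6,
                               nDatasets = 1)
  gm <- makeGeneMatrix(inst$mats[[1]], inst$groups[[1]])
  freqAt <- function(th) {
    s <- screenStats(screenCollection(list(gm),
                                      cfg = screenConfig(foldThreshold = th)))
    s$freq[s$present]
  }
  f1 <- freqAt(1.5); f2 <- freqAt(2); f3 <- freqAt(3)
  expect_true(all(f2 <= f1) && all(f3 <= f2))

  markedAt <- function(fold, freq) {
    m <- markedGenes(screenCollection(list(gm), cfg = screenConfig(
      foldThreshold = fold, freqThreshold = freq)))
    m$gene[m$marked]
  }
  expect_true(all(markedAt(2, 0.4) %in% markedAt(2, 0.3)))
  expect_true(all(markedAt(3, 0.3) %in% markedAt(2, 0.3)))
})

test_that("exported tables reproduce the marked flags on re-import", {
  inst <- randomScreenInstance(21, nGenes = 10, nDatasets = 3)
  gms <- lapply(names(inst$mats), function(d)
    makeGeneMatrix(inst$mats[[d]], inst$groups[[d]], datasetId = d))
  res <- screenCollection(gms)
  out <- tempfile()
  exportScreenTables(res, out)
  expect_true(all(file.exists(file.path(out, c(
    "fold_matrix.tsv", "freq_matrix.tsv", "pvalue_matrix.tsv",
    "padj_matrix.tsv", "marked_genes.tsv")))))
  freq <- read.delim(file.path(out, "freq_matrix.tsv"), check.names = FALSE)
  marked <- read.delim(file.path(out, "marked_genes.tsv"))
  # recompute majority_present flags from the exported frequency cells
  recomputed <- apply(freq[, -1, drop = FALSE], 1, function(fr) {
    pres <- !is.na(fr)
    sum(fr[pres] >= 0.30) > sum(pres) / 2
  })
  expect_identical(unname(recomputed),
                   marked$marked_majority_present[match(freq$gene, marked$gene)])
  # absent gene/dataset cells are NA in every matrix
  fold <- read.delim(file.path(out, "fold_matrix.tsv"), check.names = FALSE)
  expect_true(any(is.na(as.matrix(fold[, -1]))))
})
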