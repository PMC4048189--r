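test_that("the noiseless limit gives exact 2-fold calls in every tumor", {
  cfg <- simConfig(seed = 3, nDatasets = 1, nGenes = 30, nTumor = 8,
                   nNormal = 4, noiseSd = 0, sampleOffsetSd = 0,
                   baselineSd = 0, spikeGenes = 1001:1003, spikeDelta = 1,
                   spikeFraction = 1, missingGeneRate = 0)
  sim <- simulateExpressionCollection(cfg)
  gm <- collapseProbes(medianNormalize(sim$datasets[[1]]), sim$annotation)
  s <- screenStats(screenCollection(list(gm)))
  spiked <- s$gene %in% 1001:1003
  expect_equal(s$freq[spiked], rep(1, 3))
  expect_equal(s$fold[spiked], rep(2, 3), tolerance = 1e-9)
  fc <- sampleFoldCalls(gm, 1001)
  expect_equal(fc$fold, rep(2, 8), tolerance = 1e-9)
  expect_true(all(fc$call))
})

test_that("no gene passes the frequency gate when no tumor carries a spike", {
  cfg <- simConfig(seed = 4, nDatasets = 2, nGenes = 40, nTumor = 10,
                   nNormal = 5, spikeGenes = 1001:1005, spikeDelta = 3,
                   spikeFraction = 0, missingGeneRate = 0)
  sim <- simulateExpressionCollection(cfg)
  gms <- lapply(sim$datasets, function(ed)
    collapseProbes(medianNormalize(ed), sim$annotation))
  expect_equal(sum(markedGenes(screenCollection(gms))$marked), 0)
  expect_equal(nrow(sim$truth$carriers), 0)
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- simConfig(seed = 17, nDatasets = 2, nGenes = 25, nTumor = 6,
                   nNormal = 4)
  a <- simulateExpressionCollection(cfg)
  b <- simulateExpressionCollection(cfg)
  expect_identical(lapply(a$datasets, SummarizedExperiment::assay),
                   lapply(b$datasets, SummarizedExperiment::assay))
  expect_identical(a$truth, b$truth)
  fa <- tempfile(); fb <- tempfile(); meta <- tempfile()
  writeExpressionDataset(a$datasets[[1]], fa, meta)
  writeExpressionDataset(b$datasets[[1]], fb, meta)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("truth table carriers match the spiked values in the matrix", {
  cfg <- simConfig(seed = 9, nDatasets = 1, nGenes = 20, nTumor = 10,
                   nNormal = 4, noiseSd = 0, sampleOffsetSd = 0,
                   spikeGenes = c(1001L, 1010L), spikeDelta = 2,
                   spikeFraction = 0.5, missingGeneRate = 0)
  sim <- simulateExpressionCollection(cfg)
  gm <- collapseProbes(sim$datasets[[1]], sim$annotation)
  values <- SummarizedExperiment::assay(gm)
  for (g in c(1001L, 1010L)) {
    carriers <- sim$truth$carriers$sample_id[sim$truth$carriers$gene == g]
    normals <- values[as.character(g), sampleGroups(gm) == "normal_liver"]
    tumors <- values[as.character(g), sampleGroups(gm) == "tumor"]
    expect_equal(unname(tumors[carriers]),
                 rep(mean(normals) + 2, length(carriers)), tolerance = 1e-9)
    others <- setdiff(names(tumors), carriers)
    expect_equal(unname(tumors[others]), rep(mean(normals), length(others)),
                 tolerance = 1e-9)
  }
})

test_that("spike ids outside the simulated gene range are a config error", {
  expect_error(simConfig(nGenes = 10, spikeGenes = 1011L),
               class = "mitoscreen_config_error")
  expect_error(simConfig(spikeFraction = 1.2),
               class = "mitoscreen_config_error")
})

test_that("noiseless qPCR generation recovers the true fold exactly", {
  for (f in c(1, 4)) {
    qe <- simulateQpcrExperiment(f, ctNoiseSd = 0, seed = 1)
    expect_equal(foldBetweenConditions(qe, "A", "B")$fold, f,
                 tolerance = 1e-12)
  }
  expect_error(simulateQpcrExperiment(-2), class = "mitoscreen_config_error")
})

test_that("cohort generation hits the requested up-regulation fraction", {
  expect_equal(specimenSurvey(simulateSpecimenCohort(
    nPairs = 20, fracUp = 0, seed = 2))$percent_up, 0)
  expect_equal(specimenSurvey(simulateSpecimenCohort(
    nPairs = 20, fracUp = 1, seed = 2))$percent_up, 100)
  sv <- specimenSurvey(simulateSpecimenCohort(seed = 5))
  expect_equal(sv$n_total, 53)
  expect_equal(sv$n_up, 46)
})

test_that("assay generation honors its effect sizes", {
  tabs <- simulateAssayTables(list(
    viability = list(noise_sd = 0), colony = list(noise_sd = 0),
    xenograft = list(sigma = 0)), seed = 1)
  rv <- relativeViability(tabs$viability$od450[tabs$viability$group == "treated"],
                          tabs$viability$od450[tabs$viability$group == "vehicle"])
  expect_equal(rv$percent, 50)    # default effect 0.5, zero noise

  armA <- tabs$xenograft[tabs$xenograft$arm == "A", ]
  armB <- tabs$xenograft[tabs$xenograft$arm == "B", ]
  gc <- growthCurveCompare(armA, armB)
  expect_equal(gc$endpoint$ratio, 2, tolerance = 1e-9)

  # identical arms: flagged p = 1 at every day
  eq <- simulateAssayTables(list(xenograft = list(ratio = 1, sigma = 0)),
                            seed = 1)
  armA <- eq$xenograft[eq$xenograft$arm == "A", ]
  armB <- eq$xenograft[eq$xenograft$arm == "B", ]
  gc <- growthCurveCompare(armA, armB)
  expect_true(all(gc$per_day$p_value == 1))
  expect_true(all(gc$per_day$zero_variance))
})

test_that("xenograft arms with a true 2-fold volume ratio estimate near 2", {
  ratios <- vapply(0:9, function(seed) {
    tabs <- simulateAssayTables(list(xenograft = list(ratio = 2, sigma = 0.2,
                                                      n = 5)), seed = seed)
    gc <- growthCurveCompare(tabs$xenograft[tabs$xenograft$arm == "A", ],
                             tabs$xenograft[tabs$xenograft$arm == "B", ])
    gc$endpoint$ratio
  }, 0)
  expect_true(all(ratios >= 1.5 & ratios <= 2.7))
})

test_that("simulated colony effects are detected in most seeds", {
  hits <- vapply(seq_len(10), function(seed) {
    tabs <- simulateAssayTables(seed = seed)
    cc <- colonyCompare(tabs$colony$count[tabs$colony$group == "a"],
                        tabs$colony$count[tabs$colony$group == "b"])
    cc$p_value < 0.05
  }, TRUE)
  expect_gte(sum(hits), 9)
})
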