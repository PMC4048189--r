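# Deterministic synthetic-data generators. These emulate the statistical
# structure the screen assumes -- multi-probe genes, per-sample loading
# offsets, tumor/normal group structure, a spiked gene subset overexpressed
# in a parameterized fraction of the patient population, per-dataset
# missing genes, Ct replicate noise, and treatment-effect assay readouts --
# so every pipeline stage is testable without downloads. Identical
# configuration (including the seed) yields identical output, byte for
# byte once written.

#' Simulation configuration for an expression collection
#'
#' Defaults describe the regime the screen is validated under: 3 datasets
#' of 500 genes (1-3 probes each), 60 tumors and 20 normal livers per
#' dataset, gene baselines ~ Normal(8, 1) log2, measurement noise sd 0.5
#' log2, per-sample loading offsets sd 0.5 log2, 10 spiked genes carrying
#' +1.5 log2 (2.8-fold) in 60 percent of tumors, and 5 percent of genes
#' missing per dataset.
#'
#' @param seed integer seed fixing every draw.
#' @param nDatasets,nGenes,nTumor,nNormal,nAdjacent cohort dimensions per
#'   dataset.
#' @param probesPerGene integer range (min, max) of probes per gene.
#' @param baselineMean,baselineSd log2 baseline distribution per gene.
#' @param noiseSd,sampleOffsetSd log2 measurement noise and per-sample
#'   offset standard deviations.
#' @param spikeGenes Entrez ids of spiked genes (gene ids run from 1001 to
#'   1000 + `nGenes`).
#' @param spikeDelta log2 shift added to a carrier tumor sample.
#' @param spikeFraction fraction of tumors carrying the spike (independent
#'   Bernoulli per dataset, gene and tumor).
#' @param missingGeneRate fraction of genes omitted per dataset.
#' @return a `simConfig` list.
#' @export
simConfig <- function(seed = 1, nDatasets = 3, nGenes = 500,
                      probesPerGene = c(1, 3), nTumor = 60, nNormal = 20,
                      nAdjacent = 0, baselineMean = 8, baselineSd = 1,
                      noiseSd = 0.5, sampleOffsetSd = 0.5,
                      spikeGenes = 1000 + seq_len(10), spikeDelta = 1.5,
                      spikeFraction = 0.6, missingGeneRate = 0.05) {
  cfg <- list(seed = as.integer(seed), nDatasets = nDatasets,
              nGenes = nGenes, probesPerGene = probesPerGene,
              nTumor = nTumor, nNormal = nNormal, nAdjacent = nAdjacent,
              baselineMean = baselineMean, baselineSd = baselineSd,
              noiseSd = noiseSd, sampleOffsetSd = sampleOffsetSd,
              spikeGenes = as.integer(spikeGenes), spikeDelta = spikeDelta,
              spikeFraction = spikeFraction,
              missingGeneRate = missingGeneRate)
  if (any(c(cfg$noiseSd, cfg$sampleOffsetSd, cfg$baselineSd) < 0))
    msError("standard deviations must be >= 0", "mitoscreen_config_error")
  if (cfg$spikeFraction < 0 || cfg$spikeFraction > 1)
    msError("spikeFraction must lie in [0, 1]", "mitoscreen_config_error")
  if (!all(cfg$spikeGenes %in% (1000 + seq_len(cfg$nGenes))))
    msError("spike gene ids outside the simulated gene range",
            "mitoscreen_config_error")
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a multi-dataset expression collection
#'
#' Probe value = gene baseline + per-sample offset + Normal(0, noiseSd)
#' noise, all in log2 (multiplicative on the intensity scale); spiked genes
#' add `spikeDelta` to carrier tumor samples. Adjacent non-tumor samples
#' (when requested) behave like normals and are paired one-to-one with the
#' first tumors.
#'
#' @param cfg a [simConfig()].
#' @return list with `datasets` (list of [ExpressionDataset], probe level,
#'   log2), `annotation` (probe-to-Entrez map shared across datasets),
#'   `truth` (`spike_genes`, and `carriers`: data.frame dataset, gene,
#'   sample_id for every spiked tumor), and `config`.
#' @export
simulateExpressionCollection <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  entrez <- 1000 + seq_len(cfg$nGenes)
  nProbes <- sample(seq(cfg$probesPerGene[1], cfg$probesPerGene[2]),
                    cfg$nGenes, replace = TRUE)
  geneOfProbe <- rep(entrez, nProbes)
  probeIds <- unlist(lapply(seq_len(cfg$nGenes), function(g)
    sprintf("g%d_p%d", entrez[g], seq_len(nProbes[g]))))
  annotation <- stats::setNames(geneOfProbe, probeIds)

  nS <- cfg$nTumor + cfg$nNormal + cfg$nAdjacent
  datasets <- vector("list", cfg$nDatasets)
  carriers <- list()
  for (d in seq_len(cfg$nDatasets)) {
    dsid <- sprintf("sim%d", d)
    sampleIds <- c(sprintf("%s_T%02d", dsid, seq_len(cfg$nTumor)),
                   sprintf("%s_N%02d", dsid, seq_len(cfg$nNormal)),
                   if (cfg$nAdjacent)
                     sprintf("%s_A%02d", dsid, seq_len(cfg$nAdjacent)))
    group <- c(rep("tumor", cfg$nTumor), rep("normal_liver", cfg$nNormal),
               rep("adjacent_nontumor", cfg$nAdjacent))
    mu <- rnorm(cfg$nGenes, cfg$baselineMean, cfg$baselineSd)
    offsets <- rnorm(nS, 0, cfg$sampleOffsetSd)
    values <- matrix(rnorm(length(probeIds) * nS, 0, cfg$noiseSd),
                     nrow = length(probeIds),
                     dimnames = list(probeIds, sampleIds))
    values <- values + mu[match(geneOfProbe, entrez)] +
      rep(offsets, each = length(probeIds))
    for (g in cfg$spikeGenes) {
      carrier <- rbinom(cfg$nTumor, 1, cfg$spikeFraction) == 1
      rows <- which(geneOfProbe == g)
      values[rows, seq_len(cfg$nTumor)] <-
        values[rows, seq_len(cfg$nTumor)] +
        rep(cfg$spikeDelta * carrier, each = length(rows))
      if (any(carrier))
        carriers[[length(carriers) + 1L]] <- data.frame(
          dataset = dsid, gene = g,
          sample_id = sampleIds[seq_len(cfg$nTumor)][carrier],
          stringsAsFactors = FALSE)
    }
    nMissing <- round(cfg$missingGeneRate * cfg$nGenes)
    if (nMissing > 0) {
      missingGenes <- sample(entrez, nMissing)
      values <- values[!(geneOfProbe %in% missingGenes), , drop = FALSE]
    }
    pairWith <- NULL
    if (cfg$nAdjacent > 0) {
      nPair <- min(cfg$nTumor, cfg$nAdjacent)
      pairWith <- stats::setNames(
        sampleIds[cfg$nTumor + cfg$nNormal + seq_len(nPair)],
        sampleIds[seq_len(nPair)])
    }
    datasets[[d]] <- ExpressionDataset(values, datasetId = dsid,
                                       group = group, pairWith = pairWith,
                                       scaleFlag = "log2")
  }
  truthCarriers <- if (length(carriers)) do.call(rbind, carriers) else
    data.frame(dataset = character(0), gene = integer(0),
               sample_id = character(0), stringsAsFactors = FALSE)
  list(datasets = datasets, annotation = annotation,
       truth = list(spike_genes = cfg$spikeGenes, carriers = truthCarriers),
       config = cfg)
}

#' Simulate a two-condition qPCR experiment with known fold
#'
#' Reference (beta-actin) Ct replicates are drawn around 16 cycles, target
#' Ct sits 8 cycles above the reference in condition B, and condition A's
#' target Ct is lowered by `log2(trueFold)` cycles, so the ddCt estimate
#' recovers `trueFold` exactly in the noiseless limit.
#'
#' @param trueFold true linear expression fold of condition A over B (> 0).
#' @param nObs observations (replicate runs) per condition; default 3.
#' @param nCtReps Ct replicates per observation; default 3 (triplicate).
#' @param ctNoiseSd Ct replicate noise sd in cycles; default 0.1.
#' @param seed integer seed.
#' @param conditions labels for the two conditions; default `c("A", "B")`.
#' @return a [QpcrExperiment].
#' @export
simulateQpcrExperiment <- function(trueFold, nObs = 3, nCtReps = 3,
                                   ctNoiseSd = 0.1, seed = 1,
                                   conditions = c("A", "B")) {
  if (trueFold <= 0)
    msError("trueFold must be positive", "mitoscreen_config_error")
  set.seed(seed)
  rows <- list()
  for (ci in 1:2) {
    shift <- if (ci == 1) -log2(trueFold) else 0
    for (o in seq_len(nObs)) {
      sid <- sprintf("%s_obs%d", conditions[ci], o)
      rf <- 16 + rnorm(nCtReps, 0, ctNoiseSd)
      tg <- 16 + 8 + shift + rnorm(nCtReps, 0, ctNoiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, condition = conditions[ci],
        gene_role = rep(c("target", "reference"), each = nCtReps),
        replicate = rep(seq_len(nCtReps), 2), ct = c(tg, rf),
        stringsAsFactors = FALSE)
    }
  }
  QpcrExperiment(do.call(rbind, rows))
}

#' Simulate a paired tumor/adjacent specimen cohort
#'
#' `round(fracUp * nPairs)` pairs are drawn with tumor-over-adjacent fold
#' uniform in `upFoldRange` (comfortably above the 2-fold call threshold),
#' the rest with fold in `downFoldRange` (below it). Each observation is a
#' Ct triplicate for target and reference.
#'
#' @param nPairs number of specimen pairs; default 53.
#' @param fracUp fraction of up-regulated pairs in `[0, 1]`; default 46/53.
#' @param upFoldRange,downFoldRange linear fold ranges for up-regulated and
#'   background pairs.
#' @param ctNoiseSd Ct replicate noise sd in cycles; default 0.05.
#' @param seed integer seed.
#' @return a [QpcrExperiment] with conditions `"tumor"` and `"adjacent"`.
#' @export
simulateSpecimenCohort <- function(nPairs = 53, fracUp = 46 / 53,
                                   upFoldRange = c(2.5, 16),
                                   downFoldRange = c(0.7, 1.4),
                                   ctNoiseSd = 0.05, seed = 1) {
  if (fracUp < 0 || fracUp > 1)
    msError("fracUp must lie in [0, 1]", "mitoscreen_config_error")
  set.seed(seed)
  nUp <- round(fracUp * nPairs)
  fold <- c(runif(nUp, upFoldRange[1], upFoldRange[2]),
            runif(nPairs - nUp, downFoldRange[1], downFoldRange[2]))
  rows <- list()
  for (i in seq_len(nPairs)) {
    sid <- sprintf("pair%02d", i)
    adjDelta <- rnorm(1, 8, 1)          # adjacent target sits ~8 cycles up
    for (cond in c("tumor", "adjacent")) {
      delta <- if (cond == "tumor") adjDelta - log2(fold[i]) else adjDelta
      rf <- 16 + rnorm(3, 0, ctNoiseSd)
      tg <- 16 + delta + rnorm(3, 0, ctNoiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, condition = cond,
        gene_role = rep(c("target", "reference"), each = 3),
        replicate = rep(1:3, 2), ct = c(tg, rf), stringsAsFactors = FALSE)
    }
  }
  QpcrExperiment(do.call(rbind, rows))
}

#' Simulate phenotype-assay tables with known effects
#'
#' Draws OD450 viability replicates, annexin-positive fractions, colony
#' counts and a two-arm caliper series with the specified group effects and
#' noise; the effect parameters are returned as the truth record.
#'
#' @param effects named list overriding any of the defaults: `viability`
#'   (`vehicle_mean`, `effect` = treated/vehicle ratio, `noise_sd`, `n`),
#'   `apoptosis` (`means` named fractions, `noise_sd`, `n`), `colony`
#'   (`mean_a`, `mean_b`, `noise_sd`, `n`), `xenograft` (`ratio` of arm A
#'   over arm B volumes, `sigma` lognormal noise, `n` mice per arm, `days`,
#'   `base_volume_day7` mm^3, `doubling_days`, `aspect` major/minor ratio).
#' @param seed integer seed.
#' @return list of data.frames `viability`, `apoptosis`, `colony`,
#'   `xenograft`, plus `truth` (the effect list used).
#' @export
simulateAssayTables <- function(effects = list(), seed = 1) {
  defaults <- list(
    viability = list(vehicle_mean = 0.8, effect = 0.5, noise_sd = 0.02,
                     n = 3),
    apoptosis = list(means = c(naive = 0.30, resistant = 0.10),
                     noise_sd = 0.02, n = 3),
    colony = list(mean_a = 100, mean_b = 50, noise_sd = 5, n = 3),
    xenograft = list(ratio = 2, sigma = 0.2, n = 5,
                     days = c(7, 10, 14, 17, 21, 24, 28),
                     base_volume_day7 = 50, doubling_days = 7,
                     aspect = 1.5))
  eff <- utils::modifyList(defaults, effects)
  if (eff$viability$effect <= 0 || eff$colony$mean_a < 0 ||
      eff$xenograft$ratio <= 0)
    msError("effect sizes must be positive", "mitoscreen_config_error")
  set.seed(seed)

  v <- eff$viability
  viability <- data.frame(
    group = rep(c("treated", "vehicle"), each = v$n),
    replicate = rep(seq_len(v$n), 2),
    od450 = c(rnorm(v$n, v$vehicle_mean * v$effect, v$noise_sd),
              rnorm(v$n, v$vehicle_mean, v$noise_sd)),
    stringsAsFactors = FALSE)

  a <- eff$apoptosis
  apoptosis <- do.call(rbind, lapply(names(a$means), function(g)
    data.frame(group = g, experiment = seq_len(a$n),
               fraction = pmin(1, pmax(0, rnorm(a$n, a$means[[g]],
                                                a$noise_sd))),
               stringsAsFactors = FALSE)))

  co <- eff$colony
  colony <- data.frame(
    group = rep(c("a", "b"), each = co$n),
    replicate = rep(seq_len(co$n), 2),
    count = pmax(0, round(c(rnorm(co$n, co$mean_a, co$noise_sd),
                            rnorm(co$n, co$mean_b, co$noise_sd)))),
    stringsAsFactors = FALSE)

  x <- eff$xenograft
  xeno <- do.call(rbind, lapply(c("A", "B"), function(arm) {
    do.call(rbind, lapply(seq_len(x$n), function(m) {
      base <- x$base_volume_day7 *
        2^((x$days - x$days[1]) / x$doubling_days)
      vol <- base * (if (arm == "A") x$ratio else 1) *
        exp(rnorm(length(x$days), 0, x$sigma))
      minor <- (6 * vol / (pi * x$aspect))^(1 / 3)
      data.frame(arm = arm, mouse = sprintf("%s%d", arm, m), day = x$days,
                 major_mm = x$aspect * minor, minor_mm = minor,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(viability = viability, apoptosis = apoptosis, colony = colony,
       xenograft = xeno, truth = eff)
}
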