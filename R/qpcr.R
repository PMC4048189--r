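# qPCR relative quantification: -dCt levels, ddCt fold changes with the
# beta-actin endogenous reference, paired specimen surveys and siRNA
# knockdown QC. Amplification efficiency is fixed at perfect doubling
# (2 per cycle); replicate means are arithmetic on the Ct scale.

#' Relative expression levels per observation
#'
#' For each (sample, condition) observation: `delta_ct` = mean target Ct -
#' mean reference Ct, `neg_delta_ct` = -delta_ct (higher means more
#' transcript relative to beta-actin), `rel_level` = `2^(-delta_ct)`.
#' A replicate spread above 1.5 cycles within target or reference triggers
#' a QC warning but is not fatal.
#'
#' @param qe a [QpcrExperiment].
#' @return data.frame with columns `sample_id`, `condition`, `delta_ct`,
#'   `neg_delta_ct`, `rel_level`.
#' @export
relativeLevel <- function(qe) {
  obs <- qpcrObservations(qe)
  key <- unique(obs[, c("sample_id", "condition")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- obs$sample_id == key$sample_id[i] & obs$condition == key$condition[i]
    tg <- obs$ct[sel & obs$gene_role == "target"]
    rf <- obs$ct[sel & obs$gene_role == "reference"]
    if (diff(range(tg)) > 1.5 || diff(range(rf)) > 1.5)
      warning(sprintf("QC: Ct replicate spread > 1.5 cycles for %s/%s",
                      key$sample_id[i], key$condition[i]))
    dct <- mean(tg) - mean(rf)
    data.frame(sample_id = key$sample_id[i], condition = key$condition[i],
               delta_ct = dct, neg_delta_ct = -dct, rel_level = 2^(-dct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expression fold between two conditions (ddCt)
#'
#' Fold of condition A over condition B from per-observation relative
#' levels: `fold = mean(rel_A) / mean(rel_B)`; the accompanying standard
#' deviation is that of the per-observation A ratios against the fixed mean
#' of B, matching the single `fold +/- s.d.` cell format used for
#' resistant-versus-parental comparisons. The p-value is a two-tailed
#' pooled-variance Student's t on the -dCt values, which are closer to
#' normal than the ratios themselves.
#'
#' @param qe a [QpcrExperiment].
#' @param conditionA,conditionB condition labels present in `qe`.
#' @return list with `fold`, `sd`, `p_value`, `zero_variance`, `n_A`, `n_B`.
#' @export
foldBetweenConditions <- function(qe, conditionA, conditionB) {
  lev <- relativeLevel(qe)
  a <- lev[lev$condition == conditionA, , drop = FALSE]
  b <- lev[lev$condition == conditionB, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    msError("need at least 2 observations per condition",
            "mitoscreen_insufficient_data_error")
  meanB <- mean(b$rel_level)
  ratios <- a$rel_level / meanB
  tt <- tTestPooled(a$neg_delta_ct, b$neg_delta_ct)
  list(fold = mean(a$rel_level) / meanB, sd = sd(ratios),
       p_value = tt$p_value, zero_variance = tt$zero_variance,
       n_A = nrow(a), n_B = nrow(b))
}

#' Paired tumor/adjacent specimen survey
#'
#' For every specimen pair, the tumor-over-adjacent fold
#' `2^(negDeltaCt_tumor - negDeltaCt_adjacent)` and the up-regulation call
#' `fold >= callFoldThreshold`. Reports the number and percentage of
#' up-regulated specimens (half-up rounded to one decimal, so 46 of 53
#' prints 86.8) and box-plot statistics (median, quartiles, extremes) of
#' the -dCt values per group.
#'
#' @param qe a [QpcrExperiment] whose conditions include the two group
#'   labels; pairs are matched on `sample_id`.
#' @param callFoldThreshold linear fold needed (inclusive) to call a pair
#'   up-regulated; default 2.
#' @param tumorCondition,adjacentCondition condition labels; defaults
#'   `"tumor"` and `"adjacent"`.
#' @return list with `pairs` (per-pair `sample_id`, `fold`, `call`),
#'   `n_up`, `n_total`, `percent_up`, and `box_stats` (per group: median,
#'   q25, q75, min, max of -dCt).
#' @export
specimenSurvey <- function(qe, callFoldThreshold = 2,
                           tumorCondition = "tumor",
                           adjacentCondition = "adjacent") {
  lev <- relativeLevel(qe)
  tum <- lev[lev$condition == tumorCondition, , drop = FALSE]
  adj <- lev[lev$condition == adjacentCondition, , drop = FALSE]
  if (nrow(tum) == 0)
    msError("no tumor observations", "mitoscreen_pairing_error")
  if (!setequal(tum$sample_id, adj$sample_id))
    msError(sprintf("unmatched specimen pair id(s): %s",
                    paste(union(setdiff(tum$sample_id, adj$sample_id),
                                setdiff(adj$sample_id, tum$sample_id)),
                          collapse = ", ")),
            "mitoscreen_pairing_error")
  adj <- adj[match(tum$sample_id, adj$sample_id), ]
  fold <- 2^(tum$neg_delta_ct - adj$neg_delta_ct)
  call <- fold >= callFoldThreshold
  boxOf <- function(x) c(median = median(x),
                         q25 = unname(quantile(x, 0.25)),
                         q75 = unname(quantile(x, 0.75)),
                         min = min(x), max = max(x))
  list(pairs = data.frame(sample_id = tum$sample_id, fold = fold,
                          call = call, stringsAsFactors = FALSE),
       n_up = sum(call), n_total = length(call),
       percent_up = roundHalfUp(100 * sum(call) / length(call), 1),
       box_stats = list(tumor = boxOf(tum$neg_delta_ct),
                        adjacent = boxOf(adj$neg_delta_ct)))
}

#' siRNA knockdown efficiency QC
#'
#' Remaining target mRNA after knockdown, relative to the negative-control
#' siRNA: `mean(rel_level_si) / mean(rel_level_nc)`. The QC passes only
#' when the remaining fraction is strictly below `maxRemaining`;
#' a fraction exactly at the bound fails.
#'
#' @param qe a [QpcrExperiment].
#' @param siCondition,ncCondition condition labels of the silenced and
#'   negative-control observations.
#' @param maxRemaining strict upper bound on the remaining fraction;
#'   default 0.60.
#' @return list with `remaining_fraction` and `pass`.
#' @export
knockdownQC <- function(qe, siCondition = "si", ncCondition = "nc",
                        maxRemaining = 0.60) {
  lev <- relativeLevel(qe)
  si <- lev$rel_level[lev$condition == siCondition]
  nc <- lev$rel_level[lev$condition == ncCondition]
  if (length(si) < 1 || length(nc) < 1)
    msError("need at least 1 observation per condition",
            "mitoscreen_insufficient_data_error")
  remaining <- mean(si) / mean(nc)
  list(remaining_fraction = remaining, pass = remaining < maxRemaining)
}

#' Read qPCR observations from TSV
#'
#' @param path TSV with columns `sample_id`, `condition`, `gene_role`
#'   (`target`/`reference`), `replicate`, `ct`.
#' @return a [QpcrExperiment].
#' @export
readQpcrTable <- function(path) {
  QpcrExperiment(readTsv(path))
}

#' Write qPCR observations to TSV
#'
#' @param qe a [QpcrExperiment].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeQpcrTable <- function(qe, path) {
  writeTsv(qpcrObservations(qe), path)
  invisible(path)
}
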