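# Phenotype-assay statistics: CCK-8 viability (OD450), siRNA
# proliferation-hit calling, annexin apoptosis fractions, soft-agar colony
# counts, and xenograft growth from caliper measurements. All comparisons
# use the two-tailed pooled-variance Student's t, with the pipeline-wide
# zero-variance convention (p = 1, flagged).

#' Relative cell viability from OD450 readings
#'
#' Percent viability of a treated group against a vehicle (e.g. DMSO)
#' control: `100 * mean(treated) / mean(vehicle)`, with the s.d. of the
#' per-replicate treated ratios against the fixed vehicle mean, and a
#' two-tailed pooled-variance t on the raw absorbances.
#'
#' @param treated,vehicle numeric OD450 replicate vectors (>= 2 each, > 0).
#' @return list with `percent`, `sd`, `p_value`, `zero_variance`.
#' @export
relativeViability <- function(treated, vehicle) {
  if (length(treated) < 2 || length(vehicle) < 2)
    msError("need at least 2 OD450 replicates per group",
            "mitoscreen_insufficient_data_error")
  if (any(treated <= 0) || any(vehicle <= 0))
    msError("OD450 absorbances must be positive",
            "mitoscreen_validation_error")
  tt <- tTestPooled(treated, vehicle)
  list(percent = 100 * mean(treated) / mean(vehicle),
       sd = 100 * sd(treated / mean(vehicle)),
       p_value = tt$p_value, zero_variance = tt$zero_variance)
}

#' Proliferation hit call from siRNA viability
#'
#' A gene knockdown counts as an inhibitory hit when the relative viability
#' against the negative-control siRNA falls strictly below the threshold;
#' exactly 75 percent is not a hit.
#'
#' @param percentViability relative viability in percent (>= 0).
#' @param thresholdPercent strict threshold; default 75.
#' @return logical hit call.
#' @export
proliferationHitCall <- function(percentViability, thresholdPercent = 75) {
  if (any(percentViability < 0))
    msError("viability percent must be non-negative",
            "mitoscreen_validation_error")
  percentViability < thresholdPercent
}

#' Apoptosis summary from annexin-positive fractions
#'
#' Mean and standard deviation of the annexin-positive percentage per
#' group over independent experiments, with pairwise two-tailed
#' pooled-variance t tests between groups.
#'
#' @param groups named list of numeric vectors of annexin-positive
#'   fractions in `[0, 1]`, one value per independent experiment (>= 2
#'   each).
#' @return list with `summary` (data.frame group, `mean_percent`,
#'   `sd_percent`, `n`) and `pairwise` (data.frame `group_a`, `group_b`,
#'   `p_value`, `zero_variance`).
#' @export
apoptosisSummary <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  for (g in names(groups)) {
    x <- groups[[g]]
    if (any(x < 0 | x > 1))
      msError(sprintf("group '%s': annexin-positive fractions must lie in [0, 1]", g),
              "mitoscreen_validation_error")
    if (length(x) < 2)
      msError(sprintf("group '%s': need at least 2 experiments", g),
              "mitoscreen_insufficient_data_error")
  }
  summary <- data.frame(
    group = names(groups),
    mean_percent = vapply(groups, function(x) 100 * mean(x), 0),
    sd_percent = vapply(groups, function(x) 100 * sd(x), 0),
    n = lengths(groups), row.names = NULL, stringsAsFactors = FALSE)
  pairs <- if (length(groups) >= 2) t(utils::combn(names(groups), 2)) else
    matrix(character(0), 0, 2)
  pairwise <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    tt <- tTestPooled(groups[[pairs[i, 1]]], groups[[pairs[i, 2]]])
    data.frame(group_a = pairs[i, 1], group_b = pairs[i, 2],
               p_value = tt$p_value, zero_variance = tt$zero_variance,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Compare soft-agar colony counts between two groups
#'
#' Counts are assumed already filtered by the colony-size rule (only
#' colonies of at least `minCellsPerColony` cells counted); the rule is
#' recorded in the output as metadata.
#'
#' @param groupA,groupB non-negative integer colony counts (>= 2
#'   replicates each).
#' @param minCellsPerColony size rule used upstream; default 50.
#' @return list with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `p_value`,
#'   `zero_variance`, `min_cells_per_colony`.
#' @export
colonyCompare <- function(groupA, groupB, minCellsPerColony = 50) {
  for (x in list(groupA, groupB)) {
    if (any(x < 0) || any(x != floor(x)))
      msError("colony counts must be non-negative integers",
              "mitoscreen_validation_error")
  }
  if (length(groupA) < 2 || length(groupB) < 2)
    msError("need at least 2 replicates per group",
            "mitoscreen_insufficient_data_error")
  tt <- tTestPooled(groupA, groupB)
  list(mean_a = mean(groupA), mean_b = mean(groupB),
       sd_a = sd(groupA), sd_b = sd(groupB),
       p_value = tt$p_value, zero_variance = tt$zero_variance,
       min_cells_per_colony = minCellsPerColony)
}

#' Ellipsoid tumor volume from caliper axes
#'
#' `volume = pi/6 * major * minor^2` in cubic millimetres, the standard
#' two-axis caliper approximation (a sphere when major = minor).
#'
#' @param majorMm,minorMm perpendicular axis lengths in mm (vectors
#'   allowed); requires `majorMm >= minorMm > 0`.
#' @return volume(s) in mm^3.
#' @export
tumorVolume <- function(majorMm, minorMm) {
  if (any(minorMm <= 0) || any(majorMm <= 0))
    msError("caliper axes must be positive", "mitoscreen_validation_error")
  if (any(minorMm > majorMm))
    msError("minor axis exceeds major axis (axis order error)",
            "mitoscreen_axis_order_error")
  pi / 6 * majorMm * minorMm^2
}

#' Compare xenograft growth curves between two arms
#'
#' Converts per-mouse caliper series to ellipsoid volumes, summarizes each
#' measurement day per arm (mean +/- sd) with a per-day two-tailed
#' pooled-variance t, and reports endpoint (last shared day) summaries,
#' optionally with a tumor-weight comparison.
#'
#' @param armA,armB data.frames with columns `mouse`, `day`, `major_mm`,
#'   `minor_mm` (>= 2 mice per arm; both arms measured on the same days).
#' @param weightsA,weightsB optional endpoint tumor weights per mouse.
#' @return list with `per_day` (data.frame `day`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `p_value`, `zero_variance`), `endpoint`
#'   (`day`, means, `ratio`, `p_value`), and `weights` (`p_value`,
#'   `zero_variance`) when weights are given.
#' @export
growthCurveCompare <- function(armA, armB, weightsA = NULL, weightsB = NULL) {
  need <- c("mouse", "day", "major_mm", "minor_mm")
  stopifnot(all(need %in% colnames(armA)), all(need %in% colnames(armB)))
  if (length(unique(armA$mouse)) < 2 || length(unique(armB$mouse)) < 2)
    msError("need at least 2 mice per arm",
            "mitoscreen_insufficient_data_error")
  if (!setequal(unique(armA$day), unique(armB$day)))
    msError(sprintf("measurement day(s) present in one arm only: %s",
                    paste(union(setdiff(armA$day, armB$day),
                                setdiff(armB$day, armA$day)), collapse = ", ")),
            "mitoscreen_alignment_error")
  armA$volume <- tumorVolume(armA$major_mm, armA$minor_mm)
  armB$volume <- tumorVolume(armB$major_mm, armB$minor_mm)
  days <- sort(unique(armA$day))
  perDay <- do.call(rbind, lapply(days, function(d) {
    va <- armA$volume[armA$day == d]
    vb <- armB$volume[armB$day == d]
    tt <- tTestPooled(va, vb)
    data.frame(day = d, mean_a = mean(va), sd_a = sd(va), n_a = length(va),
               mean_b = mean(vb), sd_b = sd(vb), n_b = length(vb),
               p_value = tt$p_value, zero_variance = tt$zero_variance)
  }))
  last <- perDay[perDay$day == max(days), ]
  out <- list(per_day = perDay,
              endpoint = list(day = max(days), mean_a = last$mean_a,
                              mean_b = last$mean_b,
                              ratio = last$mean_a / last$mean_b,
                              p_value = last$p_value))
  if (!is.null(weightsA) && !is.null(weightsB)) {
    tt <- tTestPooled(weightsA, weightsB)
    out$weights <- list(mean_a = mean(weightsA), mean_b = mean(weightsB),
                        p_value = tt$p_value, zero_variance = tt$zero_variance)
  }
  out
}
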