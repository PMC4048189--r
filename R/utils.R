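# Internal helpers shared across modules.

#' @importFrom stats t.test median sd quantile p.adjust rnorm runif rbinom
NULL

msError <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "mitoscreen_error")))
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; reported percentages here use
#' conventional half-up rounding (so 86.75 prints as 86.8, not 86.8 by
#' accident of the banker's rule).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Two-tailed pooled-variance Student's t test
#'
#' Wrapper around [stats::t.test()] with `var.equal = TRUE` that treats
#' degenerate comparisons as flagged results rather than errors: when the
#' pooled standard deviation is zero (or, paired, the differences are
#' constant) the p-value is 1 if the group means agree and 0 otherwise;
#' when the two groups hold identical values the p-value is 1. Both cases
#' set `zero_variance`. Missing values are dropped before testing.
#'
#' @param x,y numeric vectors of observations for the two groups.
#' @param paired logical; paired test (requires equal lengths).
#' @return list with `statistic`, `df`, `p_value`, `zero_variance`.
#' @export
tTestPooled <- function(x, y, paired = FALSE) {
  if (paired) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2)
      msError("paired t test needs at least 2 complete pairs",
              "mitoscreen_insufficient_data_error")
    d <- x - y
    if (sd(d) == 0) {
      return(list(statistic = NA_real_, df = length(d) - 1,
                  p_value = if (mean(d) == 0) 1 else 0, zero_variance = TRUE))
    }
    tt <- t.test(x, y, paired = TRUE)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, zero_variance = FALSE))
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    msError("t test needs at least 2 non-missing values per group",
            "mitoscreen_insufficient_data_error")
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(statistic = NA_real_, df = length(x) + length(y) - 2,
                p_value = if (mean(x) == mean(y)) 1 else 0,
                zero_variance = TRUE))
  }
  if (length(x) == length(y) && all(sort(x) == sort(y))) {
    return(list(statistic = 0, df = length(x) + length(y) - 2,
                p_value = 1, zero_variance = TRUE))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, zero_variance = FALSE)
}

# Read/write the package's TSV dialect ("NA" for missing, no quoting).
readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}
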