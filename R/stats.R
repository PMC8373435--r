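#' @include brs.R
NULL

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample's own mean and standard deviation.  Used only to document the
#' choice of nonparametric group tests; it never switches the pipeline's
#' test automatically.  With estimated parameters (no Lilliefors
#' correction) the p-values are conservative.
#'
#' @param values numeric vector of length >= 5 with positive spread.
#' @return the KS p-value.
#' @export
ksNormality <- function(values) {
  if (length(values) < 5L) stop("at least 5 values are required")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) sample")
  suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum test: exact null distribution when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie correction (and continuity correction) otherwise.
#'
#' @param a,b numeric vectors (each length >= 3).
#' @return list with \code{statistic} (the Mann-Whitney U of group
#'   \code{a}) and \code{p.value} (two-sided).
#' @examples
#' ranksumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # exact 0.1
#' @export
ranksumTest <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha nominal family-wise level, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return \code{alpha / m} (0.05 over 6 regions gives 0.0083 to 4 dp).
#' @export
bonferroniAlpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

#' Pre-planned between-group comparisons of BRS values
#'
#' For each comparison (default AD vs HC, MCI vs HC, AD vs MCI) and each
#' region (and band subset, if the table carries several), a two-sided
#' Wilcoxon rank-sum test on the chosen BRS value, flagged significant at
#' the Bonferroni-corrected level alpha / (number of regions per
#' comparison).
#'
#' @param brs long BRS table from [computeBrsFeatures()] (columns
#'   \code{participant}, \code{group}, \code{region}, \code{band_set}, and
#'   the value column).
#' @param comparisons list of 2-vectors of group labels; the first label's
#'   median minus the second's is the reported direction.
#' @param value which column to test: \code{"std"} (default) or
#'   \code{"raw"}.
#' @param alpha nominal family-wise level (default 0.05).
#' @return data frame with one row per comparison x region x band set:
#'   \code{comparison}, \code{region}, \code{band_set}, \code{statistic},
#'   \code{p.value}, \code{alpha.corrected}, \code{significant},
#'   \code{median.diff}.
#' @export
compareGroups <- function(brs,
                          comparisons = list(c("AD", "HC"), c("MCI", "HC"),
                                             c("AD", "MCI")),
                          value = c("std", "raw"), alpha = 0.05) {
  value <- match.arg(value)
  for (cmp in comparisons) {
    missing <- setdiff(cmp, unique(brs$group))
    if (length(missing) > 0L)
      stop(sprintf("unknown group label(s): %s", paste(missing, collapse = ", ")))
  }
  regions <- unique(brs$region)
  bandSets <- unique(brs$band_set)
  alphaCorr <- bonferroniAlpha(alpha, length(regions))
  rows <- list()
  for (cmp in comparisons) {
    for (bs in bandSets) {
      for (region in regions) {
        sel <- brs$region == region & brs$band_set == bs
        a <- brs[[value]][sel & brs$group == cmp[1]]
        b <- brs[[value]][sel & brs$group == cmp[2]]
        test <- ranksumTest(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste(cmp, collapse = "-"), region = region,
          band_set = bs, statistic = test$statistic,
          p.value = test$p.value, alpha.corrected = alphaCorr,
          significant = test$p.value < alphaCorr,
          median.diff = stats::median(a) - stats::median(b),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
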