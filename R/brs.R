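#' @include bandpower.R
NULL

BRS_DISTANCE_FLOOR <- 1e-12

#' Between-run similarity of two power-vector series
#'
#' For run-1 vectors \eqn{p_i^1} (i = 1..n) and run-2 vectors \eqn{p_j^2}
#' (j = 1..m), each epoch pair contributes the reciprocal Euclidean distance
#' \eqn{s_{ij} = 1 / \|p_j^2 - p_i^1\|}, and the between-run similarity is
#' the mean over all n x m pairs, \eqn{S = \frac{1}{nm}\sum_i\sum_j s_{ij}}.
#' Zero distances are floored at 1e-12 so the statistic stays finite on
#' degenerate (identical-vector) input; the floor is unreachable on noisy
#' data.  High S means the two runs have similar spectral structure, i.e.
#' low task-induced intra-subject variability.
#'
#' @param P1,P2 [RegionPowerSeries-class] objects for runs 1 and 2 of the
#'   same region and band subset, or plain numeric matrices (epochs x
#'   bands).
#' @return the raw similarity S (positive scalar) with attributes \code{n}
#'   and \code{m} (epoch counts).
#' @examples
#' betweenRunSimilarity(rbind(c(0, 0)), rbind(c(3, 4)))  # 1/5
#' @export
betweenRunSimilarity <- function(P1, P2) {
  if (is(P1, "RegionPowerSeries") && is(P2, "RegionPowerSeries")) {
    if (P1@region != P2@region)
      stop(sprintf("region mismatch: '%s' vs '%s'", P1@region, P2@region))
    if (!identical(P1@bands, P2@bands))
      stop("band-subset mismatch between runs")
    A <- P1@vectors; B <- P2@vectors
  } else {
    A <- as.matrix(P1); B <- as.matrix(P2)
  }
  if (ncol(A) != ncol(B))
    stop(sprintf("power-vector dimension mismatch: %d vs %d", ncol(A), ncol(B)))
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("each run needs at least one epoch")
  n <- nrow(A); m <- nrow(B)
  # direct differences (no expanded-square shortcut): reciprocal distances
  # magnify cancellation error on close epoch pairs
  small <- if (m <= n) B else A
  tBig <- if (m <= n) t(A) else t(B)
  total <- 0
  for (j in seq_len(nrow(small))) {
    d <- sqrt(colSums((tBig - small[j, ])^2))
    total <- total + sum(1 / pmax(d, BRS_DISTANCE_FLOOR))
  }
  S <- total / (n * m)
  attr(S, "n") <- n
  attr(S, "m") <- m
  S
}

#' Standardize raw similarities against the healthy-control group
#'
#' \eqn{S_{std}(i) = (S(i) - mean_{HC}) / sd_{HC}} with the sample (n-1)
#' standard deviation by default.  After standardization the HC group has
#' mean 0 and standard deviation 1 by construction, and patients' values
#' read as deviations from the healthy population in HC standard-deviation
#' units.
#'
#' @param values named numeric vector of raw similarities (names =
#'   participant ids).
#' @param hcIds participant ids forming the healthy-control benchmark; in
#'   \code{mode = "global"} all of them are used (whole-cohort benchmark),
#'   in \code{mode = "fold-train"} only those also listed in
#'   \code{trainIds} (leakage-safe cross-validation variant).
#' @param mode \code{"global"} (default) or \code{"fold-train"}.
#' @param trainIds training-set participant ids, required for
#'   \code{"fold-train"}.
#' @param sdType \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return named numeric vector of standardized similarities.
#' @export
standardizeBrs <- function(values, hcIds, mode = c("global", "fold-train"),
                           trainIds = NULL, sdType = c("sample", "population")) {
  mode <- match.arg(mode)
  sdType <- match.arg(sdType)
  if (is.null(names(values)))
    stop("values must be named by participant id")
  if (mode == "fold-train") {
    if (is.null(trainIds))
      stop("fold-train mode requires trainIds")
    hcIds <- intersect(hcIds, trainIds)
  }
  hcIds <- intersect(hcIds, names(values))
  if (length(hcIds) < 2L)
    stop("at least 2 healthy-control participants are required for standardization")
  hc <- values[hcIds]
  mu <- mean(hc)
  s <- stats::sd(hc)
  if (sdType == "population")
    s <- s * sqrt((length(hc) - 1) / length(hc))
  if (!is.finite(s) || s == 0)
    stop("healthy-control similarities have zero spread; cannot standardize")
  (values - mu) / s
}

#' Raw and standardized BRS for a whole cohort
#'
#' Runs the region-mean power-vector and between-run-similarity steps for
#' every participant and region, then standardizes each region's raw values
#' against the cohort's healthy controls.  With the default six-region
#' montage this yields six similarity values per participant.
#'
#' @param cohort named list, one entry per participant id, each a list with
#'   elements \code{run1} and \code{run2} that are [BandPowerTensor-class]
#'   (or [EpochArray-class], converted via [computeBandPowers()]).
#' @param groups named character vector: participant id -> group label.
#' @param montage a [ScalpMontage-class] (default [defaultMontage()]).
#' @param bands band-scheme data frame (default [defaultBands()]).
#' @param bandNames band subset for per-band similarity, or NULL for the
#'   full scheme.
#' @param hcIds healthy-control ids; defaults to participants labelled
#'   \code{"HC"} in \code{groups}.
#' @param sdType standardization denominator, see [standardizeBrs()].
#' @return data frame with one row per participant x region: columns
#'   \code{participant}, \code{group}, \code{region}, \code{band_set},
#'   \code{n}, \code{m}, \code{raw}, \code{std}.
#' @export
computeBrsFeatures <- function(cohort, groups, montage = defaultMontage(),
                               bands = defaultBands(), bandNames = NULL,
                               hcIds = NULL, sdType = "sample") {
  if (length(cohort) == 0L) stop("empty cohort")
  ids <- names(cohort)
  if (is.null(ids)) stop("cohort must be a named list (participant ids)")
  missingRun <- ids[!vapply(cohort, function(p)
    all(c("run1", "run2") %in% names(p)), logical(1))]
  if (length(missingRun) > 0L)
    stop(sprintf("participant(s) missing a run: %s",
                 paste(missingRun, collapse = ", ")))
  if (is.null(hcIds)) hcIds <- ids[groups[ids] == "HC"]
  bandSet <- if (is.null(bandNames)) "all" else paste(bandNames, collapse = "+")
  asTensor <- function(x) {
    if (is(x, "EpochArray")) computeBandPowers(x, bands) else x
  }
  rows <- list()
  for (id in ids) {
    bp1 <- asTensor(cohort[[id]]$run1)
    bp2 <- asTensor(cohort[[id]]$run2)
    for (region in regionNames(montage)) {
      P1 <- regionPowerSeries(bp1, montage, region, bandNames)
      P2 <- regionPowerSeries(bp2, montage, region, bandNames)
      S <- betweenRunSimilarity(P1, P2)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, group = unname(groups[id]), region = region,
        band_set = bandSet, n = attr(S, "n"), m = attr(S, "m"),
        raw = as.numeric(S), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$std <- NA_real_
  for (region in unique(res$region)) {
    sel <- res$region == region
    v <- stats::setNames(res$raw[sel], res$participant[sel])
    res$std[sel] <- as.numeric(standardizeBrs(v, hcIds, sdType = sdType))
  }
  res
}

#' BRS features from pre-computed region power series
#'
#' Same output as [computeBrsFeatures()] but starting from the power-vector
#' level (as produced by [simulatePowerVectors()]): each participant entry
#' is a named list of regions, each holding matrices \code{run1} and
#' \code{run2}.
#'
#' @param series named list: participant -> region -> list(run1, run2)
#'   epoch x band matrices.
#' @param groups named character vector: participant id -> group label.
#' @param hcIds healthy-control ids (default: groups == "HC").
#' @param sdType standardization denominator, see [standardizeBrs()].
#' @return data frame as in [computeBrsFeatures()].
#' @export
brsFromPowerVectors <- function(series, groups, hcIds = NULL,
                                sdType = "sample") {
  ids <- names(series)
  if (is.null(ids) || length(ids) == 0L) stop("empty power-vector series")
  if (is.null(hcIds)) hcIds <- ids[groups[ids] == "HC"]
  rows <- list()
  for (id in ids) {
    for (region in names(series[[id]])) {
      pair <- series[[id]][[region]]
      S <- betweenRunSimilarity(pair$run1, pair$run2)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, group = unname(groups[id]), region = region,
        band_set = "all", n = attr(S, "n"), m = attr(S, "m"),
        raw = as.numeric(S), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$std <- NA_real_
  for (region in unique(res$region)) {
    sel <- res$region == region
    v <- stats::setNames(res$raw[sel], res$participant[sel])
    res$std[sel] <- as.numeric(standardizeBrs(v, hcIds, sdType = sdType))
  }
  res
}

#' Wide participant x region feature matrix from long BRS results
#'
#' @param brs data frame from [computeBrsFeatures()] /
#'   [brsFromPowerVectors()].
#' @param value \code{"std"} (default) or \code{"raw"}.
#' @param regionOrder column order (default: order of appearance).
#' @return list with \code{X} (participants x regions matrix), \code{y}
#'   (named group-label vector).
#' @export
brsFeatureMatrix <- function(brs, value = c("std", "raw"),
                             regionOrder = NULL) {
  value <- match.arg(value)
  if (is.null(regionOrder)) regionOrder <- unique(brs$region)
  ids <- unique(brs$participant)
  X <- matrix(NA_real_, nrow = length(ids), ncol = length(regionOrder),
              dimnames = list(ids, regionOrder))
  for (k in seq_len(nrow(brs)))
    X[brs$participant[k], brs$region[k]] <- brs[[value]][k]
  if (anyNA(X)) stop("incomplete BRS table: some participant x region missing")
  y <- stats::setNames(brs$group[match(ids, brs$participant)], ids)
  list(X = X, y = y)
}
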