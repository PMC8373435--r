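#' @include AllClasses.R
NULL

FEATURE_COLUMNS <- c("participant", "group", "region", "band_set",
                     "feature", "value")

#' Write a long-format feature/result table
#'
#' Writes one row per participant x region x feature with the fixed column
#' set \code{participant, group, region, band_set, feature, value}.  Rows
#' are ordered deterministically: by participant id, then by region in the
#' order given (montage order), then by feature name.  Values are kept to 12
#' significant digits in CSV.
#'
#' @param records data frame containing at least the fixed columns.
#' @param path output path.
#' @param format \code{"csv"} (default) or \code{"json"}.
#' @param regionOrder optional character vector fixing the region sort order
#'   (e.g. \code{regionNames(defaultMontage())}); unknown regions sort last.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(records, path, format = c("csv", "json"),
                              regionOrder = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame")
  missing <- setdiff(FEATURE_COLUMNS, names(records))
  if (length(missing) > 0L)
    stop(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  records <- records[, FEATURE_COLUMNS, drop = FALSE]
  regionKey <- if (is.null(regionOrder)) records$region else {
    factor(records$region, levels = c(regionOrder,
                                      setdiff(unique(records$region), regionOrder)))
  }
  ord <- order(records$participant, regionKey, records$feature)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  if (format == "csv") {
    out <- records
    out$value <- formatC(out$value, digits = 12, format = "g")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a feature/result table written by [writeFeatureTable()]
#'
#' @param path CSV or JSON path (format inferred from the extension).
#' @return data frame with the fixed feature-table columns.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(FEATURE_COLUMNS, names(tab))
  if (length(missing) > 0L)
    stop(sprintf("table lacks column(s): %s", paste(missing, collapse = ", ")))
  tab$value <- as.numeric(tab$value)
  tab
}
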