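#' @include AllClasses.R
NULL

#' Default spectral band scheme
#'
#' The seven canonical bands used throughout the pipeline: delta 1-4 Hz,
#' theta 4-8, low alpha 8-10, high alpha 10-13, low beta 13-20, high beta
#' 20-30, gamma 30-45.  The row order is fixed and defines the component
#' order of every power vector.  Band intervals are half-open
#' \code{[low, high)} so shared edges (4, 8, 10, 13, 20, 30 Hz) are counted
#' exactly once.
#'
#' @return data frame with columns \code{name}, \code{low}, \code{high}
#'   (Hz), one row per band.
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  data.frame(
    name = c("delta", "theta", "low_alpha", "high_alpha",
             "low_beta", "high_beta", "gamma"),
    low  = c(1, 4, 8, 10, 13, 20, 30),
    high = c(4, 8, 10, 13, 20, 30, 45),
    stringsAsFactors = FALSE)
}

#' Validate a band-scheme data frame
#'
#' @param bands data frame with columns \code{name}, \code{low}, \code{high}.
#' @return the validated data frame, invisibly usable downstream.
#' @keywords internal
validateBands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands)))
    stop("bands must be a data frame with columns name, low, high")
  if (nrow(bands) < 1L)
    stop("band scheme must contain at least one band")
  if (anyDuplicated(bands$name))
    stop("duplicate band names")
  if (any(!is.finite(bands$low)) || any(!is.finite(bands$high)) ||
      any(bands$low >= bands$high) || any(bands$low < 0))
    stop("each band needs 0 <= low < high")
  bands
}

#' Restrict a band scheme to a subset, preserving scheme order
#'
#' @param bands band-scheme data frame.
#' @param subset character vector of band names, or NULL for all bands.
#' @return the subset rows of \code{bands}, in scheme order.
#' @examples
#' bandSubset(defaultBands(), "low_beta")
#' @export
bandSubset <- function(bands, subset = NULL) {
  bands <- validateBands(bands)
  if (is.null(subset)) return(bands)
  missing <- setdiff(subset, bands$name)
  if (length(missing) > 0L)
    stop(sprintf("unknown band(s): %s", paste(missing, collapse = ", ")))
  bands[bands$name %in% subset, , drop = FALSE]
}
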