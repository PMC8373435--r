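#' @include AllClasses.R
NULL

#' Default 30-electrode, six-region scalp montage
#'
#' International 10-20 layout divided into six scalp regions: frontal (FP1,
#' FP2, F3, F4, F7, F8, Fz), central (FC3, FC4, FCz, C3, C4, Cz), parietal
#' (CP3, CP4, CPz, P3, P4, Pz), occipital (O1, O2, Oz), left temporal (FT7,
#' T3, TP7, T5) and right temporal (FT8, T4, TP8, T6).
#'
#' The third occipital electrode defaults to Oz so the montage has 30 unique
#' electrodes; \code{occipitalThird = "Cz"} keeps Cz there instead (in which
#' case Cz belongs to both the central and occipital regions and the montage
#' covers 29 unique electrodes).
#'
#' @param occipitalThird \code{"Oz"} (default) or \code{"Cz"}.
#' @return a [ScalpMontage-class] object.
#' @examples
#' defaultMontage()
#' @export
defaultMontage <- function(occipitalThird = c("Oz", "Cz")) {
  occipitalThird <- match.arg(occipitalThird)
  new("ScalpMontage", regions = list(
    frontal        = c("FP1", "FP2", "F3", "F4", "F7", "F8", "Fz"),
    central        = c("FC3", "FC4", "FCz", "C3", "C4", "Cz"),
    parietal       = c("CP3", "CP4", "CPz", "P3", "P4", "Pz"),
    occipital      = c("O1", "O2", occipitalThird),
    left_temporal  = c("FT7", "T3", "TP7", "T5"),
    right_temporal = c("FT8", "T4", "TP8", "T6")))
}

#' Load a scalp montage from a YAML file
#'
#' The file maps region names to electrode lists, e.g.
#' \preformatted{frontal: [FP1, FP2, Fz]
#' occipital: [O1, O2, Oz]}
#' A missing path (NULL) returns [defaultMontage()].
#'
#' @param path YAML file path, or NULL for the built-in default.
#' @param occipitalThird passed to [defaultMontage()] when \code{path} is NULL.
#' @return a [ScalpMontage-class] object.
#' @export
loadMontage <- function(path = NULL, occipitalThird = "Oz") {
  if (is.null(path))
    return(defaultMontage(occipitalThird))
  if (!file.exists(path))
    stop(sprintf("montage file not found: %s", path))
  spec <- yaml::read_yaml(path)
  if (!is.list(spec) || length(spec) == 0L)
    stop("montage file must map at least one region to an electrode list")
  regions <- lapply(spec, function(x) as.character(unlist(x)))
  new("ScalpMontage", regions = regions)  # validity enforces uniqueness
}

#' Write a montage to a YAML file
#'
#' @param montage a [ScalpMontage-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMontage <- function(montage, path) {
  stopifnot(is(montage, "ScalpMontage"))
  yaml::write_yaml(lapply(montage@regions, as.list), path)
  invisible(path)
}

#' All electrodes of a montage, in region order
#'
#' @param montage a [ScalpMontage-class].
#' @param unique drop duplicates across regions (default TRUE).
#' @return character vector of electrode names.
#' @export
montageElectrodes <- function(montage, unique = TRUE) {
  el <- unlist(montage@regions, use.names = FALSE)
  if (unique) el <- base::unique(el)
  el
}
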