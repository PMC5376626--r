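#' Default configuration for the benchmarking pipeline
#'
#' Central place for the artifact constants that are not part of the root
#' growth model itself: rendering resolution, noise densities, binarization
#' threshold and clean-up sizes for the descriptor extractor, and the path
#' to the parameter-sampling intervals file.
#'
#' @param ... named overrides for individual entries.
#' @return A named list with components:
#'   \describe{
#'     \item{dpi}{rendering resolution in dots per inch (default 300).}
#'     \item{margin_mm}{white margin added around the root system when
#'       rendering (default 2 mm).}
#'     \item{noise_fractions}{named vector of pixel fractions flipped by the
#'       salt-and-pepper filter for levels \code{medium} and \code{high}.}
#'     \item{threshold}{global intensity threshold separating foreground
#'       (dark roots) from background (default 128).}
#'     \item{despeckle_px}{connected components smaller than this pixel area
#'       are removed before measuring (default 4).}
#'     \item{default_diameter_mm}{diameter assigned to RSML nodes that carry
#'       no diameter annotation (default 0.1).}
#'     \item{exploration_inverse}{if TRUE report projected-area / hull-area
#'       (the "solidity" direction) instead of hull/area.}
#'     \item{diam_from_distance_map}{reserved switch for estimating mean
#'       diameter from a distance transform instead of area/skeleton-length;
#'       the area-based estimator is the implemented default.}
#'     \item{sampling_file}{path to the JSON file of sampling intervals.}
#'   }
#' @export
rootbench_config <- function(...) {
  cfg <- list(
    dpi = 300,
    margin_mm = 2,
    noise_fractions = c(medium = 0.05, high = 0.15),
    threshold = 128,
    despeckle_px = 4,
    default_diameter_mm = 0.1,
    exploration_inverse = FALSE,
    diam_from_distance_map = FALSE,
    sampling_file = system.file("extdata", "sampling_intervals.json",
                                package = "rootbench")
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Load parameter-sampling intervals
#'
#' Reads the versioned JSON file holding, per plant type, the uniform
#' sampling interval of every growth-model parameter.
#'
#' @param file path to the intervals file; defaults to the file shipped with
#'   the package.
#' @return A named list with elements \code{fibrous} and \code{tap}, each a
#'   named list of length-2 numeric ranges.
#' @export
sampling_intervals <- function(file = rootbench_config()$sampling_file) {
  if (!file.exists(file)) stop("sampling intervals file not found: ", file)
  iv <- jsonlite::read_json(file, simplifyVector = TRUE)
  iv$version <- NULL
  iv$comment <- NULL
  iv
}
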