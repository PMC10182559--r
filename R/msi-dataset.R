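#' MSI dataset container
#'
#' Holds a raster of pixels with integer grid coordinates, the acquisition
#' (scan) order, and one centroided spectrum per pixel. The coordinate
#' convention everywhere in this package is 0-based, `x` = column growing
#' left to right, `y` = row growing top to bottom.
#'
#' @param pixels `data.frame` with columns `pixel_id`, `x`, `y`,
#'   `scan_index`; `(x, y)` unique, `scan_index` a permutation of
#'   `0..N-1`.
#' @param spectra List (length = pixels) of lists with numeric `mz`
#'   (ascending) and `intensity` (non-negative) of equal length.
#' @param metadata List; recognised entries `step_um` (pixel pitch,
#'   default 75), `mass_range` (default `c(500, 3000)`), `mode`
#'   (`"processed"` or `"continuous"`).
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(pixels, spectra, metadata = list()) {
  stopifnot(is.data.frame(pixels),
            all(c("pixel_id", "x", "y", "scan_index") %in% colnames(pixels)),
            is.list(spectra), length(spectra) == nrow(pixels))
  if (anyDuplicated(pixels[, c("x", "y")]))
    stop("duplicate (x, y) pixel coordinates")
  if (!setequal(pixels$scan_index, seq_len(nrow(pixels)) - 1L))
    stop("scan_index must be a permutation of 0..N-1")
  md <- utils::modifyList(
    list(step_um = 75, mass_range = c(500, 3000), mode = "processed"),
    metadata)
  ds <- structure(list(pixels = pixels, spectra = spectra, metadata = md),
                  class = "msi_dataset")
  validate_msi_dataset(ds)
  ds
}

validate_msi_dataset <- function(ds) {
  for (i in seq_along(ds$spectra)) {
    sp <- ds$spectra[[i]]
    if (length(sp$mz) != length(sp$intensity))
      stop("pixel ", ds$pixels$pixel_id[i], ": mz/intensity length mismatch")
    if (length(sp$mz) > 1L && is.unsorted(sp$mz, strictly = FALSE))
      stop("pixel ", ds$pixels$pixel_id[i], ": m/z not ascending")
    if (any(sp$intensity < 0))
      stop("pixel ", ds$pixels$pixel_id[i], ": negative intensity")
  }
  invisible(ds)
}

#' @export
print.msi_dataset <- function(x, ...) {
  np <- nrow(x$pixels)
  npk <- sum(vapply(x$spectra, function(s) length(s$mz), integer(1)))
  cat(sprintf(
    "<msi_dataset> %d pixels (%d x %d grid), %d centroids, %s mode, %g um step\n",
    np, length(unique(x$pixels$x)), length(unique(x$pixels$y)), npk,
    x$metadata$mode, x$metadata$step_um))
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param ds An `msi_dataset`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(ds) nrow(ds$pixels)
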