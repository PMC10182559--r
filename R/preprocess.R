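#' Lock-mass recalibration configuration
#'
#' @param lock_mz Lock-mass m/z, Da (default the N-glycan lock ion
#'   1257.4296 used for carbohydrate imaging).
#' @param tolerance Search window around the lock mass, Da (> 0).
#' @param min_counts Minimum lock-peak intensity for a pixel to contribute
#'   to the shift estimate, counts.
#' @param time_bin Scan-index span pooled into one shift estimate.
#' @return A `recalibration_config` list.
#' @export
recalibration_config <- function(lock_mz = 1257.4296, tolerance = 1.0,
                                 min_counts = 1e5, time_bin = 64L) {
  if (!(tolerance > 0)) stop("tolerance must be > 0")
  if (!(min_counts >= 0)) stop("min_counts must be >= 0")
  if (!(time_bin >= 1)) stop("time_bin must be >= 1")
  structure(list(lock_mz = lock_mz, tolerance = tolerance,
                 min_counts = min_counts, time_bin = as.integer(time_bin)),
            class = "recalibration_config")
}

#' Recalibrate the m/z axis against the lock mass
#'
#' For each time bin (a span of `time_bin` consecutive scan indices) the
#' mass shift is the median of (observed lock m/z - lock m/z) over pixels
#' whose lock peak lies within `tolerance` Da and has intensity at least
#' `min_counts`; every centroid m/z in that bin is then shifted by the
#' negative of the estimate. Bins with no qualifying pixel inherit the
#' nearest qualifying bin's shift (reported in the shift table). The
#' median makes the estimate robust to lock-peak dropouts.
#'
#' @param ds An [msi_dataset()].
#' @param cfg A [recalibration_config()].
#' @return List with `dataset` (recalibrated) and `shifts` (`data.frame`
#'   of `bin`, `scan_from`, `scan_to`, `shift_da`, `n_pixels`,
#'   `inherited`).
#' @export
recalibrate <- function(ds, cfg = recalibration_config()) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(cfg, "recalibration_config"))
  n <- n_pixels(ds)
  bin_of <- ds$pixels$scan_index %/% cfg$time_bin
  bins <- sort(unique(bin_of))

  observed <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sp <- ds$spectra[[i]]
    in_win <- which(abs(sp$mz - cfg$lock_mz) <= cfg$tolerance &
                    sp$intensity >= cfg$min_counts)
    if (length(in_win)) {
      j <- in_win[which.max(sp$intensity[in_win])]
      observed[i] <- sp$mz[j]
    }
  }
  if (all(is.na(observed)))
    stop("cannot calibrate: no lock-mass peak above ", cfg$min_counts,
         " counts within ", cfg$tolerance, " Da of ", cfg$lock_mz,
         " in any pixel")

  shift <- vapply(bins, function(b) {
    v <- observed[bin_of == b]
    stats::median(v[!is.na(v)] - cfg$lock_mz)
  }, numeric(1))
  n_qual <- vapply(bins, function(b) sum(!is.na(observed[bin_of == b])),
                   integer(1))
  inherited <- is.na(shift)
  if (any(inherited)) {
    ok <- which(!inherited)
    for (b in which(inherited))
      shift[b] <- shift[ok[which.min(abs(bins[ok] - bins[b]))]]
  }

  out <- ds
  for (i in seq_len(n)) {
    s <- shift[match(bin_of[i], bins)]
    out$spectra[[i]]$mz <- out$spectra[[i]]$mz - s
  }
  shifts <- data.frame(bin = bins,
                       scan_from = bins * cfg$time_bin,
                       scan_to = pmin((bins + 1L) * cfg$time_bin - 1L,
                                      max(ds$pixels$scan_index)),
                       shift_da = shift, n_pixels = n_qual,
                       inherited = inherited)
  list(dataset = out, shifts = shifts)
}

#' Integrate panel peaks into a raw feature matrix
#'
#' For every pixel and panel target, sums centroid intensity within the
#' panel window (`|m/z - target| <= window_halfwidth`, default 0.4 Da so
#' the full window stays under 1 Da). The per-pixel total ion current
#' (TIC) is the sum of *all* centroid intensities in the spectrum, not
#' only panel windows. Pixels with empty spectra get a zero row and are
#' flagged.
#'
#' @param ds A (recalibrated) [msi_dataset()].
#' @param panel A [peak_panel()].
#' @return A `feature_matrix`: list with `values` (pixels x features,
#'   feature labels as column names), `tic`, `normalized = FALSE`,
#'   `panel`, `pixels` (coordinate frame), `flagged_empty` (pixel ids).
#' @export
integrate_panel <- function(ds, panel) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(panel, "peak_panel"))
  hw <- attr(panel, "window_halfwidth")
  n <- n_pixels(ds)
  values <- matrix(0, nrow = n, ncol = nrow(panel),
                   dimnames = list(ds$pixels$pixel_id, panel$label))
  tic <- numeric(n)
  empty <- integer(0)
  for (i in seq_len(n)) {
    sp <- ds$spectra[[i]]
    if (length(sp$mz) == 0L) { empty <- c(empty, ds$pixels$pixel_id[i]); next }
    tic[i] <- sum(sp$intensity)
    lo <- findInterval(panel$target_mz - hw, sp$mz)
    hi <- findInterval(panel$target_mz + hw, sp$mz)
    hit <- hi > lo
    if (any(hit)) {
      cs <- c(0, cumsum(sp$intensity))
      values[i, hit] <- cs[hi[hit] + 1L] - cs[lo[hit] + 1L]
    }
  }
  structure(list(values = values, tic = tic, normalized = FALSE,
                 panel = panel, pixels = ds$pixels, flagged_empty = empty),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "TIC-normalized" else "raw counts"))
  invisible(x)
}

#' TIC-normalize a feature matrix
#'
#' Divides each pixel's row by its total ion current so downstream
#' analysis is invariant to per-pixel multiplicative gain. Pixels with
#' zero TIC are dropped (their count is reported in
#' `attr(, "dropped_zero_tic")`). Normalizing twice is an error.
#'
#' @param fm A raw `feature_matrix` from [integrate_panel()].
#' @return A normalized `feature_matrix`.
#' @export
tic_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$normalized) stop("feature matrix is already TIC-normalized")
  keep <- fm$tic > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " pixel(s) with zero TIC dropped")
  out <- fm
  out$values <- fm$values[keep, , drop = FALSE] / fm$tic[keep]
  out$tic <- fm$tic[keep]
  out$pixels <- fm$pixels[keep, , drop = FALSE]
  out$normalized <- TRUE
  attr(out, "dropped_zero_tic") <- dropped
  out
}
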