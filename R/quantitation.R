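#' Per-spot calibration signals from a raw feature matrix
#'
#' Summarises the quantified feature over each calibration spot ROI.
#' The per-pixel mean (default) keeps the fitted slope in the same units
#' as the generating counts-per-ng response; `statistic = "sum"` gives
#' summed spot intensity.
#'
#' @param fm A *raw* (not TIC-normalized) `feature_matrix` of the spots
#'   dataset.
#' @param spot_of Integer spot membership per pixel (NA = background),
#'   e.g. `truth$spot_of` from [make_standard_spots()].
#' @param feature Feature label to quantify (default `"1175"`, the DP 7
#'   rung).
#' @param statistic `"mean"` or `"sum"` over member pixels.
#' @return Numeric vector of spot signals in spot order.
#' @export
spot_signals <- function(fm, spot_of, feature = "1175",
                         statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$normalized)
    stop("quantitation uses raw counts, not TIC-normalized values")
  if (!feature %in% colnames(fm$values))
    stop("feature not in panel: ", feature)
  v <- fm$values[, feature]
  ids <- sort(unique(spot_of[!is.na(spot_of)]))
  f <- if (statistic == "mean") mean else sum
  vapply(ids, function(s) f(v[!is.na(spot_of) & spot_of == s]), numeric(1))
}

#' Fit an on-slide glycogen standard curve
#'
#' Ordinary least squares of signal on spotted amount, intercept
#' estimated; a through-origin slope is reported alongside. The linear
#' range is the widest contiguous span of amounts over which the relative
#' residual (|residual| / fitted) stays below `rel_tol`.
#'
#' @param signals Numeric spot signals (counts).
#' @param amounts Spotted amounts (ng), strictly increasing, length
#'   matching `signals`, at least 3 spots.
#' @param rel_tol Relative-residual bound defining the linear range.
#' @return A `standard_curve`: `slope` (counts/ng), `intercept`,
#'   `r_squared`, `slope_origin`, `amounts`, `signals`, `linear_range`
#'   (ng, ng).
#' @export
fit_standard_curve <- function(signals, amounts, rel_tol = 0.2) {
  if (length(signals) != length(amounts)) stop("length mismatch")
  if (length(amounts) < 3L) stop("need at least 3 calibration spots")
  if (any(diff(amounts) <= 0)) stop("amounts must be strictly increasing")
  if (stats::var(amounts) == 0) stop("zero-variance amounts")
  fit <- stats::lm(signals ~ amounts)
  co <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  ok <- abs(stats::resid(fit)) < rel_tol * abs(fitted)
  # widest contiguous TRUE run
  best <- c(0L, 0L); run <- 0L; start <- 1L
  for (i in seq_along(ok)) {
    if (ok[i]) {
      if (run == 0L) start <- i
      run <- run + 1L
      if (run > diff(best) + 1L || best[2] == 0L) best <- c(start, i)
    } else run <- 0L
  }
  lr <- if (best[2] > 0L) c(amounts[best[1]], amounts[best[2]])
        else c(NA_real_, NA_real_)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 slope_origin = sum(signals * amounts) / sum(amounts^2),
                 amounts = amounts, signals = signals,
                 linear_range = lr),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4g counts/ng, intercept %.4g, r2 %.4f, linear %g-%g ng\n",
    x$slope, x$intercept, x$r_squared, x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Absolute glycogen quantitation in ng per pixel
#'
#' Back-calculates ng/pixel from raw feature counts through a fitted
#' standard curve: `ng = (signal - intercept) / slope`, clipped at 0
#' (clipped pixels flagged). Pixels outside the spotted amount range are
#' flagged as extrapolated. Region summaries are mean and SEM.
#'
#' @param fm Raw `feature_matrix` of the tissue (same acquisition units as
#'   the spots).
#' @param curve A [fit_standard_curve()] result.
#' @param feature Feature label (default `"1175"`); use
#'   `feature = "dp_sum"` to quantify on the summed DP ladder instead.
#' @param grouping Optional region/group per pixel for summaries.
#' @return List with `ng_per_pixel` (`data.frame`: `pixel_id`, `x`, `y`,
#'   `ng`, `clipped`, `extrapolated`) and `region_means` (`data.frame` or
#'   NULL).
#' @export
quantify <- function(fm, curve, feature = "1175", grouping = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(curve, "standard_curve"))
  if (fm$normalized)
    stop("quantitation uses raw counts, not TIC-normalized values")
  if (!(curve$slope > 0)) stop("non-positive curve slope")
  sig <- if (identical(feature, "dp_sum")) {
    is_dp <- fm$panel$class == "glycogen_dp"
    rowSums(fm$values[, fm$panel$label[is_dp], drop = FALSE])
  } else {
    if (!feature %in% colnames(fm$values))
      stop("feature not in panel: ", feature)
    fm$values[, feature]
  }
  ng_raw <- (sig - curve$intercept) / curve$slope
  ng <- pmax(ng_raw, 0)
  res <- data.frame(pixel_id = fm$pixels$pixel_id,
                    x = fm$pixels$x, y = fm$pixels$y, ng = ng,
                    clipped = ng_raw < 0,
                    extrapolated = ng_raw > max(curve$amounts) |
                      ng_raw < min(curve$amounts))
  region_means <- NULL
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == nrow(res))
    gs <- unique(as.character(grouping))
    region_means <- do.call(rbind, lapply(gs, function(g) {
      v <- ng[grouping == g]
      data.frame(region = g, mean_ng = mean(v),
                 sem_ng = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
  }
  list(ng_per_pixel = res, region_means = region_means)
}
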