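#' Scan-order mass drift model
#'
#' Smooth, bounded drift of the observed m/z axis as a function of
#' acquisition (scan) index, used by the phantom generator; recalibration
#' against the lock mass is the stage under test. `|offset| <= amplitude`
#' for every shape.
#'
#' @param scan_index Integer vector of scan indices (0-based).
#' @param amplitude Maximum absolute offset, Da, >= 0.
#' @param period Scale in scan-index units: a `linear` ramp reaches
#'   `amplitude` at `scan_index = period`; a `sinusoid` has this period.
#' @param shape `"constant"`, `"linear"` or `"sinusoid"`.
#' @return Numeric vector of m/z offsets in Da.
#' @examples
#' mass_drift(0:10, amplitude = 0.3, period = 10, shape = "linear")
#' @export
mass_drift <- function(scan_index, amplitude, period = max(scan_index),
                       shape = c("sinusoid", "linear", "constant")) {
  shape <- match.arg(shape)
  if (!(is.numeric(amplitude) && amplitude >= 0))
    stop("amplitude must be >= 0")
  if (amplitude == 0) return(rep(0, length(scan_index)))
  switch(shape,
    constant = rep(amplitude, length(scan_index)),
    linear   = amplitude * pmin(scan_index / period, 1),
    sinusoid = amplitude * sin(2 * pi * scan_index / period))
}

#' Phantom configuration
#'
#' Describes a synthetic MSI slide: a rectangular grid with a matrix
#' (off-tissue) border, a background tissue region, and zero or more shaped
#' tissue regions, each pointing at a per-feature intensity signature.
#' Shapes must be pairwise disjoint and lie inside the tissue area; every
#' tissue pixel not covered by a shape belongs to the background region.
#'
#' @param grid_width,grid_height Grid size in pixels.
#' @param regions List of shape specs:
#'   `list(region_id=, shape="rect", x0=, x1=, y0=, y1=, signature=)` or
#'   `list(region_id=, shape="ellipse", cx=, cy=, rx=, ry=, signature=)`
#'   (0-based, inclusive coordinates). Default: one fibrotic ellipse.
#' @param signatures Named list mapping signature id to a named numeric
#'   vector of mean intensities (counts) over panel feature labels; default
#'   [default_signatures()] of `panel`.
#' @param background_signature Signature id of uncovered tissue pixels.
#' @param matrix_border_width Width of the off-tissue border, pixels.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   pixel noise (unitless, >= 0).
#' @param drift_amplitude Mass-drift amplitude, Da; must stay below the
#'   1 Da lock-mass tolerance.
#' @param drift_period,drift_shape Passed to [mass_drift()]; period
#'   defaults to the number of scans.
#' @param seed Integer seed; phantoms are deterministic given the config.
#' @param panel A [peak_panel()]; default [build_default_panel()].
#' @param lock_mz,lock_intensity Lock-mass ion present in every pixel.
#' @param mass_range Acquired m/z range, Da.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_width = 40L, grid_height = 40L,
                           regions = NULL,
                           signatures = NULL,
                           background_signature = "normal",
                           matrix_border_width = 4L,
                           noise_cv = 0.2,
                           drift_amplitude = 0.2,
                           drift_period = NULL,
                           drift_shape = "sinusoid",
                           seed = 1L,
                           panel = build_default_panel(),
                           lock_mz = 1257.4296,
                           lock_intensity = 2e5,
                           mass_range = c(500, 3000)) {
  if (is.null(regions))
    regions <- list(list(region_id = "fibrotic", shape = "ellipse",
                         cx = 26, cy = 20, rx = 8, ry = 6,
                         signature = "fibrotic"))
  if (is.null(signatures)) signatures <- default_signatures(panel)
  if (!(noise_cv >= 0)) stop("noise_cv must be >= 0")
  if (!(drift_amplitude >= 0 && drift_amplitude < 1))
    stop("drift_amplitude must be in [0, 1) Da (below lock-mass tolerance)")
  if (any(unlist(lapply(signatures, function(s) s < 0))))
    stop("signature mean intensities must be >= 0")
  cfg <- list(grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              regions = regions, signatures = signatures,
              background_signature = background_signature,
              matrix_border_width = as.integer(matrix_border_width),
              noise_cv = noise_cv, drift_amplitude = drift_amplitude,
              drift_period = drift_period, drift_shape = drift_shape,
              seed = as.integer(seed), panel = panel,
              lock_mz = lock_mz, lock_intensity = lock_intensity,
              mass_range = mass_range)
  class(cfg) <- "phantom_config"
  cfg
}

#' Default per-region feature signatures
#'
#' A stated world for the phantom: off-tissue pixels carry CHCA matrix
#' cluster ions (mean `matrix_level`) with a small carbohydrate
#' bleed-through (`bleed_fraction` of the matrix level, <= 2%); tissue
#' pixels carry a glycogen DP ladder with a chain-length distribution
#' peaked near DP 8 plus the N-glycan panel and residual matrix signal.
#' The fibrotic signature scales every glycogen DP feature by
#' `glycogen_fold` (default 2.4, mirroring fibrosis-associated glycogen
#' accumulation) and fucosylated (dHex-containing) N-glycans by
#' `fucosylated_fold`.
#'
#' @param panel A [peak_panel()].
#' @param matrix_level Mean matrix-ion intensity off tissue, counts.
#' @param tissue_matrix_level Residual matrix-ion intensity on tissue.
#' @param glycogen_total Summed DP-ladder mean intensity in normal tissue.
#' @param nglycan_level Mean per-N-glycan intensity in normal tissue.
#' @param glycogen_fold Fibrotic / normal glycogen scale factor.
#' @param fucosylated_fold Fibrotic scale factor for dHex-containing
#'   N-glycans.
#' @param bleed_fraction Carbohydrate bleed-through off tissue, as a
#'   fraction of `matrix_level` (must be <= 0.02).
#' @param dp_mode,dp_sd Centre and width (in DP units) of the Gaussian
#'   chain-length abundance profile.
#' @return Named list of signatures `matrix`, `normal`, `fibrotic`.
#' @export
default_signatures <- function(panel,
                               matrix_level = 5e4,
                               tissue_matrix_level = 200,
                               glycogen_total = 3e4,
                               nglycan_level = 4e3,
                               glycogen_fold = 2.4,
                               fucosylated_fold = 3,
                               bleed_fraction = 0.01,
                               dp_mode = 8, dp_sd = 2.5) {
  stopifnot(bleed_fraction <= 0.02)
  labs <- panel$label
  is_mat <- panel$class == "matrix"
  is_dp <- panel$class == "glycogen_dp"
  is_ng <- panel$class == "nglycan"
  dp_of <- ifelse(is_dp, round((panel$target_mz - mass_constants[["water"]] -
                                mass_constants[["na_cation"]]) /
                               mass_constants[["hex"]]), NA)
  w <- exp(-(dp_of - dp_mode)^2 / (2 * dp_sd^2))
  w[!is_dp] <- 0
  dp_means <- glycogen_total * w / sum(w, na.rm = TRUE)
  fuc <- !is.na(panel$composition) & grepl("dHex", panel$composition) & is_ng

  base <- numeric(nrow(panel))
  names(base) <- labs
  mat <- base; mat[is_mat] <- matrix_level
  mat[is_dp | is_ng] <- bleed_fraction * matrix_level
  nrm <- base; nrm[is_mat] <- tissue_matrix_level
  nrm[is_dp] <- dp_means[is_dp]; nrm[is_ng] <- nglycan_level
  fib <- nrm
  fib[is_dp] <- nrm[is_dp] * glycogen_fold
  fib[fuc] <- nrm[fuc] * fucosylated_fold
  list(matrix = mat, normal = nrm, fibrotic = fib)
}

# Paint the region label map; errors on overlap or empty regions.
build_label_map <- function(cfg) {
  w <- cfg$grid_width; h <- cfg$grid_height; b <- cfg$matrix_border_width
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  lab <- matrix("matrix", nrow = h, ncol = w)
  tissue <- xs >= b & xs < w - b & ys >= b & ys < h - b
  lab[tissue] <- cfg$background_signature
  covered <- matrix(FALSE, nrow = h, ncol = w)
  for (rg in cfg$regions) {
    m <- switch(rg$shape,
      rect = xs >= rg$x0 & xs <= rg$x1 & ys >= rg$y0 & ys <= rg$y1,
      ellipse = ((xs - rg$cx) / rg$rx)^2 + ((ys - rg$cy) / rg$ry)^2 <= 1,
      stop("unknown region shape: ", rg$shape))
    m <- m & tissue
    if (!any(m)) stop("empty region: ", rg$region_id)
    if (any(m & covered))
      stop("overlapping region masks at region: ", rg$region_id)
    covered <- covered | m
    lab[m] <- rg$region_id
  }
  sig_of <- structure(
    c("matrix", cfg$background_signature,
      vapply(cfg$regions, `[[`, character(1), "signature")),
    names = c("matrix", cfg$background_signature,
              vapply(cfg$regions, `[[`, character(1), "region_id")))
  list(label = lab, signature_of = sig_of)
}

#' Generate a synthetic MSI phantom with ground truth
#'
#' Draws one centroided spectrum per pixel: each panel feature with a
#' positive signature mean gets intensity `mean * LN(1, noise_cv)`
#' (multiplicative lognormal noise with unit expectation) at
#' `theoretical m/z + drift(scan index)`; a lock-mass ion is emitted in
#' every pixel. Off-tissue pixels draw matrix-class peaks plus the small
#' configured bleed-through. Acquisition is row-major (y outer, x inner).
#'
#' @param config A [phantom_config()].
#' @return List with `dataset` (an [msi_dataset()]) and `truth` (label map
#'   `data.frame`, signature table, per-scan drift offsets, region ids).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  lm <- build_label_map(config)
  w <- config$grid_width; h <- config$grid_height
  px <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  px <- px[order(px$y, px$x), , drop = FALSE]
  n <- nrow(px)
  pixels <- data.frame(pixel_id = seq_len(n), x = px$x, y = px$y,
                       scan_index = seq_len(n) - 1L)
  region <- lm$label[cbind(px$y + 1L, px$x + 1L)]
  period <- if (is.null(config$drift_period)) max(n - 1L, 1L)
            else config$drift_period
  offsets <- mass_drift(pixels$scan_index, config$drift_amplitude, period,
                        config$drift_shape)
  pan <- config$panel
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  mz0 <- c(pan$target_mz, config$lock_mz)
  ord0 <- order(mz0)

  spectra <- with_seed(config$seed, lapply(seq_len(n), function(i) {
    sig <- config$signatures[[lm$signature_of[[region[i]]]]]
    means <- c(sig[pan$label], config$lock_intensity)
    noise <- if (config$noise_cv > 0)
      stats::rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(means))
    int <- unname(means * noise)
    keep <- unname(means > 0)
    mzs <- unname(mz0 + offsets[i])[ord0]
    ints <- int[ord0]
    k <- keep[ord0]
    list(mz = mzs[k], intensity = ints[k])
  }))

  ds <- msi_dataset(pixels, spectra,
                    metadata = list(mode = "processed",
                                    mass_range = config$mass_range))
  truth <- list(
    label_map = data.frame(x = pixels$x, y = pixels$y, region_id = region),
    signature_of = lm$signature_of,
    signatures = config$signatures,
    drift_offsets = data.frame(scan_index = pixels$scan_index,
                               offset_da = offsets),
    spot_amounts = NULL,
    config = config)
  list(dataset = ds, truth = truth)
}

#' Generate on-slide calibration standard spots
#'
#' Emulates purified glycogen standards spotted next to the tissue: one
#' square ROI per amount, each pixel carrying a glycogen DP ladder whose
#' DP 7 (1175 m/z) rung has mean intensity `amount * response_slope`
#' counts, the other rungs scaled by the chain-length profile; background
#' pixels carry matrix ions only. The lock ion is present everywhere.
#'
#' @param amounts Spotted amounts in ng, strictly increasing, all > 0;
#'   default the 1-1000 ng series.
#' @param response_slope Instrument response, counts per ng on the DP 7
#'   rung (per pixel), > 0.
#' @param noise_cv Multiplicative lognormal CV.
#' @param seed Integer seed.
#' @param spot_size Side of each square spot ROI, pixels.
#' @param gap Gap between spots, pixels.
#' @param panel A [peak_panel()].
#' @param lock_mz,lock_intensity Lock-mass ion parameters.
#' @return List with `dataset` and `truth`; `truth$spot_amounts` maps
#'   `spot_id` to `amount_ng` and member pixels, `truth$response_slope`
#'   records the generating slope.
#' @export
make_standard_spots <- function(amounts = c(1, 10, 20, 40, 100, 1000),
                                response_slope = 50,
                                noise_cv = 0.05,
                                seed = 1L,
                                spot_size = 3L,
                                gap = 2L,
                                panel = build_default_panel(),
                                lock_mz = 1257.4296,
                                lock_intensity = 2e5) {
  if (any(amounts <= 0) || any(diff(amounts) <= 0))
    stop("amounts must be positive and strictly increasing")
  if (!(response_slope > 0)) stop("response_slope must be > 0")
  k <- length(amounts)
  w <- as.integer(k * (spot_size + gap) + gap)
  h <- as.integer(spot_size + 2L * gap)
  px <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  px <- px[order(px$y, px$x), , drop = FALSE]
  n <- nrow(px)
  pixels <- data.frame(pixel_id = seq_len(n), x = px$x, y = px$y,
                       scan_index = seq_len(n) - 1L)
  spot_of <- rep(NA_integer_, n)
  for (s in seq_len(k)) {
    x0 <- gap + (s - 1L) * (spot_size + gap)
    hit <- px$x >= x0 & px$x < x0 + spot_size &
      px$y >= gap & px$y < gap + spot_size
    spot_of[hit] <- s
  }

  is_dp <- panel$class == "glycogen_dp"
  is_mat <- panel$class == "matrix"
  dp_of <- round((panel$target_mz - mass_constants[["water"]] -
                  mass_constants[["na_cation"]]) / mass_constants[["hex"]])
  shape <- exp(-(dp_of - 8)^2 / (2 * 2.5^2))
  i7 <- which(is_dp & dp_of == 7)
  if (!length(i7)) stop("panel lacks the DP 7 (1175 m/z) rung")
  rel <- shape / shape[i7]          # DP 7 rung == 1

  sdlog <- sqrt(log(1 + noise_cv^2))
  mz0 <- c(panel$target_mz, lock_mz)
  ord0 <- order(mz0)
  spectra <- with_seed(seed, lapply(seq_len(n), function(i) {
    means <- numeric(nrow(panel))
    if (is.na(spot_of[i])) {
      means[is_mat] <- 5e4
    } else {
      means[is_dp] <- amounts[spot_of[i]] * response_slope * rel[is_dp]
      means[is_mat] <- 200
    }
    means <- c(means, lock_intensity)
    noise <- if (noise_cv > 0)
      stats::rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(means))
    int <- unname(means * noise)
    keep <- unname(means > 0)
    list(mz = unname(mz0)[ord0][keep[ord0]], intensity = int[ord0][keep[ord0]])
  }))
  ds <- msi_dataset(pixels, spectra, metadata = list(mode = "processed"))
  region <- ifelse(is.na(spot_of), "matrix", paste0("spot_", spot_of))
  truth <- list(
    label_map = data.frame(x = pixels$x, y = pixels$y, region_id = region),
    spot_amounts = data.frame(spot_id = seq_len(k), amount_ng = amounts,
                              n_pixels = as.vector(table(factor(spot_of,
                                levels = seq_len(k))))),
    spot_of = spot_of,
    response_slope = response_slope,
    drift_offsets = data.frame(scan_index = pixels$scan_index,
                               offset_da = 0))
  list(dataset = ds, truth = truth)
}
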