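#' Read / write a pixel table CSV
#'
#' The tabular export dialect: a header row `x,y,scan_index` followed by
#' one column per panel feature, columns named by the nominal integer m/z
#' label. Strict parsing — missing or non-numeric cells are an error
#' (no silent imputation), duplicate coordinates are rejected, and rows are
#' canonicalised to (y, x) order so the result is independent of row order
#' on disk.
#'
#' @param path CSV path; comma separator, `.` decimal, UTF-8.
#' @return A list with `coords` (`data.frame` of `x`, `y`, `scan_index`)
#'   and `values` (numeric matrix, pixels by features, feature labels as
#'   column names).
#' @export
read_pixel_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("x", "y", "scan_index")
  if (!all(need %in% colnames(df)[1:3]))
    stop("pixel table must start with columns x,y,scan_index")
  assert_numeric_cells(df, path)
  if (anyDuplicated(df[, c("x", "y")])) {
    i <- which(duplicated(df[, c("x", "y")]))[1]
    stop(sprintf("%s: duplicate pixel coordinate (%d, %d) at row %d",
                 path, df$x[i], df$y[i], i))
  }
  o <- order(df$y, df$x)
  df <- df[o, , drop = FALSE]
  feats <- setdiff(colnames(df), need)
  values <- as.matrix(df[, feats, drop = FALSE])
  rownames(values) <- NULL
  list(coords = data.frame(x = as.integer(df$x), y = as.integer(df$y),
                           scan_index = as.integer(df$scan_index)),
       values = values)
}

#' @rdname read_pixel_table
#' @param coords `data.frame` with `x`, `y`, `scan_index`.
#' @param values Numeric matrix, one row per pixel.
#' @export
write_pixel_table <- function(coords, values, path) {
  stopifnot(nrow(coords) == nrow(values))
  df <- cbind(coords[, c("x", "y", "scan_index")], as.data.frame(values,
              check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-pixel label or value map as CSV + PNG
#'
#' Renders values on the pixel grid as a raster with row = y, column = x
#' (top-left origin). Categorical labels get a deterministic qualitative
#' palette indexed by label id; continuous values (e.g. ng/pixel) get a
#' monotone viridis-like ramp. Pixels absent from `coords` (e.g. removed
#' matrix pixels) are rendered as background.
#'
#' @param values Vector, one value per row of `coords`; factor/integer
#'   labels are treated as categorical unless `continuous = TRUE`.
#' @param coords `data.frame` with `x`, `y` (0-based grid coordinates).
#' @param path Output stem; writes `<path>.csv` and `<path>.png`.
#' @param continuous Force continuous colour scale.
#' @param background RGB of missing pixels, default dark grey.
#' @return Named list of the two file paths, invisibly.
#' @export
write_label_map <- function(values, coords, path, continuous = NULL,
                            background = c(0.15, 0.15, 0.15)) {
  if (length(values) != nrow(coords))
    stop("values length does not match the pixel frame")
  if (is.null(continuous))
    continuous <- is.numeric(values) && !is.integer(values) &&
      length(unique(values)) > 24
  csv_path <- paste0(path, ".csv")
  png_path <- paste0(path, ".png")
  utils::write.csv(data.frame(x = coords$x, y = coords$y, value = values),
                   csv_path, row.names = FALSE, quote = FALSE)

  w <- max(coords$x) + 1L
  h <- max(coords$y) + 1L
  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  if (continuous) {
    rng <- range(as.numeric(values))
    t <- if (diff(rng) > 0) (as.numeric(values) - rng[1]) / diff(rng)
         else rep(0.5, length(values))
    cols <- grDevices::rgb(0.2 + 0.7 * t, 0.1 + 0.8 * t^0.7, 0.5 - 0.4 * t)
  } else {
    ids <- as.integer(factor(values, levels = sort(unique(values))))
    pal <- grDevices::hcl(h = (seq_len(max(ids)) * 67) %% 360, c = 70, l = 60)
    cols <- pal[ids]
  }
  rgbm <- grDevices::col2rgb(cols) / 255
  for (k in 1:3)
    img[cbind(coords$y + 1L, coords$x + 1L, k)] <- rgbm[k, ]
  png::writePNG(img, png_path)
  invisible(list(csv = csv_path, png = png_path))
}
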