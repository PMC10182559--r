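#' Curated peak panel
#'
#' The panel is the user-input side of the workflow: a curated list of target
#' m/z values, each labelled `matrix` (CHCA cluster ion), `glycogen_dp`
#' (glucose-polymer ladder rung) or `nglycan`. Integration sums centroid
#' intensity within `window_halfwidth` Da of each target, so the full window
#' (< 1 Da by construction) never spans two targets.
#'
#' @param target_mz Numeric vector of target m/z, strictly increasing.
#' @param class Character vector, one of `"matrix"`, `"glycogen_dp"`,
#'   `"nglycan"` per target.
#' @param composition Character vector of composition strings
#'   (`""`/`NA` allowed for matrix peaks).
#' @param label Feature labels; defaults to the nominal integer m/z.
#' @param window_halfwidth Half-width of the integration window in Da,
#'   must be < 0.5 so neighbouring DP-ladder windows (162 Da apart) and any
#'   validated panel cannot overlap.
#' @return A `peak_panel` (a validated `data.frame` with attributes).
#' @export
peak_panel <- function(target_mz, class,
                       composition = NA_character_,
                       label = NULL,
                       window_halfwidth = 0.4) {
  n <- length(target_mz)
  class <- rep_len(as.character(class), n)
  composition <- rep_len(as.character(composition), n)
  if (is.null(label)) label <- as.character(nominal_label(target_mz))
  pan <- data.frame(target_mz = as.numeric(target_mz), class = class,
                    composition = composition,
                    label = rep_len(as.character(label), n),
                    stringsAsFactors = FALSE)
  pan <- pan[order(pan$target_mz), , drop = FALSE]
  rownames(pan) <- NULL
  attr(pan, "window_halfwidth") <- window_halfwidth
  class(pan) <- c("peak_panel", "data.frame")
  validate_panel(pan)
  pan
}

#' Validate peak-panel invariants
#'
#' Checks strict monotonicity and uniqueness of targets, window half-width
#' < 0.5 Da, non-overlapping windows, known classes, and that every
#' `glycogen_dp` entry sits on the theoretical DP ladder within 0.01 Da.
#'
#' @param pan A `peak_panel`.
#' @return `pan`, invisibly; errors name the offending entries.
#' @export
validate_panel <- function(pan) {
  stopifnot(inherits(pan, "peak_panel"))
  hw <- attr(pan, "window_halfwidth")
  if (!is.numeric(hw) || hw <= 0 || hw >= 0.5)
    stop("window_halfwidth must be in (0, 0.5)")
  if (nrow(pan) == 0L) stop("empty panel")
  bad <- setdiff(unique(pan$class), c("matrix", "glycogen_dp", "nglycan"))
  if (length(bad)) stop("unknown panel class: ", paste(bad, collapse = ", "))
  d <- diff(pan$target_mz)
  if (any(d <= 0))
    stop("target_mz must be strictly increasing and unique")
  if (any(d <= 2 * hw)) {
    i <- which(d <= 2 * hw)[1]
    stop(sprintf("integration windows overlap: %.4f and %.4f with halfwidth %.3f",
                 pan$target_mz[i], pan$target_mz[i + 1], hw))
  }
  gi <- which(pan$class == "glycogen_dp")
  if (length(gi)) {
    lad <- dp_ladder(1L, 30L)
    off <- vapply(pan$target_mz[gi], function(m) min(abs(lad$mz - m)),
                  numeric(1))
    if (any(off > 0.01))
      stop("glycogen_dp target off the theoretical DP ladder: ",
           paste(sprintf("%.4f", pan$target_mz[gi][off > 0.01]),
                 collapse = ", "))
  }
  if (any(duplicated(pan$label)))
    stop("duplicate feature labels: ",
         paste(unique(pan$label[duplicated(pan$label)]), collapse = ", "))
  invisible(pan)
}

#' CHCA matrix cluster-ion m/z values
#'
#' alpha-Cyano-4-hydroxycinnamic acid (CHCA, C10H7NO3, monoisotopic
#' 189.042593 Da) forms abundant cluster ions `[nM+H]+`, `[nM+Na]+` and
#' `[nM+2Na-H]+`; off-tissue pixels are dominated by them. Values below the
#' acquisition floor are dropped.
#'
#' @param n_range Integers, cluster sizes n.
#' @param mass_range Acquired m/z range; peaks outside are dropped.
#' @return Sorted numeric vector of m/z.
#' @export
chca_matrix_mz <- function(n_range = 3:8, mass_range = c(500, 3000)) {
  chca <- 189.042593
  proton <- 1.007276
  na <- mass_constants[["na_cation"]]
  mz <- c(outer(n_range * chca, c(proton, na, 2 * na - proton), `+`))
  mz <- sort(mz[mz >= mass_range[1] & mz <= mass_range[2]])
  unname(mz)
}

#' Default N-glycan composition strings
#'
#' High-mannose series plus canonical core-fucosylated complex-type
#' compositions seen in positive-mode CHCA tissue imaging. `Hex5HexNAc2`
#' (the usual lock-mass glycan) is deliberately excluded: the lock ion is
#' handled by recalibration, not quantified as a feature.
#'
#' @return Character vector of composition strings.
#' @export
default_nglycan_compositions <- function() {
  c("Hex3HexNAc2", "Hex4HexNAc2", "Hex6HexNAc2", "Hex7HexNAc2",
    "Hex8HexNAc2", "Hex9HexNAc2",
    "Hex4HexNAc3dHex1", "Hex3HexNAc4dHex1", "Hex4HexNAc4dHex1",
    "Hex5HexNAc4", "Hex5HexNAc4dHex1", "Hex5HexNAc5dHex1",
    "Hex6HexNAc5dHex1")
}

#' Build the default curated peak panel
#'
#' Combines a glycogen DP ladder (default DP 3-14), a set of N-glycan
#' compositions, and CHCA matrix cluster ions into one validated panel.
#' Duplicate or window-overlapping targets are rejected naming the
#' colliding pair.
#'
#' @param dp_min,dp_max DP ladder range.
#' @param nglycans Character vector of composition strings.
#' @param matrix_mz Numeric vector of matrix-peak m/z.
#' @param window_halfwidth Integration half-width, Da.
#' @return A [peak_panel()].
#' @examples
#' pan <- build_default_panel()
#' subset(pan, label == "1175")
#' @export
build_default_panel <- function(dp_min = 3L, dp_max = 14L,
                                nglycans = default_nglycan_compositions(),
                                matrix_mz = chca_matrix_mz(),
                                window_halfwidth = 0.4) {
  lad <- dp_ladder(dp_min, dp_max)
  comps <- lapply(nglycans, parse_composition)
  ng_mz <- vapply(comps, sodiated_mz, numeric(1))
  target <- c(lad$mz, ng_mz, matrix_mz)
  cls <- c(rep("glycogen_dp", nrow(lad)),
           rep("nglycan", length(ng_mz)),
           rep("matrix", length(matrix_mz)))
  comp <- c(sprintf("Hex%d", lad$dp),
            vapply(comps, format_composition, character(1)),
            rep(NA_character_, length(matrix_mz)))
  o <- order(target)
  too_close <- which(diff(target[o]) <= 2 * window_halfwidth)
  if (length(too_close)) {
    i <- too_close[1]
    stop(sprintf("panel targets collide: %.4f (%s) and %.4f (%s)",
                 target[o][i], cls[o][i], target[o][i + 1], cls[o][i + 1]))
  }
  peak_panel(target[o], cls[o], comp[o], window_halfwidth = window_halfwidth)
}

#' Read / write a peak panel as TSV
#'
#' Four tab-separated columns `target_mz`, `class`, `composition`, `label`
#' with a header row. The parser is strict: malformed lines are reported
#' with their line number.
#'
#' @param path File path.
#' @param window_halfwidth Half-width used when reading (not stored in the
#'   TSV).
#' @return [read_panel_tsv()] returns a validated [peak_panel()];
#'   [write_panel_tsv()] returns `path` invisibly.
#' @export
read_panel_tsv <- function(path, window_halfwidth = 0.4) {
  if (!file.exists(path)) stop("no such panel file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("panel file has no entries: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("target_mz", "class", "composition", "label")
  if (!identical(hdr[seq_along(need)], need))
    stop("panel header must be: ", paste(need, collapse = "\t"))
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop(sprintf("panel line %d: expected 4 tab-separated fields, got %d",
                   i, length(f)))
    mz <- suppressWarnings(as.numeric(f[1]))
    if (is.na(mz))
      stop(sprintf("panel line %d: non-numeric target_mz '%s'", i, f[1]))
    list(mz = mz, class = f[2], comp = f[3], label = f[4])
  })
  peak_panel(vapply(rows, `[[`, numeric(1), "mz"),
             vapply(rows, `[[`, character(1), "class"),
             ifelse(vapply(rows, `[[`, character(1), "comp") == "",
                    NA_character_, vapply(rows, `[[`, character(1), "comp")),
             vapply(rows, `[[`, character(1), "label"),
             window_halfwidth = window_halfwidth)
}

#' @rdname read_panel_tsv
#' @param pan A `peak_panel` to write.
#' @export
write_panel_tsv <- function(pan, path) {
  validate_panel(pan)
  out <- data.frame(target_mz = sprintf("%.6f", pan$target_mz),
                    class = pan$class,
                    composition = ifelse(is.na(pan$composition), "",
                                         pan$composition),
                    label = pan$label)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}
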