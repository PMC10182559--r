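#' Monoisotopic mass constants for carbohydrate residues
#'
#' Residue (dehydrated monomer) monoisotopic masses in Da, plus the mass of
#' water and of the sodium cation (electron-corrected). A neutral
#' oligosaccharide mass is the sum of its residue masses plus one water;
#' the sodiated adduct \eqn{[M+Na]^+} adds the cation mass.
#'
#' @format Named numeric vector with elements `hex` (hexose, C6H10O5),
#'   `hexnac` (N-acetylhexosamine, C8H13NO5), `dhex` (deoxyhexose/fucose,
#'   C6H10O4), `neuac` (N-acetylneuraminic acid, C11H17NO8), `water` (H2O)
#'   and `na_cation` (Na+ minus one electron mass).
#' @export
mass_constants <- c(
  hex       = 162.052824,
  hexnac    = 203.079373,
  dhex      = 146.057909,
  neuac     = 291.095417,
  water     = 18.010565,
  na_cation = 22.989218
)

#' Carbohydrate composition
#'
#' A composition counts residues; it carries no topology. `kind` separates
#' linear glucose polymers released from glycogen by isoamylase
#' (`"glucan_dp"`, hexoses only) from PNGase F-released N-glycans
#' (`"nglycan"`).
#'
#' @param hex,hexnac,dhex,neuac Non-negative integer residue counts
#'   (hexose, N-acetylhexosamine, deoxyhexose/fucose, sialic acid).
#' @param kind `"glucan_dp"` or `"nglycan"`.
#' @return An object of class `glycan_composition`.
#' @examples
#' glycan_composition(hex = 7)                      # Glc7 chain, DP 7
#' glycan_composition(5, 4, 1, kind = "nglycan")    # Hex5HexNAc4dHex1
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L,
                               kind = c("glucan_dp", "nglycan")) {
  kind <- match.arg(kind)
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("residue counts must be non-negative integers")
  if (sum(counts) < 1)
    stop("composition must contain at least one residue")
  if (kind == "glucan_dp" && any(counts[c("hexnac", "dhex", "neuac")] > 0))
    stop("a glucan_dp composition may contain only hexose residues")
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 kind = kind),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan_composition> %s (%s), [M+Na]+ %.4f\n",
              format_composition(x), x$kind, sodiated_mz(x)))
  invisible(x)
}

#' Compact residue-count string, e.g. `"Hex5HexNAc4dHex1"`
#'
#' @param comp A [glycan_composition()].
#' @return A single string; zero counts are omitted.
#' @export
format_composition <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  nm <- c("Hex", "HexNAc", "dHex", "NeuAc")
  keep <- comp$counts > 0
  paste0(nm[keep], comp$counts[keep], collapse = "")
}

#' Parse a residue-count string into a composition
#'
#' Inverse of [format_composition()]. Recognised residue tokens are `Hex`,
#' `HexNAc`, `dHex` and `NeuAc` (case sensitive), each followed by a count.
#'
#' @param text String such as `"Hex5HexNAc4dHex1"`.
#' @param kind Passed to [glycan_composition()]; default guesses
#'   `"glucan_dp"` when only hexoses are present is *not* applied —
#'   N-glycan is assumed unless `kind` says otherwise.
#' @return A [glycan_composition()].
#' @export
parse_composition <- function(text, kind = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  rx <- gregexpr("(HexNAc|NeuAc|dHex|Hex)([0-9]+)", text, perl = TRUE)[[1]]
  if (rx[1] == -1L)
    stop("cannot parse composition string: ", text)
  toks <- regmatches(text, gregexpr("(HexNAc|NeuAc|dHex|Hex)([0-9]+)", text,
                                    perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    stop("trailing or unrecognised characters in composition string: ", text)
  counts <- c(Hex = 0L, HexNAc = 0L, dHex = 0L, NeuAc = 0L)
  for (tk in toks) {
    res <- sub("[0-9]+$", "", tk)
    n <- as.integer(sub("^(HexNAc|NeuAc|dHex|Hex)", "", tk))
    if (counts[res] > 0L) stop("duplicate residue token in: ", text)
    counts[res] <- n
  }
  if (is.null(kind)) {
    kind <- if (all(counts[c("HexNAc", "dHex", "NeuAc")] == 0L))
      "glucan_dp" else "nglycan"
  }
  glycan_composition(counts[["Hex"]], counts[["HexNAc"]], counts[["dHex"]],
                     counts[["NeuAc"]], kind = kind)
}

#' Neutral monoisotopic mass of a composition
#'
#' mass = sum(count_i * residue mass_i) + water.
#'
#' @param comp A [glycan_composition()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' composition_mass(glycan_composition(hex = 1))  # free hexose, 180.0634
#' @export
composition_mass <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  res <- mass_constants[c("hex", "hexnac", "dhex", "neuac")]
  sum(comp$counts * res) + mass_constants[["water"]]
}

#' m/z of the sodiated adduct [M+Na]+
#'
#' Positive-mode CHCA carbohydrate imaging observes singly sodiated ions;
#' the adduct m/z is the neutral mass plus the (electron-corrected) sodium
#' cation mass.
#'
#' @param comp A [glycan_composition()].
#' @return m/z in Da.
#' @export
sodiated_mz <- function(comp) {
  composition_mass(comp) + mass_constants[["na_cation"]]
}

#' Nominal integer feature label for an m/z
#'
#' Imaging features are conventionally named by the integer-truncated
#' (floored) monoisotopic m/z of the sodiated ion, e.g. the DP 7 glucan at
#' 1175.3696 m/z is the "1175" feature. Truncation, not rounding: 1444.507
#' is labelled 1444 and 1485.534 is labelled 1485.
#'
#' @param mz Numeric m/z value(s).
#' @return Integer label(s).
#' @export
nominal_label <- function(mz) {
  stopifnot(is.numeric(mz), all(is.finite(mz)), all(mz >= 0))
  as.integer(floor(mz))
}

#' Glycogen chain-length (degree of polymerization) ladder
#'
#' Sodiated m/z of linear glucose chains DP `dp_min` .. `dp_max`:
#' m/z(DP n) = n * 162.052824 + 18.010565 + 22.989218. Consecutive rungs
#' are spaced by exactly one hexose residue mass.
#'
#' @param dp_min,dp_max Integer chain-length range, `1 <= dp_min <= dp_max`.
#' @return `data.frame` with columns `dp`, `mz`, `label` (nominal integer).
#' @examples
#' dp_ladder(7, 7)$mz  # 1175.3696
#' @export
dp_ladder <- function(dp_min = 3L, dp_max = 14L) {
  if (!(is.numeric(dp_min) && is.numeric(dp_max) &&
        dp_min >= 1 && dp_min <= dp_max))
    stop("require 1 <= dp_min <= dp_max")
  dp <- seq.int(dp_min, dp_max)
  mz <- dp * mass_constants[["hex"]] + mass_constants[["water"]] +
    mass_constants[["na_cation"]]
  data.frame(dp = as.integer(dp), mz = mz, label = nominal_label(mz))
}

#' Annotate an observed m/z with candidate compositions
#'
#' Exhaustively enumerates the bounded composition lattice and returns all
#' compositions whose sodiated m/z lies within `tolerance_da` of the query,
#' ranked by absolute mass error. The default bounds cover the instrument
#' mass ceiling of 3000 Da.
#'
#' @param mz Observed m/z (Da).
#' @param tolerance_da Match tolerance (Da), > 0.
#' @param max_hex,max_hexnac,max_dhex,max_neuac Upper residue-count bounds.
#' @param glucan_only If `TRUE`, search hexose-only chains.
#' @return `data.frame` with columns `composition`, `hex`, `hexnac`, `dhex`,
#'   `neuac`, `mz`, `delta_mz`, sorted by `abs(delta_mz)`; zero rows when
#'   nothing matches.
#' @export
annotate_mz <- function(mz, tolerance_da = 0.2,
                        max_hex = 15L, max_hexnac = 8L,
                        max_dhex = 3L, max_neuac = 4L,
                        glucan_only = FALSE) {
  stopifnot(is.numeric(mz), length(mz) == 1L, is.finite(mz))
  if (!(tolerance_da > 0)) stop("tolerance_da must be > 0")
  bounds <- c(max_hex, max_hexnac, max_dhex, max_neuac)
  if (any(!is.finite(bounds)) || any(bounds < 0))
    stop("residue count bounds must be finite and non-negative")
  if (glucan_only) { max_hexnac <- max_dhex <- max_neuac <- 0L }
  grid <- expand.grid(hex = 0:max_hex, hexnac = 0:max_hexnac,
                      dhex = 0:max_dhex, neuac = 0:max_neuac)
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  res <- mass_constants[c("hex", "hexnac", "dhex", "neuac")]
  cand_mz <- as.matrix(grid) %*% res + mass_constants[["water"]] +
    mass_constants[["na_cation"]]
  delta <- cand_mz[, 1] - mz
  keep <- abs(delta) <= tolerance_da
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(data.frame(composition = character(), hex = integer(),
                      hexnac = integer(), dhex = integer(), neuac = integer(),
                      mz = numeric(), delta_mz = numeric()))
  out <- data.frame(
    composition = vapply(seq_len(nrow(grid)), function(i) {
      kind <- if (all(grid[i, -1] == 0)) "glucan_dp" else "nglycan"
      format_composition(glycan_composition(grid$hex[i], grid$hexnac[i],
                                            grid$dhex[i], grid$neuac[i],
                                            kind = kind))
    }, character(1)),
    hex = grid$hex, hexnac = grid$hexnac, dhex = grid$dhex, neuac = grid$neuac,
    mz = cand_mz[keep, 1], delta_mz = delta[keep])
  out <- out[order(abs(out$delta_mz), out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
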