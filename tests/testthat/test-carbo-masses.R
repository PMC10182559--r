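# Independent oracle: residue masses from IUPAC atomic monoisotopic masses.
atomic <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
elemental_mass <- function(C = 0, H = 0, N = 0, O = 0)
  sum(c(C, H, N, O) * atomic[c("C", "H", "N", "O")])

test_that("mass constants equal their elemental sums within 1e-5 Da", {
  expect_equal(mass_constants[["hex"]], elemental_mass(6, 10, 0, 5),
               tolerance = 1e-5)
  expect_equal(mass_constants[["hexnac"]], elemental_mass(8, 13, 1, 5),
               tolerance = 1e-5)
  expect_equal(mass_constants[["dhex"]], elemental_mass(6, 10, 0, 4),
               tolerance = 1e-5)
  expect_equal(mass_constants[["neuac"]], elemental_mass(11, 17, 1, 8),
               tolerance = 1e-5)
  expect_equal(mass_constants[["water"]], elemental_mass(H = 2, O = 1),
               tolerance = 1e-5)
  # Na cation = atomic Na minus one electron
  expect_equal(mass_constants[["na_cation"]], 22.9897692809 - 0.00054858,
               tolerance = 1e-5)
})

test_that("composition_mass matches the elemental oracle", {
  # free hexose as a 1-residue chain is glucose C6H12O6
  expect_equal(composition_mass(glycan_composition(hex = 1)),
               elemental_mass(6, 12, 0, 6), tolerance = 1e-4)
  expect_equal(composition_mass(glycan_composition(hex = 1)), 180.0634,
               tolerance = 1e-4)
  # frozen residue-sum oracle values
  expect_equal(composition_mass(parse_composition("Hex5HexNAc2")),
               1234.4333, tolerance = 1e-4)
  expect_equal(composition_mass(parse_composition("Hex5HexNAc4dHex1")),
               1786.6501, tolerance = 1e-4)
})

test_that("composition constructor enforces invariants", {
  expect_error(glycan_composition(0, 0, 0, 0), "at least one residue")
  expect_error(glycan_composition(hex = -1), "non-negative")
  expect_error(glycan_composition(2, 1, kind = "glucan_dp"), "only hexose")
})

test_that("sodiated m/z and floor labels reproduce all six printed assignments", {
  cases <- list(
    list(comp = glycan_composition(hex = 7), mz = 1175.370, label = 1175L),
    list(comp = parse_composition("Hex8HexNAc2"), mz = 1743.581,
         label = 1743L),
    list(comp = parse_composition("Hex3HexNAc4dHex1"), mz = 1485.534,
         label = 1485L),
    list(comp = parse_composition("Hex5HexNAc4dHex1"), mz = 1809.639,
         label = 1809L),
    list(comp = parse_composition("Hex5HexNAc5dHex1"), mz = 2012.719,
         label = 2012L),
    list(comp = parse_composition("Hex4HexNAc3dHex1"), mz = 1444.507,
         label = 1444L))
  for (cs in cases) {
    expect_equal(sodiated_mz(cs$comp), cs$mz, tolerance = 1e-3)
    expect_identical(nominal_label(sodiated_mz(cs$comp)), cs$label)
  }
  # rounding to nearest would break two of them; truncation must not
  expect_identical(nominal_label(1444.507), 1444L)
  expect_identical(nominal_label(1485.534), 1485L)
})

test_that("dp_ladder formula, base case and spacing", {
  lad <- dp_ladder(1, 20)
  expect_equal(lad$mz[lad$dp == 7], 1175.370, tolerance = 1e-3)
  expect_equal(lad$mz[lad$dp == 1], 203.052607, tolerance = 1e-6)
  expect_equal(diff(lad$mz), rep(162.052824, 19), tolerance = 1e-9)
  expect_error(dp_ladder(5, 3), "dp_min")
})

test_that("mass arithmetic is order-independent to < 1e-9 Da", {
  comp <- parse_composition("Hex5HexNAc4dHex1NeuAc2")
  res <- mass_constants[c("hex", "hexnac", "dhex", "neuac")]
  shuffles <- replicate(10, sample(4), simplify = FALSE)
  ref <- composition_mass(comp)
  for (s in shuffles)
    expect_equal(sum((comp$counts[s]) * res[s]) + mass_constants[["water"]],
                 ref, tolerance = 1e-9)
})

test_that("annotate_mz brute-force definition and worked examples", {
  hit <- annotate_mz(1175.37, 0.1, glucan_only = TRUE)
  expect_identical(hit$composition, "Hex7")
  top <- annotate_mz(2012.72, 0.2, max_hex = 12L, max_hexnac = 12L)
  expect_identical(top$composition[1], "Hex5HexNAc5dHex1")
  expect_identical(nrow(annotate_mz(100.0, 0.1)), 0L)
  expect_error(annotate_mz(1000, tolerance_da = 0), "tolerance")
})

test_that("annotate_mz round-trips random compositions", {
  set.seed(7)
  for (i in 1:25) {
    comp <- glycan_composition(sample(0:9, 1), sample(0:5, 1),
                               sample(0:2, 1), sample(0:2, 1),
                               kind = "nglycan")
    if (sum(comp$counts) == 0) next
    hits <- annotate_mz(sodiated_mz(comp), 0.05)
    expect_true(format_composition(comp) %in% hits$composition)
  }
})

test_that("composition strings parse and format round-trip", {
  for (s in c("Hex7", "Hex5HexNAc4dHex1", "Hex5HexNAc5dHex1NeuAc2"))
    expect_identical(format_composition(parse_composition(s)), s)
  expect_identical(parse_composition("Hex7")$kind, "glucan_dp")
  expect_error(parse_composition("Foo3"), "parse")
  expect_error(parse_composition("Hex5Xyz2"), "parse|unrecognised")
})
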