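test_that("noiseless phantom is region-piecewise-constant at the signatures", {
  cfg <- small_phantom_config(noise_cv = 0, drift_amplitude = 0)
  ph <- make_phantom(cfg)
  fm <- integrate_panel(ph$dataset, cfg$panel)
  region <- ph$truth$label_map$region_id
  for (rg in unique(region)) {
    rows <- fm$values[region == rg, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(v) diff(range(v)) == 0)))
    sig <- cfg$signatures[[ph$truth$signature_of[[rg]]]]
    # lock ion lands in no panel window of the small panel
    expect_equal(unname(rows[1, ]), unname(sig[colnames(fm$values)]),
                 tolerance = 1e-12)
  }
})

test_that("phantom generation is deterministic and truth is a bijection", {
  cfg <- small_phantom_config(seed = 9)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(nrow(a$truth$label_map), n_pixels(a$dataset))
  expect_identical(anyDuplicated(a$truth$label_map[, c("x", "y")]), 0L)
})

test_that("emitted intensities and m/z respect the configured ranges", {
  cfg <- small_phantom_config(noise_cv = 0.3, drift_amplitude = 0.3, seed = 4)
  ph <- make_phantom(cfg)
  for (sp in ph$dataset$spectra) {
    expect_true(all(sp$intensity >= 0))
    expect_true(all(sp$mz >= cfg$mass_range[1] - 1 &
                      sp$mz <= cfg$mass_range[2] + 1))
    expect_false(is.unsorted(sp$mz))
  }
})

test_that("invalid region geometry is rejected", {
  overlapping <- list(
    list(region_id = "a", shape = "rect", x0 = 5, x1 = 12, y0 = 5, y1 = 12,
         signature = "fibrotic"),
    list(region_id = "b", shape = "ellipse", cx = 10, cy = 10, rx = 4,
         ry = 4, signature = "fibrotic"))
  cfg <- small_phantom_config()
  cfg$regions <- overlapping
  expect_error(make_phantom(cfg), "overlapping")
  cfg$regions <- list(list(region_id = "void", shape = "rect", x0 = 50,
                           x1 = 60, y0 = 50, y1 = 60, signature = "fibrotic"))
  expect_error(make_phantom(cfg), "empty region")
  expect_error(phantom_config(noise_cv = -0.1), "noise_cv")
  expect_error(phantom_config(drift_amplitude = 1.5), "drift_amplitude")
})

test_that("drift model obeys its contract", {
  expect_identical(mass_drift(0:99, amplitude = 0), rep(0, 100))
  expect_equal(mass_drift(100, 0.3, period = 100, shape = "linear"), 0.3)
  expect_equal(mass_drift(0, 0.2, period = 40, shape = "sinusoid"),
               mass_drift(40, 0.2, period = 40, shape = "sinusoid"),
               tolerance = 1e-12)
  off <- mass_drift(0:500, 0.25, period = 123, shape = "sinusoid")
  expect_true(all(abs(off) <= 0.25 + 1e-12))
  expect_error(mass_drift(1, 0.1, shape = "sawtooth"), "arg")
  expect_error(mass_drift(1, -0.1), "amplitude")
})

test_that("standard spots: exact noiseless sums, default amounts, rejections", {
  pan <- small_panel()
  sp <- make_standard_spots(amounts = c(1, 10, 100), response_slope = 5,
                            noise_cv = 0, seed = 1, panel = pan)
  fm <- integrate_panel(sp$dataset, pan)
  sums <- spot_signals(fm, sp$truth$spot_of, statistic = "sum")
  npx <- sp$truth$spot_amounts$n_pixels
  expect_equal(sums, c(5, 50, 500) * npx, tolerance = 1e-9)

  def <- make_standard_spots(seed = 1, panel = pan)
  expect_equal(def$truth$spot_amounts$amount_ng, c(1, 10, 20, 40, 100, 1000))
  expect_identical(nrow(def$truth$spot_amounts), 6L)

  expect_error(make_standard_spots(amounts = c(10, 5)), "increasing")
  expect_error(make_standard_spots(response_slope = 0), "response_slope")
})

test_that("2.4x glycogen signature is recovered by the downstream total", {
  # Monte-Carlo over 20 seeds on the raw (count-scale) feature matrix
  ratios <- vapply(1:20, function(s) {
    cfg <- small_phantom_config(noise_cv = 0.2, drift_amplitude = 0, seed = s)
    ph <- make_phantom(cfg)
    fm <- integrate_panel(ph$dataset, cfg$panel)
    tg <- chain_profile(fm, ph$truth$label_map$region_id)$total_glycogen
    mean(tg$total[tg$group == "fibrotic"]) /
      mean(tg$total[tg$group == "normal"])
  }, numeric(1))
  expect_equal(mean(ratios), 2.4, tolerance = 0.05)
})
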