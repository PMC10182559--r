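test_that("recalibration recovers constant and zero drift", {
  cfg <- small_phantom_config(noise_cv = 0, drift_amplitude = 0.1,
                              drift_shape = "constant", seed = 2)
  rc <- recalibrate(make_phantom(cfg)$dataset)
  expect_true(all(abs(rc$shifts$shift_da - 0.1) < 1e-6))

  cfg0 <- small_phantom_config(noise_cv = 0, drift_amplitude = 0, seed = 2)
  rc0 <- recalibrate(make_phantom(cfg0)$dataset)
  expect_true(all(rc0$shifts$shift_da == 0))
})

test_that("pixels with weak lock peaks are excluded from the estimate but recalibrated", {
  lock <- 1257.4296
  mk <- function(lock_int, drift)
    list(mz = c(1000, lock + drift), intensity = c(50, lock_int))
  ds <- toy_dataset(list(mk(2e5, 0.2), mk(99000, 0.9), mk(2e5, 0.2)))
  rc <- recalibrate(ds, recalibration_config(time_bin = 10L))
  # weak pixel's deviant 0.9 Da offset must not influence the median
  expect_equal(rc$shifts$shift_da, 0.2, tolerance = 1e-9)
  expect_identical(rc$shifts$n_pixels, 2L)
  # the weak pixel is still shifted by its bin's estimate
  expect_equal(rc$dataset$spectra[[2]]$mz[2], lock + 0.9 - 0.2,
               tolerance = 1e-9)
})

test_that("bins without qualifying pixels inherit the nearest shift", {
  lock <- 1257.4296
  spectra <- c(
    replicate(4, list(mz = c(600, lock + 0.05), intensity = c(10, 2e5)),
              simplify = FALSE),
    replicate(4, list(mz = 600, intensity = 10), simplify = FALSE))
  ds <- toy_dataset(spectra)
  rc <- recalibrate(ds, recalibration_config(time_bin = 4L))
  expect_identical(rc$shifts$inherited, c(FALSE, TRUE))
  expect_equal(rc$shifts$shift_da, c(0.05, 0.05), tolerance = 1e-9)
  # no lock anywhere -> hard error
  expect_error(recalibrate(toy_dataset(list(list(mz = 600, intensity = 5)))),
               "cannot calibrate")
})

test_that("panel integration windows, summing and TIC", {
  pan <- peak_panel(1175.370, "glycogen_dp", window_halfwidth = 0.4)
  ds <- toy_dataset(list(
    list(mz = c(1175.36, 1175.90), intensity = c(100, 50)),
    list(mz = c(1175.10, 1175.60, 2000), intensity = c(30, 20, 7)),
    list(mz = numeric(0), intensity = numeric(0))))
  fm <- integrate_panel(ds, pan)
  expect_equal(unname(fm$values[, 1]), c(100, 50, 0))  # 1175.90 outside
  expect_equal(fm$tic, c(150, 57, 0))                  # TIC over full spectrum
  expect_identical(fm$flagged_empty, 3L)
})

test_that("noiseless drifted-then-recalibrated matrix equals the undrifted one", {
  pan <- small_panel()
  drift <- phantom_fm(small_phantom_config(noise_cv = 0,
                                           drift_amplitude = 0.3,
                                           drift_shape = "sinusoid",
                                           seed = 6), normalized = FALSE)
  plain <- make_phantom(small_phantom_config(noise_cv = 0,
                                             drift_amplitude = 0, seed = 6))
  fm0 <- integrate_panel(plain$dataset, pan)
  expect_equal(drift$fm$values, fm0$values, tolerance = 1e-9)
})

test_that("TIC normalization contract", {
  pan <- peak_panel(c(1175.370, 1337.423, 1499.475),
                    rep("glycogen_dp", 3), window_halfwidth = 0.4)
  ds <- toy_dataset(list(
    list(mz = c(1175.370, 1337.423, 1499.475), intensity = c(2, 3, 5)),
    list(mz = c(1175.370, 1337.423, 1499.475), intensity = 7 * c(2, 3, 5)),
    list(mz = numeric(0), intensity = numeric(0))))
  fm <- integrate_panel(ds, pan)
  expect_message(fmn <- tic_normalize(fm), "zero TIC")
  expect_equal(unname(fmn$values[1, ]), c(0.2, 0.3, 0.5))
  # scale invariance: pixel 2 is pixel 1 scaled by 7
  expect_equal(fmn$values[1, ], fmn$values[2, ], tolerance = 1e-12)
  expect_identical(nrow(fmn$values), 2L)
  expect_identical(attr(fmn, "dropped_zero_tic"), 1L)
  expect_error(tic_normalize(fmn), "already")
})

test_that("integration is invariant to pixel order", {
  cfg <- small_phantom_config(seed = 8)
  ph <- make_phantom(cfg)
  fm <- integrate_panel(ph$dataset, cfg$panel)
  perm <- sample(n_pixels(ph$dataset))
  ds2 <- ph$dataset
  ds2$pixels <- ds2$pixels[perm, , drop = FALSE]
  ds2$spectra <- ds2$spectra[perm]
  fm2 <- integrate_panel(ds2, cfg$panel)
  expect_equal(fm2$values[order(perm), ], fm$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})
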