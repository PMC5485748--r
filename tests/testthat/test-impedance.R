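fake_spectrum <- function(f, z) {
  structure(data.frame(frequency_hz = f, z = z),
            class = c("impedance_spectrum", "data.frame"))
}

test_that("baseline normalization follows the relative-magnitude formula", {
  f <- c(10, 100, 1000)
  base <- fake_spectrum(f, c(100, 50, 20) + 0i)
  expect_equal(normalize_impedance(base, base)$z_normal, rep(0, 3))
  up <- fake_spectrum(f, 1.1 * c(100, 50, 20) * exp(1i * 0.3))
  expect_equal(normalize_impedance(up, base)$z_normal, rep(0.1, 3),
               tolerance = 1e-12)
  down <- fake_spectrum(f, 0.63 * c(100, 50, 20) + 0i)
  expect_equal(normalize_impedance(down, base)$z_normal, rep(-0.37, 3),
               tolerance = 1e-12)
  expect_error(normalize_impedance(fake_spectrum(c(10, 100), c(1, 1) + 0i), base),
               "frequency grid")
  expect_error(normalize_impedance(base, fake_spectrum(f, c(0, 1, 1) + 0i)),
               "zero")
})

test_that("the default frequency list is the 18-point sweep", {
  f <- default_frequencies()
  expect_length(f, 18)
  expect_true(all(diff(f) > 0))
  expect_equal(f[1], 10)
  expect_equal(f[18], 1e6)
  expect_true(all(c(80, 500, 2e3, 5e4, 5e5) %in% f))
})

test_that("two-electrode baseline impedance is interface-dominated at low frequency", {
  tw <- tiny_two()
  sp <- simulate_two_electrode(tw$layout, NULL,
                               frequencies = c(10, 1e3, 1e5),
                               domain = tw$domain, resolution = coarse_res())
  expect_true(all(diff(Mod(sp$z)) < 0))      # |Z| falls with frequency
  # at 10 Hz the two series films dominate: 2 |Z_el| / area_scale
  zel10 <- electrode_interface_impedance(10, electrode_interface_params())
  expect_equal(Mod(sp$z[1]), 2 * Mod(zel10) / 10, tolerance = 0.1)
})

test_that("four-electrode baseline spectrum is flat", {
  tf <- tiny_four()
  sp <- simulate_four_electrode(tf$layout, NULL,
                                frequencies = c(10, 1e2, 1e3, 1e4, 1e5, 1e6),
                                domain = tf$domain, resolution = coarse_res())
  expect_lt(max(Mod(sp$z)) / min(Mod(sp$z)), 1.01)
})

test_that("a cell raises the two-electrode impedance above 100 Hz", {
  tw <- tiny_two()
  freqs <- c(10, 1e3, 1e4, 1e5)
  base <- simulate_two_electrode(tw$layout, NULL, frequencies = freqs,
                                 domain = tw$domain, resolution = coarse_res())
  cell <- make_cell_shape(8, 5, adherent = TRUE, x0 = 30)
  sp <- simulate_two_electrode(tw$layout, cell, frequencies = freqs,
                               domain = tw$domain, resolution = coarse_res())
  zn <- normalize_impedance(sp, base)$z_normal
  expect_true(all(zn >= 0))                  # S >= 0: any cell adds impedance
  expect_gt(zn[3], 0.01)                     # clear effect at 10 kHz
  expect_gt(zn[3], zn[1] * 5)                # negligible at 10 Hz in comparison
})

test_that("position sweeps are symmetric and baseline-consistent", {
  tw <- tiny_two()
  sw <- position_sweep(tw$layout, data.frame(x0 = c(-30, 0, 30), y0 = 5),
                       frequency = 1e4, cell_r0 = 6,
                       domain = tw$domain, resolution = coarse_res())
  expect_s3_class(sw, "position_sweep")
  # mirrored positions over the mirrored electrodes agree
  expect_equal(sw$z_normal[1], sw$z_normal[3], tolerance = 0.03)
  expect_equal(max(sw$pct_of_max), 100)
  # the over-electrode position dominates the mid-gap one
  expect_gt(abs(sw$z_normal[3]), abs(sw$z_normal[2]))
})

test_that("four-electrode cell effects follow the sensitivity sign", {
  tf <- tiny_four()
  freqs <- 1e4
  # between the recording electrodes: S > 0, conductivity drop -> |Z| up
  sw <- position_sweep(tf$layout, data.frame(x0 = c(0, 55), y0 = 5),
                       frequency = freqs, cell_r0 = 8,
                       domain = tf$domain, resolution = coarse_res())
  expect_gt(sw$z_normal[1], 0)     # S > 0 region: impedance increases
  expect_lt(sw$z_normal[2], 0)     # S < 0 region: impedance decreases
})

test_that("wrapper type checks reject mismatched layouts", {
  expect_error(simulate_two_electrode(mea_layout("four_electrode")),
               "without recording")
  expect_error(simulate_four_electrode(mea_layout("two_electrode")),
               "recording_pos")
  tw <- tiny_two()
  expect_error(simulate_spectrum(tw$layout, frequencies = c(10, -5)),
               "positive")
})
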