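test_that("electrode interface impedance matches the closed form", {
  p <- electrode_interface_params()
  # frozen value computed independently (complex arithmetic on the circuit)
  z1k <- electrode_interface_impedance(1e3, p)
  expect_equal(Re(z1k), 115922.7748324857, tolerance = 1e-10)
  expect_equal(Im(z1k), -218286.05657209235, tolerance = 1e-10)
  z100k <- electrode_interface_impedance(1e5, p)
  expect_equal(Re(z100k), 7479.340856022939, tolerance = 1e-10)
  expect_equal(Im(z100k), -10740.705052593325, tolerance = 1e-10)
})

test_that("interface impedance limits behave like the circuit", {
  p <- electrode_interface_params()
  # high-frequency limit: both branches vanish
  expect_lt(Mod(electrode_interface_impedance(1e12, p)), 1)
  # low-frequency: CPE diverges, RC branch tends to R
  zlo <- electrode_interface_impedance(1e-6, p)
  expect_gt(Mod(zlo), 1e10)
  z_rc <- p$R / (1 + 1i * 2 * pi * 1e-6 * p$R * p$C)
  expect_equal(Re(z_rc), p$R, tolerance = 1e-3)
  expect_error(electrode_interface_impedance(0, p), "f > 0")
  expect_error(electrode_interface_impedance(-10, p), "f > 0")
})

test_that("interface impedance is passive and monotone over the sweep band", {
  p <- electrode_interface_params()
  f <- 10^seq(1, 6, length.out = 60)
  z <- electrode_interface_impedance(f, p)
  expect_true(all(Im(z) < 0))                 # capacitive at all frequencies
  expect_true(all(diff(Mod(z)) <= 0))         # |Z| non-increasing
})

test_that("surface impedance realizes the effective-area correction", {
  p <- electrode_interface_params(area_scale = 10)
  A <- pi * 15^2                               # um^2
  zs <- surface_impedance_electrode(1e3, p, A)
  # lumped impedance of the uniformly covered disc: zs / A = Z_el / scale
  expect_equal(zs / (A * 1e-12),
               electrode_interface_impedance(1e3, p) / 10, tolerance = 1e-12)
  p1 <- electrode_interface_params(area_scale = 1)
  zs1 <- surface_impedance_electrode(1e3, p1, A)
  expect_equal(zs1 / zs, 10 + 0i, tolerance = 1e-12)
  expect_error(surface_impedance_electrode(1e3, p, -5), "positive")
})

test_that("membrane impedance follows the parallel-RC closed form", {
  mp <- membrane_params()                      # 1 mS/cm^2, 1 uF/cm^2
  expect_equal(membrane_surface_impedance(0, mp), 1000 + 0i)
  # corner frequency g/(2 pi c) = 159.155 Hz: |z| = 1000/sqrt(2), -45 deg
  fc <- 1e-3 / (2 * pi * 1e-6)
  zc <- membrane_surface_impedance(fc, mp)
  expect_equal(Mod(zc), 1000 / sqrt(2), tolerance = 1e-9)
  expect_equal(Arg(zc) * 180 / pi, -45, tolerance = 1e-9)
  expect_lt(Mod(membrane_surface_impedance(1e9, mp)), 1e-2)
  # oracle identity at arbitrary frequencies
  for (f in c(3, 470, 8.1e4)) {
    y <- 1e-3 + 1i * 2 * pi * f * 1e-6
    expect_equal(membrane_surface_impedance(f, mp), 1 / y, tolerance = 1e-12)
  }
  expect_equal(membrane_surface_impedance_si(fc, mp), zc * 1e-4)
  expect_error(membrane_surface_impedance(0, membrane_params(g_m = 0)),
               "diverges")
})

test_that("material properties validate and form complex conductivities", {
  m <- material_props()
  expect_equal(m$medium$sigma, 1.57)
  expect_equal(m$medium$eps_r, 77)
  expect_equal(m$cytoplasm$sigma, 3)
  expect_equal(m$cytoplasm$eps_r, 80)
  k <- complex_conductivity(m, "medium", 1e5)
  expect_equal(k, 1.57 + 1i * 2 * pi * 1e5 * 8.8541878128e-12 * 77,
               tolerance = 1e-12)
  expect_error(material_props(medium = list(sigma = -1, eps_r = 77)), "sigma")
  expect_error(complex_conductivity(m, "glass", 10), "unknown region")
})

test_that("parameter constructors reject out-of-range values", {
  expect_error(electrode_interface_params(CPE_P = 1.2), "CPE_P")
  expect_error(electrode_interface_params(CPE_P = 0), "CPE_P")
  expect_error(electrode_interface_params(R = -1), "positive")
  expect_error(membrane_params(c_m = 0), "c_m")
})

test_that("noiseless circuit fit recovers the generating parameters", {
  truth <- electrode_interface_params()
  sp <- synthetic_electrode_spectrum(truth, n = 26)
  fit <- fit_equivalent_circuit(sp$frequency_hz, sp$z)
  expect_true(fit$converged)
  for (nm in c("CPE_T", "CPE_P", "R", "C", "R_B"))
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 1e-3)
})

test_that("circuit fit tolerates multiplicative noise", {
  truth <- electrode_interface_params()
  # tolerances established by Monte-Carlo recovery over 20 noise seeds:
  # the CPE pair and R_B are tightly constrained, R much less (its corner
  # lies below the measured band)
  sp <- synthetic_electrode_spectrum(truth, n = 26, noise = 0.01, seed = 7)
  fit <- fit_equivalent_circuit(sp$frequency_hz, sp$z)
  expect_lt(abs(fit$params$CPE_T - truth$CPE_T) / truth$CPE_T, 0.10)
  expect_lt(abs(fit$params$CPE_P - truth$CPE_P) / truth$CPE_P, 0.02)
  expect_lt(abs(fit$params$C - truth$C) / truth$C, 0.05)
  expect_lt(abs(fit$params$R - truth$R) / truth$R, 0.35)
  expect_lt(abs(fit$params$R_B - truth$R_B) / truth$R_B, 0.05)
})

test_that("a constant spectrum collapses to the series resistance", {
  f <- 10^seq(1, 6, length.out = 26)
  z <- rep(5000 + 0i, 26)
  # the model is overparameterized for a pure resistor; the optimizer may
  # stop on the iteration cap while already at the flat optimum
  fit <- suppressWarnings(fit_equivalent_circuit(f, z))
  expect_equal(fit$params$R_B, 5000, tolerance = 0.01)
  zm <- electrode_spectrum_model(f, fit$params)
  expect_true(all(Mod(zm - 5000) / 5000 < 1e-3))
})

test_that("degenerate fit inputs are rejected", {
  f <- c(10, 20, 30, 40, 50, 60)
  expect_error(fit_equivalent_circuit(f, rep(1 + 0i, 6)), "3 decades")
  expect_error(fit_equivalent_circuit(c(10, 1e5), c(1i, 2i)), "length")
})
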