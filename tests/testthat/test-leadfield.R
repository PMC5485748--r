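# minimal hand-built sensitivity/solution objects for pure-math checks
fake_solution <- function(mesh, J, f = 1e4) {
  structure(list(f = f, phi = NULL, J = J,
                 terminals = NULL, drive = drive_spec("A", "B"),
                 mesh = mesh, solver = list(iters = 0, relres = 0)),
            class = "field_solution")
}

test_that("two-electrode sensitivity is |J|^2 and non-negative", {
  m <- precompute_operator(toy_mesh())
  sys <- assemble_system(m, f = 1e4)
  sol <- solve_drive(sys, drive_spec("A", "B"))
  fld <- compute_sensitivity(sol)
  expect_true(all(fld$S >= 0))
  expect_equal(fld$S, rowSums(Mod(sol$J)^2), tolerance = 1e-12)
})

test_that("orthogonal lead fields give zero sensitivity", {
  m <- toy_mesh()
  nel <- nrow(m$tets)
  Jx <- matrix(0 + 0i, nel, 3); Jx[, 1] <- 1
  Jy <- matrix(0 + 0i, nel, 3); Jy[, 2] <- 1
  fld <- compute_sensitivity(fake_solution(m, Jx), fake_solution(m, Jy))
  expect_true(all(fld$S == 0))
  expect_error(compute_sensitivity(fake_solution(m, Jx),
                                   fake_solution(m, Jy, f = 2e4)),
               "frequency")
})

test_that("four-electrode sensitivity changes sign between electrode gaps", {
  tf <- tiny_four()
  m <- precompute_operator(generate_mesh(tf$layout, NULL, tf$domain, coarse_res()))
  sys <- assemble_system(m, f = 1e4)
  sol_i <- solve_drive(sys, drive_spec("E1", "E4"))
  sol_e <- solve_drive(sys, drive_spec("E2", "E3"))
  fld <- compute_sensitivity(sol_i, sol_e)
  near <- function(x, y) which(abs(m$centroid[, 1] - x) < 8 &
                               m$centroid[, 2] > 1 & m$centroid[, 2] < y &
                               abs(m$centroid[, 3]) < 8)
  # between the recording electrodes: S > 0 (both fields flow +x)
  expect_gt(median(fld$S[near(0, 10)]), 0)
  # between a recording electrode and its neighboring excitation: S < 0
  expect_lt(median(fld$S[near(60, 10)]), 0)
  expect_lt(median(fld$S[near(-60, 10)]), 0)
})

test_that("volume averaging handles constant fields and bad regions", {
  m <- toy_mesh()
  nel <- nrow(m$tets)
  Jc <- matrix(0 + 0i, nel, 3); Jc[, 1] <- 2
  fld <- compute_sensitivity(fake_solution(m, Jc))   # S = 4 everywhere
  region <- make_cell_shape(8, 10, x0 = 0)
  expect_equal(integral_sensitivity(fld, region), 4, tolerance = 1e-12)
  expect_equal(integral_sensitivity(fld, region, normalizer = 8), 0.5,
               tolerance = 1e-12)
  expect_equal(integral_sensitivity(fld, region, mode = "magnitude"), 4,
               tolerance = 1e-12)
  off_mesh <- make_cell_shape(1, 55, x0 = 0)
  expect_error(integral_sensitivity(fld, off_mesh), "centroid")
})

test_that("sensitivity scans are symmetric and peak-normalized", {
  tw <- tiny_two()
  sc <- sensitivity_scan(tw$layout, x0 = seq(-40, 40, by = 10), y0 = c(5, 12),
                         cell_r0 = 6, frequency = 1e4, domain = tw$domain,
                         resolution = coarse_res())
  expect_s3_class(sc, "sensitivity_profile")
  # normalization: profile maximum at the lowest height equals 1
  expect_equal(max(abs(sc$s_normal[sc$y0 == 5])), 1, tolerance = 1e-12)
  # mirror symmetry of the symmetric layout
  for (y in c(5, 12)) {
    d <- sc[sc$y0 == y, ]
    left <- d$s_normal[match(-d$x0, d$x0)]
    expect_equal(d$s_normal, left, tolerance = 0.05)
  }
  # sensitivity decays with height above the plane
  expect_true(all(abs(sc$s_normal[sc$y0 == 12]) <
                  abs(sc$s_normal[sc$y0 == 5]) + 0.05))
})

test_that("normalized profiles are frequency-insensitive in the resistive band", {
  # ideal electrodes isolate the volume-conductor lead field from the
  # frequency-dependent current redistribution of the interface film
  tw <- tiny_two()
  mesh <- generate_mesh(tw$layout, NULL, tw$domain, coarse_res())
  no_film <- list(electrode = NULL, membrane = NULL)
  sc1 <- sensitivity_scan(tw$layout, x0 = seq(-30, 30, by = 15), y0 = 5,
                          cell_r0 = 6, frequency = 1e3, domain = tw$domain,
                          interfaces = no_film, mesh = mesh)
  sc2 <- sensitivity_scan(tw$layout, x0 = seq(-30, 30, by = 15), y0 = 5,
                          cell_r0 = 6, frequency = 1e5, domain = tw$domain,
                          interfaces = no_film, mesh = mesh)
  expect_lt(max(abs(sc1$s_normal - sc2$s_normal)), 0.05)
})

test_that("Geselowitz perturbation matches sign conventions and the direct solve", {
  tw <- tiny_two()
  blob <- make_cell_shape(8, 10, adherent = FALSE, x0 = 0)
  m <- precompute_operator(generate_mesh(tw$layout, blob, tw$domain, coarse_res()))
  mats0 <- uniform_materials()
  iface <- transparent_membrane()
  sys0 <- assemble_system(m, mats0, iface, f = 1e4)
  s0 <- solve_drive(sys0, drive_spec("A", "B"))
  fld <- compute_sensitivity(s0)
  mask <- m$region == "cytoplasm"

  # no perturbation, no impedance change
  expect_equal(delta_z_geselowitz(fld, mask, 0, mats0), 0 + 0i)
  # conductivity decrease in an S > 0 region raises the impedance
  dz <- delta_z_geselowitz(fld, mask, -0.157, mats0)
  expect_gt(Re(dz), 0)
  # against the direct two-solve difference (first-order band: 10 %)
  mats1 <- material_props(cytoplasm = list(sigma = 1.57 - 0.157, eps_r = 77))
  z1 <- solve_drive(assemble_system(m, mats1, iface, f = 1e4),
                    drive_spec("A", "B"))$terminals[["A"]]
  dz_direct <- z1 - s0$terminals[["A"]]
  expect_lt(Mod(dz - dz_direct) / Mod(dz_direct), 0.10)

  # guard rails
  expect_error(delta_z_geselowitz(fld, mask, -2, mats0), "non-positive")
  expect_warning(delta_z_geselowitz(fld, mask, -0.5, mats0), "first-order")
})
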