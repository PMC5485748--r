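# Direct two- and four-electrode impedance simulation: spectra, Eq.-style
# baseline normalization, and cell-position sweeps.

#' The default 18-point measurement frequency list
#'
#' 10, 20, 30, 40, 50, 80, 100, 200, 500 Hz, 1, 2, 5, 10, 20, 50, 100,
#' 500 kHz and 1 MHz.
#' @return numeric vector, Hz.
#' @export
default_frequencies <- function() {
  c(10, 20, 30, 40, 50, 80, 100, 200, 500,
    1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5, 5e5, 1e6)
}

#' Simulate an impedance spectrum
#'
#' Meshes the layout (with the cell, if given) once and solves the terminal
#' drive at each frequency.  For a two-electrode layout the excitation
#' electrode is driven against the grounded counter and
#' `Z = U_excitation / I_T`, which includes both electrode interface films.
#' For a four-electrode layout the outer pair carries the current, the
#' recording pair floats behind its films (ideal infinite-impedance
#' amplifier), and the transfer impedance is
#' `Z = (U_rec+ - U_rec-) / I_T`.
#'
#' @param layout a [mea_layout()].
#' @param cell a [make_cell_shape()] or `NULL` for the baseline.
#' @param frequencies frequency vector, Hz (default [default_frequencies()]).
#' @param materials,interfaces as in [assemble_system()].
#' @param domain,resolution,fine_x meshing controls (see [generate_mesh()]).
#' @param recording_bc treatment of the floating recording pair in a
#'   four-electrode layout: `"insulating"` (default; bare face, no metal
#'   shunt, amplifier reads the area-averaged potential) or `"film"`
#'   (equipotential metal behind its interface film with zero net terminal
#'   current).
#' @param mesh optionally a prebuilt mesh (overrides `cell` etc.).
#' @return An object of class `impedance_spectrum`: data.frame with columns
#'   `frequency_hz`, `z` (complex, Ohm); configuration in attributes.
#' @export
simulate_spectrum <- function(layout, cell = NULL,
                              frequencies = default_frequencies(),
                              materials = material_props(),
                              interfaces = list(
                                electrode = electrode_interface_params(),
                                membrane = membrane_params()),
                              domain = simulation_domain(), resolution = 1,
                              fine_x = NULL,
                              recording_bc = c("insulating", "film"),
                              mesh = NULL) {
  stopifnot(inherits(layout, "mea_layout"))
  recording_bc = match.arg(recording_bc)
  frequencies <- sort(unique(frequencies))
  if (any(diff(frequencies) <= 0) || any(frequencies <= 0))
    stop("frequencies must be positive and strictly increasing")
  if (is.null(mesh))
    mesh <- generate_mesh(layout, cell = cell, domain = domain,
                          resolution = resolution, fine_x = fine_x)
  mesh <- precompute_operator(mesh)

  exc <- layout$id[layout$role == "excitation"]
  cnt <- layout$id[layout$role == "counter"]
  four <- any(layout$role == "recording_pos")
  if (four) {
    rp <- layout$id[layout$role == "recording_pos"]
    rn <- layout$id[layout$role == "recording_neg"]
  }

  ins <- if (four && recording_bc == "insulating") c(rp, rn) else character(0)
  z <- vapply(frequencies, function(f) {
    sys <- assemble_system(mesh, materials, interfaces, f = f, insulate = ins)
    sol <- solve_drive(sys, drive_spec(exc, cnt))
    if (four)
      (sol$terminals[[rp]] - sol$terminals[[rn]]) / sol$drive$I_T
    else
      sol$terminals[[exc]] / sol$drive$I_T
  }, complex(1))

  structure(data.frame(frequency_hz = frequencies, z = z),
            class = c("impedance_spectrum", "data.frame"),
            layout_type = attr(layout, "type"),
            four_electrode = four,
            cell = if (!is.null(mesh$cell)) mesh$cell else cell,
            n_elements = nrow(mesh$tets))
}

#' Two-electrode spectrum (excitation/counter pair)
#'
#' Convenience wrapper around [simulate_spectrum()] enforcing a
#' two-electrode layout.
#' @inheritParams simulate_spectrum
#' @export
simulate_two_electrode <- function(layout = mea_layout("two_electrode"),
                                   cell = NULL, ...) {
  if (any(layout$role %in% c("recording_pos", "recording_neg")))
    stop("two-electrode simulation requires a layout without recording electrodes")
  simulate_spectrum(layout, cell = cell, ...)
}

#' Four-electrode transfer-impedance spectrum
#'
#' Convenience wrapper around [simulate_spectrum()] enforcing a
#' four-electrode layout (floating recording pair).
#' @inheritParams simulate_spectrum
#' @export
simulate_four_electrode <- function(layout = mea_layout("four_electrode"),
                                    cell = NULL, ...) {
  if (!any(layout$role == "recording_pos"))
    stop("four-electrode simulation requires a recording_pos/recording_neg pair")
  simulate_spectrum(layout, cell = cell, ...)
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum (%s%s), %d frequencies\n",
              attr(x, "layout_type"),
              if (is.null(attr(x, "cell"))) ", baseline" else ", with cell",
              nrow(x)))
  df <- data.frame(frequency_hz = x$frequency_hz,
                   mod_ohm = Mod(x$z), phase_deg = Arg(x$z) * 180 / pi)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ...\n")
  invisible(x)
}

#' Baseline-normalized impedance
#'
#' Relative magnitude change against a cell-free baseline,
#' `Z_normal = (|Z| - |Z_0|) / |Z_0|`, per frequency.
#'
#' @param spectrum,baseline [simulate_spectrum()] results on identical
#'   frequency grids.
#' @return data.frame of class `normalized_spectrum` with columns
#'   `frequency_hz`, `z_normal`.
#' @export
normalize_impedance <- function(spectrum, baseline) {
  if (!isTRUE(all.equal(spectrum$frequency_hz, baseline$frequency_hz)))
    stop("spectrum and baseline must share the same frequency grid")
  z0 <- Mod(baseline$z)
  if (any(z0 == 0)) stop("baseline magnitude is zero at some frequency")
  structure(data.frame(frequency_hz = spectrum$frequency_hz,
                       z_normal = (Mod(spectrum$z) - z0) / z0),
            class = c("normalized_spectrum", "data.frame"))
}

#' Cell-position impedance sweep at a fixed frequency
#'
#' Re-meshes and re-solves the model for each cell position and reports the
#' baseline-normalized impedance.  The cell template follows the scan
#' convention: volume-conserving cap for `y0 <= r0`, free sphere above.
#' Per-position failures are recorded (`NA`) and the sweep continues.
#'
#' @param layout a [mea_layout()].
#' @param positions data.frame with columns `x0`, `y0` (um).
#' @param frequency sweep frequency, Hz (default 100 kHz, the frequency of
#'   maximum cell effect in the two-electrode spectrum).
#' @param cell_r0 free cell radius, um.
#' @param materials,interfaces,domain,resolution as elsewhere.
#' @param recording_bc treatment of the floating recording pair, see
#'   [simulate_spectrum()].
#' @param baseline optionally a precomputed baseline `z` (complex) at the
#'   sweep frequency.
#' @return data.frame of class `position_sweep` with columns `x0, y0, z,
#'   z_normal, pct_of_max` (|z_normal| as a percent of the sweep maximum).
#' @export
position_sweep <- function(layout, positions, frequency = 1e5, cell_r0 = 10,
                           materials = material_props(),
                           interfaces = list(
                             electrode = electrode_interface_params(),
                             membrane = membrane_params()),
                           domain = simulation_domain(), resolution = 1,
                           recording_bc = c("insulating", "film"),
                           baseline = NULL) {
  stopifnot(is.data.frame(positions), all(c("x0", "y0") %in% names(positions)))
  recording_bc <- match.arg(recording_bc)
  exc <- layout$id[layout$role == "excitation"]
  cnt <- layout$id[layout$role == "counter"]
  four <- any(layout$role == "recording_pos")
  if (four) {
    rp <- layout$id[layout$role == "recording_pos"]
    rn <- layout$id[layout$role == "recording_neg"]
  }
  measure <- function(mesh) {
    mesh <- precompute_operator(mesh)
    ins <- if (four && recording_bc == "insulating") c(rp, rn) else character(0)
    sys <- assemble_system(mesh, materials, interfaces, f = frequency,
                           insulate = ins)
    sol <- solve_drive(sys, drive_spec(exc, cnt))
    if (four) (sol$terminals[[rp]] - sol$terminals[[rn]]) / sol$drive$I_T
    else sol$terminals[[exc]] / sol$drive$I_T
  }
  if (is.null(baseline))
    baseline <- measure(generate_mesh(layout, NULL, domain, resolution))
  z <- vapply(seq_len(nrow(positions)), function(i) {
    tryCatch({
      cellpos <- make_cell_shape(cell_r0, positions$y0[i],
                                 adherent = positions$y0[i] <= cell_r0,
                                 x0 = positions$x0[i])
      measure(generate_mesh(layout, cellpos, domain, resolution))
    }, error = function(e) {
      warning("position (", positions$x0[i], ", ", positions$y0[i],
              ") failed: ", conditionMessage(e))
      NA_complex_
    })
  }, complex(1))
  zn <- (Mod(z) - Mod(baseline)) / Mod(baseline)
  out <- data.frame(x0 = positions$x0, y0 = positions$y0,
                    z = z, z_normal = zn,
                    pct_of_max = 100 * abs(zn) / max(abs(zn), na.rm = TRUE))
  structure(out, class = c("position_sweep", "data.frame"),
            frequency = frequency, baseline = baseline)
}
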