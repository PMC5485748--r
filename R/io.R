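# Configuration files, result serialization, mesh/field export, fixtures.

run_config_defaults <- function() {
  list(
    layout = "two_electrode",
    electrode_diameter_um = 30,
    cell = NULL,                        # list(r0, x0, y0, adherent) or NULL
    materials = list(medium = list(sigma = 1.57, eps_r = 77),
                     cytoplasm = list(sigma = 3, eps_r = 80)),
    electrode_interface = list(CPE_T = 2.819e-8, CPE_P = 0.595,
                               R = 46.26e6, C = 2.59e-9, R_B = 3.789e3,
                               area_scale = 10,
                               cpe_t_convention = "rescaled"),
    membrane = list(g_m = 1, c_m = 1),
    domain = list(x = c(-400, 400), y = c(0, 400), z = c(-200, 200)),
    resolution = 1,
    frequencies_hz = default_frequencies(),
    sweep = list(frequency_hz = 1e5, x0 = seq(0, 100, by = 10), y0 = 5),
    output_dir = ".",
    seed = 1)
}

#' Build a validated run configuration
#'
#' Merges user settings over the default setup (30 um electrode discs at
#' -50/+50 um, optionally -150/+150 um, PBS bath, fitted interface circuit,
#' the 18-point frequency list).  Unknown keys are rejected.
#'
#' The electrode-interface key `cpe_t_convention` selects how the CPE
#' coefficient is read: `"rescaled"` (default) uses `CPE_T` in S s^P on the
#' scale that reproduces megaohm-range microelectrode spectra; `"literal"`
#' multiplies `CPE_T` by 1e16, reproducing the alternative convention in
#' which the printed coefficient is 2.819e8.
#'
#' @param ... configuration entries overriding the defaults (see
#'   `measens:::run_config_defaults()` for the schema).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("schema error: unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$layout %in% c("two_electrode", "four_electrode"))
    stop("schema error: layout must be two_electrode or four_electrode")
  conv <- cfg$electrode_interface$cpe_t_convention
  if (!conv %in% c("rescaled", "literal"))
    stop("schema error: cpe_t_convention must be 'rescaled' or 'literal'")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the configuration keys.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# realize configured objects
config_layout <- function(cfg)
  mea_layout(cfg$layout, diameter = cfg$electrode_diameter_um)
config_materials <- function(cfg)
  material_props(cfg$materials$medium, cfg$materials$cytoplasm)
config_interfaces <- function(cfg) {
  ei <- cfg$electrode_interface
  cpe_t <- if (identical(ei$cpe_t_convention, "literal")) ei$CPE_T * 1e16 else ei$CPE_T
  list(electrode = electrode_interface_params(
         CPE_T = cpe_t, CPE_P = ei$CPE_P, R = ei$R, C = ei$C,
         R_B = ei$R_B, area_scale = ei$area_scale),
       membrane = membrane_params(cfg$membrane$g_m, cfg$membrane$c_m))
}
config_domain <- function(cfg)
  simulation_domain(cfg$domain$x, cfg$domain$y, cfg$domain$z)
config_cell <- function(cfg) {
  if (is.null(cfg$cell)) return(NULL)
  cl <- cfg$cell
  make_cell_shape(r0 = cl$r0 %||% 10, y0 = cl$y0 %||% 5,
                  adherent = cl$adherent %||% ((cl$y0 %||% 5) <= (cl$r0 %||% 10)),
                  x0 = cl$x0 %||% 0, z0 = cl$z0 %||% 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

provenance_header <- function(seed = NA, extra = character(0)) {
  c(sprintf("# measens %s", as.character(utils::packageVersion("measens"))),
    sprintf("# seed: %s", seed),
    if (length(extra)) paste0("# ", extra))
}

#' Write an impedance spectrum as CSV
#'
#' Columns `frequency_hz, z_real_ohm, z_imag_ohm`, preceded by a `#`
#' provenance header.
#' @param spectrum an [simulate_spectrum()] result (or any data.frame with
#'   `frequency_hz` and complex `z`).
#' @param path output file.
#' @param seed recorded in the header.
#' @export
write_spectrum_csv <- function(spectrum, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(data.frame(frequency_hz = spectrum$frequency_hz,
                              z_real_ohm = Re(spectrum$z),
                              z_imag_ohm = Im(spectrum$z)),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an impedance spectrum CSV
#' @param path CSV written by [write_spectrum_csv()] (or in the same
#'   `frequency_hz, z_real_ohm, z_imag_ohm` layout).
#' @return data.frame with `frequency_hz` and complex `z`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  data.frame(frequency_hz = df$frequency_hz,
             z = complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm))
}

#' Write a sensitivity profile or position sweep as CSV
#' @param profile a [sensitivity_scan()] or [position_sweep()] result.
#' @param path output file.
#' @param seed recorded in the header.
#' @export
write_profile_csv <- function(profile, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  df <- as.data.frame(profile)
  for (nm in names(df)) if (is.complex(df[[nm]])) {
    df[[paste0(nm, "_real")]] <- Re(df[[nm]])
    df[[paste0(nm, "_imag")]] <- Im(df[[nm]])
    df[[nm]] <- NULL
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# -- mesh and field export ---------------------------------------------------

#' Export a mesh (with optional element fields) as ASCII VTU
#'
#' Writes an XML VTK unstructured grid with the region label and any number
#' of named per-element arrays (complex arrays are split into `_re`/`_im`).
#'
#' @param mesh a `mea_mesh`.
#' @param path output `.vtu` file.
#' @param cell_data named list of per-element vectors (real or complex).
#' @export
write_vtu <- function(mesh, path, cell_data = list()) {
  nodes <- mesh$nodes; tets <- mesh$tets
  np <- nrow(nodes); nc <- nrow(tets)
  arrays <- list(region = as.integer(mesh$region == "cytoplasm"))
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.complex(v)) {
      arrays[[paste0(nm, "_re")]] <- Re(v); arrays[[paste0(nm, "_im")]] <- Im(v)
    } else arrays[[nm]] <- v
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(nodes[, 1], nodes[, 2], nodes[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(tets[, 1] - 1L, tets[, 2] - 1L, tets[, 3] - 1L, tets[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(4L * seq_len(nc)), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", nc), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  for (nm in names(arrays)) {
    w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
    writeLines(as.character(arrays[[nm]]), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Export a mesh in Gmsh MSH 4.1 ASCII format
#'
#' Minimal writer: one 3D entity per region (medium = 1, cytoplasm = 2),
#' nodes and tetrahedra.
#' @param mesh a `mea_mesh`.
#' @param path output `.msh` file.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  nodes <- mesh$nodes; tets <- mesh$tets
  np <- nrow(nodes)
  regions <- c("medium", "cytoplasm")
  present <- regions[regions %in% mesh$region]
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Entities")
  w("0 0 0 %d", length(present))
  for (i in seq_along(present))
    w("%d 0 0 0 0 0 0 0 0", i)
  w("$EndEntities")
  w("$Nodes")
  w("1 %d 1 %d", np, np)
  w("3 1 0 %d", np)
  writeLines(as.character(seq_len(np)), con)
  writeLines(paste(nodes[, 1], nodes[, 2], nodes[, 3]), con)
  w("$EndNodes")
  w("$Elements")
  w("%d %d 1 %d", length(present), nrow(tets), nrow(tets))
  eid <- 1L
  for (i in seq_along(present)) {
    sel <- which(mesh$region == present[i])
    w("3 %d 4 %d", i, length(sel))
    writeLines(paste(seq(eid, eid + length(sel) - 1L),
                     tets[sel, 1], tets[sel, 2], tets[sel, 3], tets[sel, 4]), con)
    eid <- eid + length(sel)
  }
  w("$EndElements")
  invisible(path)
}

# -- fixtures ----------------------------------------------------------------

#' Generate deterministic test fixtures
#'
#' `synthetic_electrode_spectrum`: a 26-point log-spaced (10 Hz - 1 MHz)
#' single-electrode spectrum from the default interface circuit, with
#' optional multiplicative complex noise, for circuit-fit tests.
#' `toy_mesh`: a tiny two-electrode mesh that assembles and solves in well
#' under a second.  `reference_configs`: YAML files reproducing the default
#' two- and four-electrode setups.
#'
#' @param kind one of `synthetic_electrode_spectrum`, `toy_mesh`,
#'   `reference_configs`.
#' @param dir output directory (created if needed).
#' @param seed RNG seed (noise reproducibility; byte-identical outputs for
#'   equal seeds).
#' @param noise relative noise amplitude for the synthetic spectrum
#'   (default 0: noiseless).
#' @return invisible character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("synthetic_electrode_spectrum",
                                       "toy_mesh", "reference_configs"),
                              dir = ".", seed = 1L, noise = 0) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (kind == "synthetic_electrode_spectrum") {
    sp <- synthetic_electrode_spectrum(seed = seed, noise = noise)
    f <- file.path(dir, "synthetic_electrode_spectrum.csv")
    write_spectrum_csv(sp, f, seed = seed)
    files <- f
  } else if (kind == "toy_mesh") {
    mesh <- toy_mesh()
    f <- file.path(dir, "toy_mesh.msh")
    write_msh(mesh, f)
    files <- f
  } else {
    for (ly in c("two_electrode", "four_electrode")) {
      cfg <- run_config(layout = ly, seed = seed)
      f <- file.path(dir, paste0(ly, ".yaml"))
      write_run_config(cfg, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Synthetic single-electrode spectrum
#'
#' The measurement protocol emulated: 26 frequencies distributed
#' logarithmically between 10 Hz and 1 MHz, model `R_B + Z_el(f)`,
#' optionally with multiplicative complex Gaussian noise.
#'
#' @param params an [electrode_interface_params()].
#' @param n number of frequencies.
#' @param fmin,fmax frequency range, Hz.
#' @param noise relative noise sd (e.g. 0.01 for 1 %).
#' @param seed RNG seed used when `noise > 0`.
#' @return data.frame with `frequency_hz`, complex `z`.
#' @export
synthetic_electrode_spectrum <- function(params = electrode_interface_params(),
                                         n = 26, fmin = 10, fmax = 1e6,
                                         noise = 0, seed = 1L) {
  f <- 10^seq(log10(fmin), log10(fmax), length.out = n)
  z <- electrode_spectrum_model(f, params)
  if (noise > 0) {
    set.seed(seed)
    z <- z * (1 + noise * stats::rnorm(n)) *
      exp(1i * noise * stats::rnorm(n))
  }
  data.frame(frequency_hz = f, z = z)
}

#' A tiny two-electrode mesh for solver unit tests
#'
#' 120 x 60 x 60 um bath around two 30 um discs at -25/+25 um, coarse
#' spacing; assembles and solves in a fraction of a second.
#' @param resolution density multiplier.
#' @return a `mea_mesh`.
#' @export
toy_mesh <- function(resolution = 1) {
  ly <- mea_layout("custom", electrodes = data.frame(
    id = c("A", "B"), x = c(-25, 25), z = 0, diameter = 30,
    role = c("excitation", "counter")))
  dm <- simulation_domain(x = c(-60, 60), y = c(0, 60), z = c(-30, 30))
  generate_mesh(ly, NULL, dm, resolution = mesh_resolution(
    resolution, h_xz = 10, h_y = 6, y_fine = 18))
}
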