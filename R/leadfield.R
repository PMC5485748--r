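# Lead fields, sensitivity distributions and Geselowitz perturbations.
#
# The measurement sensitivity of an impedance lead is the scalar field
#     S = J_LE . J_LI
# where J_LI is the current density produced by a unit current through the
# current-feeding pair and J_LE the (reciprocal) field of a unit current
# through the voltage pair.  For a two-electrode lead the two fields
# coincide and S = |J|^2 >= 0 everywhere; a four-electrode lead has regions
# of either sign.  A local resistivity change d(rho) shifts the transfer
# impedance by dZ = integral of S * d(rho) dV (first-order Geselowitz
# perturbation), so the volume-averaged S over the cell volume predicts how
# strongly a cell at that position affects the measurement.

#' Scalar sensitivity field of an impedance lead
#'
#' Computes per-element `S = J_LE . J_LI` from two unit-current field
#' solutions on the same mesh and frequency.  The scalar visualization
#' convention takes the real dot product
#' `Re(J_LE).Re(J_LI) + Im(J_LE).Im(J_LI)`; the unconjugated complex
#' product, which enters the Geselowitz perturbation integral, is retained
#' alongside.  For a two-electrode lead pass the same solution twice.
#'
#' @param sol_current [solve_drive()] solution of the current-feeding pair.
#' @param sol_voltage [solve_drive()] solution of the voltage pair (the
#'   same object for a two-electrode lead).
#' @return An object of class `sensitivity_field`: list with `S` (real,
#'   A^2/m^4, per element), `S_complex`, `f`, `mesh`, `drives`.
#' @export
compute_sensitivity <- function(sol_current, sol_voltage = sol_current) {
  stopifnot(inherits(sol_current, "field_solution"),
            inherits(sol_voltage, "field_solution"))
  if (!identical(dim(sol_current$J), dim(sol_voltage$J)) ||
      !identical(nrow(sol_current$mesh$tets), nrow(sol_voltage$mesh$tets)))
    stop("sensitivity requires both solutions on the same mesh")
  if (sol_current$f != sol_voltage$f)
    stop("sensitivity requires both solutions at the same frequency")
  Ji <- sol_current$J / sol_current$drive$I_T   # normalize to unit current
  Je <- sol_voltage$J / sol_voltage$drive$I_T
  S <- rowSums(Re(Je) * Re(Ji) + Im(Je) * Im(Ji))
  Sc <- rowSums(Je * Ji)
  structure(list(S = S, S_complex = Sc, f = sol_current$f,
                 mesh = sol_current$mesh,
                 drives = list(current = sol_current$drive,
                               voltage = sol_voltage$drive)),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  cat(sprintf("Sensitivity field at %g Hz over %d elements\n",
              x$f, length(x$S)))
  cat(sprintf("  range: [%.3g, %.3g] A^2/m^4\n", min(x$S), max(x$S)))
  invisible(x)
}

#' Volume-averaged sensitivity over a cell-shaped region
#'
#' Integrates `S` over the mesh elements whose centroid lies inside the
#' given cell shape, divides by the region volume (volume-weighted mean),
#' and optionally normalizes by a peak value.
#'
#' @param field a [compute_sensitivity()] result.
#' @param region a [make_cell_shape()] object positioned where the cell
#'   would be.
#' @param normalizer optional scalar (e.g. the scan peak); the result is
#'   divided by it.
#' @param mode `"signed"` averages S as is (the quantity entering the
#'   Geselowitz integral for a homogeneous perturbation); `"magnitude"`
#'   averages `|S|` (how strongly the measurement engages the volume
#'   regardless of local sign -- the conventional way to plot tetrapolar
#'   profiles, where regions of both signs above one
#'   recording electrode would otherwise cancel).  Identical for
#'   two-electrode leads, where S >= 0.
#' @return scalar volume-averaged sensitivity (normalized if a normalizer
#'   was given).
#' @export
integral_sensitivity <- function(field, region, normalizer = NULL,
                                 mode = c("signed", "magnitude")) {
  stopifnot(inherits(field, "sensitivity_field"),
            inherits(region, "cell_geometry"))
  mode <- match.arg(mode)
  mesh <- field$mesh
  sel <- cell_contains(region, mesh$centroid)
  if (!any(sel))
    stop("region at (", region$x0, ", ", region$y0, ") contains no element ",
         "centroid; the mesh needs spacing below ", signif(region$r0, 3), " um there")
  v <- mesh$vol_um3[sel]
  sv <- if (mode == "magnitude") abs(field$S[sel]) else field$S[sel]
  s <- sum(sv * v) / sum(v)
  if (!is.null(normalizer)) s <- s / normalizer
  s
}

#' Normalized sensitivity scan over cell positions
#'
#' Reproduces the volume-averaged normalized sensitivity profiles of a
#' measurement lead: solves the lead field(s) once on a cell-free mesh,
#' then volume-averages `S` over the cell shape placed at every `(x0, y0)`
#' grid point and normalizes by the peak (by default the maximum of the
#' scanned values at the smallest `y0`, so the profile at that height peaks
#' at 1).  The cell template is the adherent volume-conserving cap for
#' `y0 <= r0` and the free sphere above (the cap degenerates smoothly to
#' the sphere at `y0 = r0`).
#'
#' @param layout a [mea_layout()]; two-electrode layouts use the
#'   excitation/counter pair as the single lead; four-electrode layouts use
#'   the excitation/counter pair for current and the recording pair for
#'   voltage.
#' @param x0,y0 scan grids, um (`expand.grid` of the two is scanned).
#' @param cell_r0 free cell radius, um.
#' @param frequency lead-field frequency, Hz (default 100 kHz: conduction-
#'   dominated regime where normalized profiles are frequency-insensitive).
#' @param materials,interfaces as in [assemble_system()].
#' @param domain,resolution,fine_pad meshing controls; the fine mesh window
#'   is extended to cover the scan positions plus `fine_pad` um.
#' @param normalize `"scan_min_y0"` (peak of the values at the smallest
#'   scanned y0), `"element_peak"` (global elementwise maximum of `|S|`),
#'   or `"none"`.
#' @param mode averaging convention for the profile, see
#'   [integral_sensitivity()]; the default `"magnitude"` is the plotting
#'   convention for tetrapolar profiles (identical to `"signed"` for
#'   two-electrode leads).  The signed average is always returned in the
#'   `s_signed` column.
#' @param mesh optionally a prebuilt cell-free mesh to reuse.
#' @return data.frame of class `sensitivity_profile` with columns
#'   `x0, y0, s_avg, s_signed, s_normal`; the normalizer is stored as an
#'   attribute.
#' @export
sensitivity_scan <- function(layout, x0, y0, cell_r0 = 10, frequency = 1e5,
                             materials = material_props(),
                             interfaces = list(
                               electrode = electrode_interface_params(),
                               membrane = membrane_params()),
                             domain = simulation_domain(), resolution = 1,
                             fine_pad = 5,
                             normalize = c("scan_min_y0", "element_peak", "none"),
                             mode = c("magnitude", "signed"),
                             mesh = NULL) {
  normalize <- match.arg(normalize)
  mode <- match.arg(mode)
  grid <- expand.grid(x0 = x0, y0 = y0)
  if (is.null(mesh)) {
    fx <- range(c(grid$x0 - cell_r0 - fine_pad, grid$x0 + cell_r0 + fine_pad))
    mesh <- generate_mesh(layout, cell = NULL, domain = domain,
                          resolution = resolution, fine_x = fx)
  }
  mesh <- precompute_operator(mesh)
  # reciprocity requires both lead fields in the same volume conductor, so
  # every electrode keeps its film-backed terminal in both solves (undriven
  # terminals float with zero net current)
  sys <- assemble_system(mesh, materials, interfaces, f = frequency)
  exc <- layout$id[layout$role == "excitation"]
  cnt <- layout$id[layout$role == "counter"]
  four <- any(layout$role %in% c("recording_pos", "recording_neg"))
  sol_i <- solve_drive(sys, drive_spec(exc, cnt))
  if (four) {
    rp <- layout$id[layout$role == "recording_pos"]
    rn <- layout$id[layout$role == "recording_neg"]
    sol_e <- solve_drive(sys, drive_spec(rp, rn))
    field <- compute_sensitivity(sol_i, sol_e)
  } else {
    field <- compute_sensitivity(sol_i)
  }

  dom_ok <- grid$x0 - cell_r0 >= domain$x[1] & grid$x0 + cell_r0 <= domain$x[2]
  if (any(!dom_ok)) {
    warning(sum(!dom_ok), " grid point(s) outside the domain were skipped")
    grid <- grid[dom_ok, , drop = FALSE]
  }
  vals <- mapply(function(px, py) {
    tmpl <- make_cell_shape(cell_r0, py, adherent = py <= cell_r0, x0 = px)
    c(integral_sensitivity(field, tmpl, mode = mode),
      integral_sensitivity(field, tmpl, mode = "signed"))
  }, grid$x0, grid$y0)
  grid$s_avg <- vals[1, ]
  grid$s_signed <- vals[2, ]

  normalizer <- switch(normalize,
    scan_min_y0 = {
      y_ref <- min(grid$y0)
      max(abs(grid$s_avg[grid$y0 == y_ref]))
    },
    element_peak = max(abs(field$S)),
    none = 1)
  grid$s_normal <- grid$s_avg / normalizer
  structure(grid, class = c("sensitivity_profile", "data.frame"),
            normalizer = normalizer, frequency = frequency,
            field = field, layout_type = attr(layout, "type"))
}

#' First-order Geselowitz impedance change
#'
#' Predicts the transfer-impedance change caused by a conductivity
#' perturbation `delta_sigma` inside a region, without re-solving:
#' `dZ = sum_e S_e * (1/(k_e + d sigma) - 1/k_e) * V_e` over the affected
#' elements, with `k_e` the complex conductivity of the element's region at
#' the field frequency.  Valid to first order; a warning is issued when
#' `|delta_sigma|/sigma` exceeds 20 %.
#'
#' @param field a [compute_sensitivity()] result (unit-current drives).
#' @param region a [make_cell_shape()] volume, or a logical element mask.
#' @param delta_sigma conductivity change, S/m (scalar, may be complex).
#' @param materials the [material_props()] used for the field solves.
#' @return complex impedance change, Ohm.
#' @export
delta_z_geselowitz <- function(field, region, delta_sigma,
                               materials = material_props()) {
  mesh <- field$mesh
  sel <- if (is.logical(region)) region
         else cell_contains(region, mesh$centroid)
  if (!any(sel)) stop("perturbation region contains no element centroid")
  kk <- ifelse(mesh$region[sel] == "cytoplasm",
               complex_conductivity(materials, "cytoplasm", field$f),
               complex_conductivity(materials, "medium", field$f))
  if (any(Re(kk) + Re(delta_sigma) <= 0))
    stop("delta_sigma drives the conductivity non-positive")
  ratio <- Mod(delta_sigma) / Re(kk)
  if (any(ratio > 0.2))
    warning(sprintf("|delta_sigma|/sigma up to %.0f%%: first-order perturbation may be inaccurate",
                    100 * max(ratio)))
  drho <- 1 / (kk + delta_sigma) - 1 / kk
  vol_m3 <- mesh$vol_um3[sel] * 1e-18
  sum(field$S_complex[sel] * drho * vol_m3)
}
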