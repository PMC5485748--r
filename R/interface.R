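# Lumped equivalent-circuit models of the electrode-electrolyte interface and
# the cell membrane, and their conversion to distributed surface impedances
# used as FEM boundary conditions.

#' Electrode-electrolyte interface parameters
#'
#' Parameters of the lumped equivalent circuit of one microelectrode in
#' medium: a constant phase element (CPE) in series with a parallel RC
#' element, plus a bulk series resistance.  The interface impedance is
#' \deqn{Z_{el}(\omega) = \frac{R}{1 + j\omega R C} +
#'       \frac{1}{CPE_T (j\omega)^{CPE_P}}.}
#' `R_B` models the resistive bath; it is carried along for spectrum fitting
#' but is *not* part of `Z_el` (in the FEM model the bath is resolved
#' explicitly).
#'
#' Defaults describe a 30 um titanium-nitride microelectrode.  The CPE
#' coefficient follows the admittance-style convention
#' `Z_CPE = 1/(CPE_T (jw)^CPE_P)` with `CPE_T` in S s^CPE_P; the default
#' `2.819e-8` places the interface spectrum on the megaohm scale typical of
#' cell-sized electrodes.  `area_scale` is a dimensionless effective-area
#' multiplier accounting for surface roughness of sputtered coatings: the
#' rough electrode presents `area_scale` times the geometric disc area to the
#' double layer, which divides the lumped interface impedance realized on the
#' flat model disc.
#'
#' @param CPE_T CPE coefficient, S s^CPE_P (admittance convention).
#' @param CPE_P CPE exponent, dimensionless, in (0, 1).
#' @param R charge-transfer resistance, Ohm.
#' @param C double-layer capacitance, F.
#' @param R_B bulk series resistance, Ohm.
#' @param area_scale effective-area multiplier (default 10).
#' @return An object of class `electrode_interface_params`.
#' @export
#' @examples
#' p <- electrode_interface_params()
#' electrode_interface_impedance(1e3, p)
electrode_interface_params <- function(CPE_T = 2.819e-8, CPE_P = 0.595,
                                       R = 46.26e6, C = 2.59e-9,
                                       R_B = 3.789e3, area_scale = 10) {
  stopifnot(is.numeric(CPE_T), is.numeric(CPE_P), is.numeric(R),
            is.numeric(C), is.numeric(R_B), is.numeric(area_scale))
  if (!(CPE_P > 0 && CPE_P < 1))
    stop("CPE_P must lie strictly in (0, 1), got ", CPE_P)
  if (any(c(CPE_T, R, C, R_B, area_scale) <= 0))
    stop("CPE_T, R, C, R_B and area_scale must all be positive")
  structure(list(CPE_T = CPE_T, CPE_P = CPE_P, R = R, C = C, R_B = R_B,
                 area_scale = area_scale),
            class = "electrode_interface_params")
}

#' @export
print.electrode_interface_params <- function(x, ...) {
  cat("Electrode interface (CPE + RC):\n")
  cat(sprintf("  CPE_T = %.4g S s^P, CPE_P = %.3f\n", x$CPE_T, x$CPE_P))
  cat(sprintf("  R = %.4g Ohm, C = %.4g F, R_B = %.4g Ohm\n", x$R, x$C, x$R_B))
  cat(sprintf("  effective-area multiplier = %g\n", x$area_scale))
  invisible(x)
}

#' Lumped electrode interface impedance
#'
#' Evaluates `Z_el(w) = R/(1 + jwRC) + 1/(CPE_T (jw)^CPE_P)` at the given
#' frequencies.  The bulk resistance `R_B` is excluded: in the FEM model the
#' bath is represented explicitly by the resistive volume conductor.
#'
#' @param f frequency, Hz (vectorized); must be > 0 (the CPE diverges at DC).
#' @param params an [electrode_interface_params()] object.
#' @return complex impedance, Ohm, one value per frequency.
#' @export
electrode_interface_impedance <- function(f, params = electrode_interface_params()) {
  stopifnot(inherits(params, "electrode_interface_params"))
  if (any(f <= 0))
    stop("electrode interface impedance requires f > 0; the CPE term diverges at DC")
  w <- 2 * pi * f
  jw_p <- complex(modulus = w^params$CPE_P,
                  argument = params$CPE_P * pi / 2)   # (jw)^P, principal branch
  params$R / (1 + 1i * w * params$R * params$C) + 1 / (params$CPE_T * jw_p)
}

#' Distributed surface impedance of an electrode disc
#'
#' Converts the lumped interface impedance into the specific (per-area)
#' surface impedance applied on the electrode face in the FEM model.  A disc
#' of area `A` uniformly covered by specific impedance `z_s` has lumped
#' impedance `z_s / A`; choosing `z_s = Z_el * A / area_scale` makes the
#' realized lumped interface impedance `Z_el / area_scale`, i.e. the
#' effective-area (roughness) correction lowers the interface impedance by
#' `area_scale`.
#'
#' @param f frequency, Hz.
#' @param params an [electrode_interface_params()] object.
#' @param electrode_area geometric electrode area, um^2.
#' @return specific surface impedance, complex, Ohm m^2.
#' @export
surface_impedance_electrode <- function(f, params, electrode_area) {
  if (any(electrode_area <= 0)) stop("electrode_area must be positive")
  area_m2 <- electrode_area * 1e-12
  electrode_interface_impedance(f, params) * area_m2 / params$area_scale
}

#' Cell membrane parameters
#'
#' Passive parallel-RC description of the cell membrane as a thin layer:
#' surface conductance `g_m` and surface capacitance `c_m`.
#'
#' @param g_m membrane surface conductance, mS/cm^2 (default 1).
#' @param c_m membrane surface capacitance, uF/cm^2 (default 1).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(g_m = 1, c_m = 1) {
  if (g_m < 0) stop("g_m must be >= 0")
  if (c_m <= 0) stop("c_m must be > 0")
  structure(list(g_m = g_m, c_m = c_m), class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf("Membrane: g_m = %g mS/cm^2, c_m = %g uF/cm^2\n", x$g_m, x$c_m))
  invisible(x)
}

#' Membrane specific surface impedance
#'
#' Parallel-RC thin-layer impedance `z_m(w) = 1/(g_m + j 2 pi f c_m)`,
#' in Ohm cm^2 (the conventional unit for membrane parameters).
#'
#' @param f frequency, Hz (f >= 0).
#' @param params a [membrane_params()] object.
#' @return complex specific impedance, Ohm cm^2.
#' @seealso [membrane_surface_impedance_si()] for Ohm m^2.
#' @export
membrane_surface_impedance <- function(f, params = membrane_params()) {
  stopifnot(inherits(params, "membrane_params"))
  if (any(f < 0)) stop("f must be >= 0")
  g <- params$g_m * 1e-3          # S/cm^2
  c <- params$c_m * 1e-6          # F/cm^2
  y <- g + 1i * 2 * pi * f * c
  if (any(Mod(y) == 0))
    stop("membrane admittance is zero (g_m = 0 at DC): impedance diverges")
  1 / y
}

#' @rdname membrane_surface_impedance
#' @export
membrane_surface_impedance_si <- function(f, params = membrane_params()) {
  membrane_surface_impedance(f, params) * 1e-4   # Ohm cm^2 -> Ohm m^2
}

#' Bulk material properties
#'
#' Per-region conductivity (S/m) and relative permittivity.  Defaults:
#' phosphate-buffered saline bath (1.57 S/m, eps_r 77) and cytoplasm
#' (3 S/m, eps_r 80).
#'
#' @param medium,cytoplasm lists with entries `sigma` (S/m) and `eps_r`.
#' @return An object of class `material_props`.
#' @export
material_props <- function(medium = list(sigma = 1.57, eps_r = 77),
                           cytoplasm = list(sigma = 3, eps_r = 80)) {
  chk <- function(m, nm) {
    if (!is.list(m) || !all(c("sigma", "eps_r") %in% names(m)))
      stop(nm, " must be a list with entries sigma and eps_r")
    if (m$sigma <= 0) stop(nm, ": sigma must be > 0")
    if (m$eps_r < 1) stop(nm, ": eps_r must be >= 1")
    m[c("sigma", "eps_r")]
  }
  structure(list(medium = chk(medium, "medium"),
                 cytoplasm = chk(cytoplasm, "cytoplasm")),
            class = "material_props")
}

#' Complex conductivity of a region
#'
#' `sigma + j w eps0 eps_r` for the named region at frequency `f`.
#'
#' @param materials a [material_props()] object.
#' @param region `"medium"` or `"cytoplasm"`.
#' @param f frequency, Hz.
#' @return complex conductivity, S/m.
#' @export
complex_conductivity <- function(materials, region, f) {
  m <- materials[[region]]
  if (is.null(m)) stop("unknown region: ", region)
  m$sigma + 1i * 2 * pi * f * EPS0 * m$eps_r
}

#' Full single-electrode spectrum model (Z_el + R_B)
#'
#' The measured two-terminal spectrum of one electrode pair is dominated by
#' one interface in series with the bath; this evaluates
#' `Z(f) = R_B + Z_el(f)` -- the model that [fit_equivalent_circuit()] fits.
#'
#' @inheritParams electrode_interface_impedance
#' @return complex impedance, Ohm.
#' @export
electrode_spectrum_model <- function(f, params) {
  params$R_B + electrode_interface_impedance(f, params)
}

#' Fit the CPE + RC + R_B equivalent circuit to a measured spectrum
#'
#' Complex nonlinear least squares fit of
#' `Z(f) = R_B + R/(1+jwRC) + 1/(CPE_T (jw)^CPE_P)` using
#' Levenberg-Marquardt on the stacked real/imaginary residuals, weighted by
#' `1/|Z|` so each frequency contributes comparably across the decades.
#' Parameters are fitted on a log scale (CPE_P via logit), which enforces
#' positivity and the (0,1) bound without active constraints.
#'
#' @param freq frequencies, Hz; at least 6 values spanning >= 3 decades.
#' @param z complex impedances, Ohm, same length as `freq`.
#' @param start optional [electrode_interface_params()] with starting values;
#'   by default a heuristic start is derived from the spectrum.
#' @param area_scale carried through to the returned parameter object.
#' @return a list with elements `params` (an
#'   [electrode_interface_params()]), `residual_norm` (weighted residual
#'   2-norm), `converged` (logical) and `fit` (the `nls.lm` object).
#' @export
fit_equivalent_circuit <- function(freq, z, start = NULL, area_scale = 10) {
  stopifnot(length(freq) == length(z), length(freq) >= 6)
  if (diff(log10(range(freq))) < 3)
    stop("spectrum must span at least 3 decades of frequency")
  o <- order(freq); freq <- freq[o]; z <- z[o]
  w <- 2 * pi * freq

  # candidate starts: R_B from the high-frequency magnitude; for a grid of
  # CPE exponents, the coefficient that reproduces the low-frequency
  # magnitude; RC element sized to the remaining low-frequency impedance.
  # The least-squares surface has local minima (CPE and RC both produce
  # falling magnitude), so several starts are polished and the best kept.
  starts <- list()
  if (!is.null(start)) {
    starts <- list(start)
  } else {
    rb0 <- max(min(Mod(z)), 1e-6)
    zlo <- max(Mod(z[1]) - rb0, rb0)
    wlo <- w[1]
    for (p0 in c(0.3, 0.5, 0.7, 0.9))
      for (rfac in c(0.5, 2, 8))                  # RC corner may lie below
        for (wc in c(wlo / 10, wlo, stats::median(w))) {  # the measured band
          r0 <- zlo * rfac
          starts[[length(starts) + 1]] <- electrode_interface_params(
            CPE_T = 1 / (zlo * wlo^p0), CPE_P = p0, R = r0,
            C = 1 / (r0 * wc), R_B = rb0, area_scale = area_scale)
        }
  }

  wts <- 1 / Mod(z)
  to_theta <- function(p) c(log(p$CPE_T), stats::qlogis(p$CPE_P),
                            log(p$R), log(p$C), log(p$R_B))
  from_theta <- function(th) {
    th <- pmin(pmax(th, -300), 300)    # keep exp() away from under/overflow
    th[2] <- min(max(th[2], -30), 30)  # keep plogis() strictly inside (0, 1)
    electrode_interface_params(CPE_T = unname(exp(th[1])),
                               CPE_P = unname(stats::plogis(th[2])),
                               R = unname(exp(th[3])), C = unname(exp(th[4])),
                               R_B = unname(exp(th[5])),
                               area_scale = area_scale)
  }
  resid_fn <- function(th) {
    p <- from_theta(th)
    r <- (electrode_spectrum_model(freq, p) - z) * wts
    c(Re(r), Im(r))
  }
  fit <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(par = to_theta(st), fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-14, ptol = 1e-14))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  params <- from_theta(fit$par)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("equivalent-circuit fit did not converge (nls.lm info = ",
            fit$info, "); returning best iterate")
  list(params = params,
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = converged,
       fit = fit)
}
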