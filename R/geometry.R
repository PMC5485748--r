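# MEA layouts, cell shapes and the simulation domain.
#
# Coordinate convention: the MEA substrate is the plane y = 0, y increases
# into the bath; the electrodes lie along the x axis; all lengths in um.

#' Sphere / spherical-cap cell model
#'
#' A non-adherent cell is a sphere of radius `r0` centered at
#' `(x0, y0, z0)`; an adherent cell is a spherical cap (calotte) of the same
#' volume standing on the substrate.  The cap has height `h = r0 + y0` and
#' cap-sphere radius
#' \deqn{r = \frac{4 r_0^3}{3 h^2} + \frac{h}{3},}
#' which conserves the free-sphere volume
#' `V = 4/3 pi r0^3 = (pi h^2 / 3)(3 r - h)` exactly.  The cap model is valid
#' for `0 < y0 <= r0`; at `y0 = r0` it degenerates exactly to the full
#' sphere.  A `gap` (default 500 nm) separates cell and substrate in the
#' meshed geometry; it is excluded from the radius computation.
#'
#' @param r0 free cell radius, um (> 0).
#' @param y0 height of the cell center above the substrate, um.
#' @param adherent if `TRUE` build the volume-conserving spherical cap
#'   (requires `0 < y0 <= r0`); if `FALSE` build the free sphere.
#' @param x0,z0 lateral center position, um.
#' @param gap_nm cell-substrate gap, nm (default 500); applied as an upward
#'   translation in the meshed geometry only.
#' @return An object of class `cell_geometry` with fields `r0, x0, y0, z0,
#'   shape, h, r_cap, gap` (gap in um).
#' @export
#' @examples
#' make_cell_shape(10, 5, adherent = TRUE)    # cap: h = 15, r_cap = 10.926
#' make_cell_shape(10, 15)                    # free sphere 5 um above substrate
make_cell_shape <- function(r0, y0 = r0, adherent = FALSE, x0 = 0, z0 = 0,
                            gap_nm = 500) {
  if (r0 <= 0) stop("r0 must be positive")
  gap <- gap_nm * 1e-3
  if (adherent) {
    if (y0 <= 0)
      stop("invalid geometry: the spherical-cap model requires y0 > 0")
    if (y0 > r0) {
      warning("y0 > r0: cap degenerates (cell detached); falling back to a sphere")
      adherent <- FALSE
    }
  }
  if (adherent) {
    h <- r0 + y0
    r_cap <- 4 * r0^3 / (3 * h^2) + h / 3
    shape <- "spherical_cap"
  } else {
    h <- 2 * r0
    r_cap <- r0
    shape <- "sphere"
  }
  structure(list(r0 = r0, x0 = x0, y0 = y0, z0 = z0, shape = shape,
                 h = h, r_cap = r_cap, gap = gap),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell (%s): r0 = %g um at (%g, %g, %g) um\n",
              x$shape, x$r0, x$x0, x$y0, x$z0))
  if (x$shape == "spherical_cap")
    cat(sprintf("  cap height h = %g um, cap radius r = %.4f um\n", x$h, x$r_cap))
  cat(sprintf("  volume = %.2f um^3, substrate gap = %g nm\n",
              cell_volume(x), x$gap * 1e3))
  invisible(x)
}

#' Cell volume
#'
#' Analytic volume of the cell shape, um^3.  By construction the cap volume
#' equals the free-sphere volume `4/3 pi r0^3`.
#' @param cell a [make_cell_shape()] object.
#' @export
cell_volume <- function(cell) {
  if (cell$shape == "spherical_cap")
    pi * cell$h^2 / 3 * (3 * cell$r_cap - cell$h)
  else
    4 / 3 * pi * cell$r0^3
}

# Upward translation applied when the shape is placed in the meshed bath:
# the shape is lifted so its lowest point sits `gap` above the substrate
# (caps always start at the substrate; spheres only if they would touch it).
cell_mesh_lift <- function(cell) {
  bottom <- if (cell$shape == "spherical_cap") 0 else cell$y0 - cell$r0
  max(0, cell$gap - bottom)
}

#' Point membership of the meshed cell shape
#'
#' Tests which points lie inside the cell volume as it is placed in the
#' meshed geometry (i.e. including the substrate gap translation).
#'
#' @param cell a [make_cell_shape()] object.
#' @param pts numeric matrix, n x 3 (x, y, z in um).
#' @return logical vector of length n.
#' @export
cell_contains <- function(cell, pts) {
  pts <- matrix(pts, ncol = 3)
  lift <- cell_mesh_lift(cell)
  if (cell$shape == "spherical_cap") {
    base <- lift                            # cap base plane height
    yc <- base + cell$h - cell$r_cap        # cap-sphere center height
    d2 <- (pts[, 1] - cell$x0)^2 + (pts[, 2] - yc)^2 + (pts[, 3] - cell$z0)^2
    d2 <= cell$r_cap^2 & pts[, 2] >= base
  } else {
    yc <- cell$y0 + lift
    d2 <- (pts[, 1] - cell$x0)^2 + (pts[, 2] - yc)^2 + (pts[, 3] - cell$z0)^2
    d2 <= cell$r0^2
  }
}

# y-extent of the meshed shape (used for mesh grading), um
cell_y_extent <- function(cell) {
  lift <- cell_mesh_lift(cell)
  if (cell$shape == "spherical_cap") c(lift, lift + cell$h)
  else c(cell$y0 + lift - cell$r0, cell$y0 + lift + cell$r0)
}

#' MEA electrode layout
#'
#' Builds a planar electrode layout.  The two named defaults reproduce a
#' standard MEA measurement geometry with 30 um discs: the two-electrode
#' setup has an excitation/counter pair at x = -50 and +50 um; the
#' four-electrode setup adds an outer current-carrying pair at -150 and
#' +150 um and uses the inner pair as floating recording electrodes.
#'
#' @param type `"two_electrode"`, `"four_electrode"`, or `"custom"` (then
#'   `electrodes` must be given).
#' @param diameter electrode diameter, um (default 30).
#' @param electrodes for `type = "custom"`: a data.frame with columns
#'   `id`, `x`, `z`, `diameter`, `role`; roles from
#'   `excitation, counter, recording_pos, recording_neg, passive`.
#' @return An object of class `mea_layout`: a data.frame of electrodes with
#'   attribute `type`.
#' @export
#' @examples
#' mea_layout("two_electrode")
#' mea_layout("four_electrode")
mea_layout <- function(type = c("two_electrode", "four_electrode", "custom"),
                       diameter = 30, electrodes = NULL) {
  type <- match.arg(type)
  if (type == "two_electrode") {
    electrodes <- data.frame(
      id = c("E2", "E3"), x = c(-50, 50), z = c(0, 0),
      diameter = diameter, role = c("excitation", "counter"))
  } else if (type == "four_electrode") {
    electrodes <- data.frame(
      id = c("E1", "E2", "E3", "E4"), x = c(-150, -50, 50, 150), z = 0,
      diameter = diameter,
      role = c("excitation", "recording_pos", "recording_neg", "counter"))
  } else {
    if (is.null(electrodes) || nrow(electrodes) == 0)
      stop("configuration error: custom layout requires a non-empty electrode table")
    req <- c("id", "x", "z", "diameter", "role")
    if (!all(req %in% names(electrodes)))
      stop("configuration error: electrode table needs columns ",
           paste(req, collapse = ", "))
  }
  validate_layout(electrodes)
  structure(electrodes, class = c("mea_layout", "data.frame"), type = type)
}

validate_layout <- function(e) {
  roles <- c("excitation", "counter", "recording_pos", "recording_neg", "passive")
  if (!all(e$role %in% roles))
    stop("configuration error: unknown role(s): ",
         paste(setdiff(e$role, roles), collapse = ", "))
  for (r in c("excitation", "counter", "recording_pos", "recording_neg")) {
    n <- sum(e$role == r)
    if (n > 1) stop("configuration error: duplicate role ", r)
  }
  if (sum(e$role == "excitation") != 1 || sum(e$role == "counter") != 1)
    stop("configuration error: layout needs exactly one excitation and one counter electrode")
  nrec <- sum(e$role %in% c("recording_pos", "recording_neg"))
  if (!nrec %in% c(0, 2))
    stop("configuration error: recording electrodes must come as a pos/neg pair")
  if (anyDuplicated(e$id)) stop("configuration error: duplicate electrode ids")
  if (any(e$diameter <= 0)) stop("configuration error: non-positive diameter")
  if (nrow(e) > 1) {
    d <- as.matrix(stats::dist(e[, c("x", "z")]))
    rr <- outer(e$diameter / 2, e$diameter / 2, "+")
    diag(d) <- Inf
    if (any(d < rr))
      stop("configuration error: overlapping electrode discs")
  }
  invisible(e)
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("MEA layout (%s), %d electrodes in the plane y = 0:\n",
              attr(x, "type"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Simulation domain (bath box)
#'
#' Axis-aligned box holding the bath medium; the substrate is the face
#' y = `y[1]` (normally 0) and all outer faces are electrically insulating.
#' The default 800 x 400 x 400 um box is large against the electrode
#' constellation; doubling it changes two-electrode lumped impedances by
#' well under a percent (see the package vignette).
#'
#' @param x,y,z two-element numeric ranges, um.
#' @return An object of class `simulation_domain`.
#' @export
simulation_domain <- function(x = c(-400, 400), y = c(0, 400),
                              z = c(-200, 200)) {
  stopifnot(length(x) == 2, length(y) == 2, length(z) == 2,
            x[1] < x[2], y[1] < y[2], z[1] < z[2])
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "simulation_domain")
}

#' @export
print.simulation_domain <- function(x, ...) {
  cat(sprintf("Bath domain: x [%g, %g] x y [%g, %g] x z [%g, %g] um, insulating outer faces\n",
              x$x[1], x$x[2], x$y[1], x$y[2], x$z[1], x$z[2]))
  invisible(x)
}

# checks that layout and cell fit in the domain with margin
check_domain_fit <- function(layout, cell, domain) {
  ex <- range(layout$x - layout$diameter / 2, layout$x + layout$diameter / 2)
  ez <- range(layout$z - layout$diameter / 2, layout$z + layout$diameter / 2)
  if (ex[1] < domain$x[1] || ex[2] > domain$x[2] ||
      ez[1] < domain$z[1] || ez[2] > domain$z[2])
    stop("domain does not contain all electrodes")
  if (!is.null(cell)) {
    yy <- cell_y_extent(cell)
    if (cell$x0 - cell$r_cap < domain$x[1] || cell$x0 + cell$r_cap > domain$x[2] ||
        cell$z0 - cell$r_cap < domain$z[1] || cell$z0 + cell$r_cap > domain$z[2] ||
        yy[2] > domain$y[2])
      stop("domain does not contain the cell")
  }
  invisible(TRUE)
}
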