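# Graded structured tetrahedral mesher.
#
# The bath box is discretized by a tensor-product grid, uniform and fine over
# a window enclosing the electrodes (and the cell, if present), geometrically
# coarsened toward the outer walls, and each hexahedral grid cell is split
# into six tetrahedra along a common diagonal (Kuhn subdivision, which is
# conforming across cells).  Grid planes are forced onto the electrode edges
# and onto the cell-substrate gap so that the disc boundaries and the thin
# medium film under an adherent cell are resolved exactly in the grid.
#
# The cell membrane is represented topologically: mesh nodes shared between
# cytoplasm and medium elements are duplicated, cytoplasm connectivity is
# rewritten onto the duplicates, and the facets between the two regions are
# stored as (outer, inner) triangle pairs.  The FEM assembly couples the two
# sides through the membrane surface admittance, giving the thin-layer
# potential-jump condition.

# -- 1D grid helpers ---------------------------------------------------------

# geometric coarsening from `from` toward `to`, starting at step h0
grade_axis <- function(from, to, h0, ratio = 1.4, h_max = 250) {
  len <- abs(to - from)
  if (len < h0 * 0.6) return(numeric(0))
  s <- sign(to - from)
  steps <- numeric(0); h <- h0; tot <- 0
  while (tot < len) {
    h <- min(h * ratio, h_max)
    steps <- c(steps, h)
    tot <- tot + h
  }
  steps <- steps * (len / tot)          # stretch to fit exactly
  from + s * cumsum(steps)
}

# fine grid over [lo, hi] honoring mandatory interior breakpoints
fine_axis <- function(lo, hi, h, breaks = numeric(0)) {
  bp <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  out <- bp[1]
  for (i in seq_len(length(bp) - 1)) {
    a <- bp[i]; b <- bp[i + 1]
    n <- max(1L, round((b - a) / h))
    out <- c(out, a + (b - a) * seq_len(n) / n)
  }
  out
}

# complete 1D axis: graded | fine | graded
build_axis <- function(dom, fine_lo, fine_hi, h, breaks = numeric(0),
                       ratio = 1.4) {
  fine_lo <- max(fine_lo, dom[1]); fine_hi <- min(fine_hi, dom[2])
  mid <- fine_axis(fine_lo, fine_hi, h, breaks)
  left <- rev(grade_axis(fine_lo, dom[1], h, ratio))
  right <- grade_axis(fine_hi, dom[2], h, ratio)
  xs <- c(left, mid, right)
  xs[!duplicated(signif(xs, 12))]
}

#' Mesh resolution control
#'
#' Target edge lengths (um) of the fine mesh region.  `resolution` is a
#' global multiplier on mesh density: spacings scale as `1/resolution`, so
#' `resolution = 2` halves all fine edge lengths.
#'
#' @param resolution global density multiplier (default 1).
#' @param h_xz in-plane spacing in the fine window, um.
#' @param h_y vertical spacing near the substrate, um (default from a
#'   convergence study of the disc spreading resistance: 1.8 um keeps the
#'   near-plane field error at the percent level).
#' @param y_fine height up to which the fine vertical spacing is used, um.
#' @param ratio geometric coarsening ratio toward the outer walls.
#' @return list of spacing controls.
#' @export
mesh_resolution <- function(resolution = 1, h_xz = 4, h_y = 1.8,
                            y_fine = 30, ratio = 1.4) {
  stopifnot(resolution > 0)
  list(h_xz = h_xz / resolution, h_y = h_y / resolution,
       y_fine = y_fine, ratio = ratio, resolution = resolution)
}

# -- mesh generation ---------------------------------------------------------

#' Generate a labeled tetrahedral mesh of the MEA bath
#'
#' Builds the simulation mesh for a layout, an optional cell, and a bath
#' domain.  Elements are labeled `medium` or `cytoplasm`; electrode faces on
#' the substrate are tagged per electrode; the cytoplasm/medium interface is
#' extracted as a closed membrane surface with duplicated nodes (see the
#' file header for the discretization strategy).  The construction is fully
#' deterministic given the geometry and resolution control; `seed` is
#' recorded for provenance.
#'
#' @param layout a [mea_layout()].
#' @param cell a [make_cell_shape()] object, or `NULL` for a baseline
#'   (cell-free) mesh.
#' @param domain a [simulation_domain()].
#' @param resolution a [mesh_resolution()] object or a single number passed
#'   to `mesh_resolution()`.
#' @param fine_x optional two-element range (um) that the fine in-plane mesh
#'   window must additionally cover (e.g. a sensitivity-scan range).
#' @param seed recorded in the mesh metadata.
#' @return An object of class `mea_mesh`.
#' @export
generate_mesh <- function(layout, cell = NULL, domain = simulation_domain(),
                          resolution = 1, fine_x = NULL, seed = 1L) {
  stopifnot(inherits(layout, "mea_layout"),
            inherits(domain, "simulation_domain"))
  if (!is.null(cell) && !inherits(cell, "cell_geometry"))
    stop("cell must be a cell_geometry or NULL")
  if (!is.list(resolution)) resolution <- mesh_resolution(resolution)
  check_domain_fit(layout, cell, domain)
  if (!is.null(cell) && cell_intersects_electrode(cell, layout))
    stop("meshing failure: cell '", cell$shape, "' at (", cell$x0, ", ",
         cell$y0, ") intersects an electrode volume")

  r <- layout$diameter / 2
  exg <- range(c(layout$x - r, layout$x + r))
  ezg <- range(c(layout$z - r, layout$z + r))
  pad <- 10
  fx <- exg + c(-pad, pad); fz <- ezg + c(-pad, pad)
  if (!is.null(fine_x)) fx <- range(c(fx, fine_x))
  if (!is.null(cell)) {
    fx <- range(c(fx, cell$x0 - cell$r_cap - 5, cell$x0 + cell$r_cap + 5))
    fz <- range(c(fz, cell$z0 - cell$r_cap - 5, cell$z0 + cell$r_cap + 5))
  }
  # cluster grid lines toward the disc rims: the current density has an
  # edge singularity there and uniform spacing converges slowly
  h0 <- resolution$h_xz
  edge_cluster <- function(edges) as.vector(outer(c(-2/3, -1/3, 0, 1/3, 2/3) * h0, edges, "+"))
  xbreaks <- c(layout$x, edge_cluster(c(layout$x - r, layout$x + r)))
  zbreaks <- c(layout$z, edge_cluster(c(layout$z - r, layout$z + r)))
  ybreaks <- numeric(0)
  y_top_fine <- resolution$y_fine
  if (!is.null(cell)) {
    ye <- cell_y_extent(cell)
    ybreaks <- c(ybreaks, ye[1])
    y_top_fine <- max(y_top_fine, ye[2] + 2)
    xbreaks <- c(xbreaks, cell$x0)
    zbreaks <- c(zbreaks, cell$z0)
  }

  xs <- build_axis(domain$x, fx[1], fx[2], resolution$h_xz, xbreaks,
                   resolution$ratio)
  zs <- build_axis(domain$z, fz[1], fz[2], resolution$h_xz, zbreaks,
                   resolution$ratio)
  ys <- c(domain$y[1],
          domain$y[1] + sort(unique(signif(c(
            fine_axis(0, y_top_fine, resolution$h_y,
                      ybreaks - domain$y[1])[-1],
            grade_axis(y_top_fine, diff(domain$y), resolution$h_y,
                       resolution$ratio)), 12))))

  grid <- tensor_tet_grid(xs, ys, zs)
  nodes <- grid$nodes; tets <- grid$tets

  # region labels by element centroid
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
           nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  region <- rep("medium", nrow(tets))
  if (!is.null(cell)) {
    inside <- cell_contains(cell, cent)
    region[inside] <- "cytoplasm"
    if (!any(inside))
      stop("meshing failure: no element centroid falls inside the cell; ",
           "increase the mesh resolution")
  }

  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("internal mesher error: non-positive element volume")

  mem <- extract_membrane(nodes, tets, region)
  nodes <- mem$nodes; tets <- mem$tets

  elec <- extract_electrode_facets(nodes, tets, layout, domain)

  structure(list(
    nodes = nodes, n_base = grid$n, tets = tets, region = region,
    vol_um3 = vol, centroid = cent,
    membrane = mem$membrane, elec = elec,
    layout = layout, cell = cell, domain = domain,
    resolution = resolution, seed = seed,
    quality = tet_quality(nodes, tets)),
    class = "mea_mesh")
}

cell_intersects_electrode <- function(cell, layout) {
  # electrodes are zero-thickness discs at y=0; the meshed cell is lifted by
  # the gap, so a geometric collision only happens for a non-positive lift
  ye <- cell_y_extent(cell)
  ye[1] <= 0
}

# tensor grid -> Kuhn tetrahedra (vectorized over all hex cells)
tensor_tet_grid <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  nid <- function(i, j, k) (k - 1L) * (nx * ny) + (j - 1L) * nx + i
  hi <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  hj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  hk <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  v <- function(dx, dy, dz) nid(hi + dx, hj + dy, hk + dz)
  v000 <- v(0L,0L,0L); v100 <- v(1L,0L,0L); v010 <- v(0L,1L,0L)
  v001 <- v(0L,0L,1L); v110 <- v(1L,1L,0L); v101 <- v(1L,0L,1L)
  v011 <- v(0L,1L,1L); v111 <- v(1L,1L,1L)
  # six tets around the v000-v111 diagonal
  tets <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v110, v010, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v011, v001, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v101, v100, v111))
  # fix orientation (positive volume)
  a <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  b <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  cc <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  neg <- det6 < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  list(nodes = nodes, tets = tets, n = nrow(nodes))
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  abs(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# crude shape quality: min (3 * inradius / circum-ish edge) over the mesh
tet_quality <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  emax <- rep(0, nrow(tets))
  for (pr in list(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))) {
    d <- nodes[tets[, pr[1]], , drop = FALSE] - nodes[tets[, pr[2]], , drop = FALSE]
    emax <- pmax(emax, sqrt(rowSums(d^2)))
  }
  q <- (6 * sqrt(2) * v)^(1 / 3) / emax   # 1 for the regular tet
  min(q)
}

# encode sorted node triples as doubles for face matching (vectorized sort)
face_key <- function(tri, nmax) {
  a <- pmin(tri[, 1], tri[, 2], tri[, 3])
  c3 <- pmax(tri[, 1], tri[, 2], tri[, 3])
  b <- tri[, 1] + tri[, 2] + tri[, 3] - a - c3
  (as.numeric(a) * nmax + b) * nmax + c3
}

tet_faces <- function(tets) {
  rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
        tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
}

tri_areas <- function(nodes, tri) {
  a <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  b <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# membrane extraction + node duplication
extract_membrane <- function(nodes, tets, region) {
  cyto <- region == "cytoplasm"
  if (!any(cyto))
    return(list(nodes = nodes, tets = tets,
                membrane = list(outer = matrix(integer(0), 0, 3),
                                inner = matrix(integer(0), 0, 3),
                                area_um2 = numeric(0))))
  n <- nrow(nodes)
  cy_nodes <- unique(as.vector(tets[cyto, ]))
  md_nodes <- unique(as.vector(tets[!cyto, ]))
  iface <- intersect(cy_nodes, md_nodes)

  # membrane facets: faces shared by a cytoplasm and a medium tet
  fc <- tet_faces(tets[cyto, , drop = FALSE])
  fm <- tet_faces(tets[!cyto, , drop = FALSE])
  kc <- face_key(fc, n + 1); km <- face_key(fm, n + 1)
  sel <- kc %in% km
  outer_tri <- fc[sel, , drop = FALSE]
  outer_tri <- outer_tri[!duplicated(face_key(outer_tri, n + 1)), , drop = FALSE]

  # cytoplasm faces not shared with medium must be interior cyto/cyto faces
  # (appear twice); a once-only face would sit on the domain boundary
  kco <- kc[!(kc %in% km)]
  if (length(kco)) {
    once <- !(duplicated(kco) | duplicated(kco, fromLast = TRUE))
    if (any(once))
      stop("meshing failure: cytoplasm region touches the domain boundary")
  }

  # duplicate interface nodes; cytoplasm connectivity uses the duplicates
  map <- integer(n); map[iface] <- n + seq_along(iface)
  nodes2 <- rbind(nodes, nodes[iface, , drop = FALSE])
  tc <- tets[cyto, , drop = FALSE]
  repl <- map[tc] != 0L
  tc[repl] <- map[tc][repl]
  tets[cyto, ] <- tc
  inner_tri <- matrix(map[outer_tri], ncol = 3)
  if (any(inner_tri == 0L))
    stop("internal mesher error: membrane facet node without duplicate")

  list(nodes = nodes2, tets = tets,
       membrane = list(outer = outer_tri, inner = inner_tri,
                       area_um2 = tri_areas(nodes, outer_tri)))
}

extract_electrode_facets <- function(nodes, tets, layout, domain) {
  n <- nrow(nodes)
  f <- tet_faces(tets)
  k <- face_key(f, n + 1)
  once <- !(duplicated(k) | duplicated(k, fromLast = TRUE))
  bnd <- f[once, , drop = FALSE]
  y0 <- domain$y[1]
  onplane <- abs(nodes[bnd[, 1], 2] - y0) < 1e-9 &
             abs(nodes[bnd[, 2], 2] - y0) < 1e-9 &
             abs(nodes[bnd[, 3], 2] - y0) < 1e-9
  bnd <- bnd[onplane, , drop = FALSE]
  cx <- (nodes[bnd[, 1], 1] + nodes[bnd[, 2], 1] + nodes[bnd[, 3], 1]) / 3
  cz <- (nodes[bnd[, 1], 3] + nodes[bnd[, 2], 3] + nodes[bnd[, 3], 3]) / 3
  elec <- list()
  for (i in seq_len(nrow(layout))) {
    rr <- layout$diameter[i] / 2
    sel <- (cx - layout$x[i])^2 + (cz - layout$z[i])^2 <= rr^2 * (1 + 1e-9)
    tri <- bnd[sel, , drop = FALSE]
    if (nrow(tri) == 0)
      stop("meshing failure: electrode ", layout$id[i],
           " is not covered by any boundary facet")
    ar <- tri_areas(nodes, tri)
    nominal <- pi * rr^2
    if (sum(ar) < 0.5 * nominal)
      stop("meshing failure: electrode ", layout$id[i],
           " covered by less than half its nominal area; refine the mesh")
    # nodes usable as an equipotential tie for ideal (film-free) electrodes:
    # plane nodes inside the disc radius (facet-based sets overshoot by h/2)
    pl <- which(abs(nodes[, 2] - y0) < 1e-9)
    tie <- pl[(nodes[pl, 1] - layout$x[i])^2 +
              (nodes[pl, 3] - layout$z[i])^2 <= rr^2 * (1 + 1e-9)]
    elec[[layout$id[i]]] <- list(tri = tri, area_um2 = ar,
                                 role = layout$role[i],
                                 nominal_area_um2 = nominal,
                                 tie_nodes = sort(tie))
  }
  elec
}

#' @export
print.mea_mesh <- function(x, ...) {
  cat(sprintf("MEA mesh: %d nodes, %d tetrahedra (%d cytoplasm), %d electrodes\n",
              nrow(x$nodes), nrow(x$tets), sum(x$region == "cytoplasm"),
              length(x$elec)))
  cat(sprintf("  membrane facets: %d; min element quality: %.3f\n",
              nrow(x$membrane$outer), x$quality))
  cat(sprintf("  fine spacing: h_xz = %.2f um, h_y = %.2f um\n",
              x$resolution$h_xz, x$resolution$h_y))
  invisible(x)
}

#' Mesh summary statistics
#' @param mesh a `mea_mesh`.
#' @return named list of counts and quality metrics.
#' @export
mesh_stats <- function(mesh) {
  list(n_nodes = nrow(mesh$nodes),
       n_elements = nrow(mesh$tets),
       n_cytoplasm = sum(mesh$region == "cytoplasm"),
       n_membrane_facets = nrow(mesh$membrane$outer),
       electrode_cover = vapply(mesh$elec, function(e)
         sum(e$area_um2) / e$nominal_area_um2, numeric(1)),
       min_quality = mesh$quality,
       total_volume_um3 = sum(mesh$vol_um3))
}
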