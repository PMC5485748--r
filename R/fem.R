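# Quasi-static complex-conductivity FEM core.
#
# Unknowns: nodal potentials phi (P1 tetrahedra, complex) plus one terminal
# voltage per electrode.  Weak form of
#     div((sigma + j w eps0 eps_r) grad phi) = 0
# with insulating outer walls, the complete electrode model on each
# electrode face (distributed surface impedance z_s behind an equipotential
# terminal), and a thin-layer membrane jump condition (potential jump
# proportional to the normal current density through surface impedance z_m).
# The drive grounds its sink terminal at solve time, so any electrode pair
# can serve as a current lead (needed for reciprocal lead-field drives).
#
# The grounded system K = Kr + j Ki has symmetric positive-definite real
# part and positive-semidefinite imaginary part; it is solved by complex
# BiCGStab preconditioned with a sparse Cholesky factorization of
# (Kr + Ki).  For this matrix class the preconditioned spectrum lies in a
# sector bounded away from zero and the iteration converges in a handful of
# steps, each costing two triangular solves.

# -- frequency-independent geometric operator --------------------------------

# Per-region volume stiffness, membrane jump surface-mass, and per-electrode
# surface-mass blocks.  All in SI units (meters).  Cached via attribute by
# callers that reuse a mesh across frequencies.
fem_operator <- function(mesh) {
  nodes_m <- mesh$nodes * 1e-6
  nn <- nrow(nodes_m)
  tets <- mesh$tets

  stiff_parts <- function(sel) {
    tt <- tets[sel, , drop = FALSE]
    m <- nrow(tt)
    p1 <- nodes_m[tt[, 1], , drop = FALSE]; p2 <- nodes_m[tt[, 2], , drop = FALSE]
    p3 <- nodes_m[tt[, 3], , drop = FALSE]; p4 <- nodes_m[tt[, 4], , drop = FALSE]
    a <- p2 - p1; b <- p3 - p1; cc <- p4 - p1
    det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
           a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    vol <- abs(det) / 6
    # columns of inv([a|b|c]) give grad l2, grad l3, grad l4; grad l1 = -sum
    g <- array(0, c(m, 4, 3))
    g[, 2, 1] <- (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) / det
    g[, 2, 2] <- (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) / det
    g[, 2, 3] <- (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]) / det
    g[, 3, 1] <- (cc[, 2] * a[, 3] - cc[, 3] * a[, 2]) / det
    g[, 3, 2] <- (cc[, 3] * a[, 1] - cc[, 1] * a[, 3]) / det
    g[, 3, 3] <- (cc[, 1] * a[, 2] - cc[, 2] * a[, 1]) / det
    g[, 4, 1] <- (a[, 2] * b[, 3] - a[, 3] * b[, 2]) / det
    g[, 4, 2] <- (a[, 3] * b[, 1] - a[, 1] * b[, 3]) / det
    g[, 4, 3] <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
    g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
    ii <- jj <- matrix(0L, m, 16); xx <- matrix(0, m, 16)
    col <- 1L
    for (ia in 1:4) for (ja in 1:4) {
      ii[, col] <- tt[, ia]; jj[, col] <- tt[, ja]
      xx[, col] <- vol * (g[, ia, 1] * g[, ja, 1] + g[, ia, 2] * g[, ja, 2] +
                          g[, ia, 3] * g[, ja, 3])
      col <- col + 1L
    }
    K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                              x = as.vector(xx), dims = c(nn, nn))
    list(K = K, grads = g, vol = vol, tt = tt)
  }

  med <- mesh$region == "medium"
  sm <- stiff_parts(med)
  grads <- list(medium = sm[c("grads", "vol", "tt")])
  K_cyto <- NULL
  if (any(!med)) {
    sc <- stiff_parts(!med)
    K_cyto <- sc$K
    grads$cytoplasm <- sc[c("grads", "vol", "tt")]
  }

  # triangle surface-mass triplets: area/12 * [2 1 1; 1 2 1; 1 1 2]
  mass_triplets <- function(rowtri, coltri, area_m2) {
    ii <- jj <- matrix(0L, nrow(rowtri), 9); xx <- matrix(0, nrow(rowtri), 9)
    col <- 1L
    for (ia in 1:3) for (ja in 1:3) {
      ii[, col] <- rowtri[, ia]; jj[, col] <- coltri[, ja]
      xx[, col] <- area_m2 * (if (ia == ja) 2 else 1) / 12
      col <- col + 1L
    }
    list(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx))
  }

  # membrane jump quadratic form: (phi_out - phi_in)' M (phi_out - phi_in)
  memb <- mesh$membrane
  M_jump <- NULL
  if (nrow(memb$outer) > 0) {
    am <- memb$area_um2 * 1e-12
    mo <- mass_triplets(memb$outer, memb$outer, am)
    mi <- mass_triplets(memb$inner, memb$inner, am)
    mx <- mass_triplets(memb$outer, memb$inner, am)
    M_jump <- Matrix::sparseMatrix(
      i = c(mo$i, mi$i, mx$i, mx$j),
      j = c(mo$j, mi$j, mx$j, mx$i),
      x = c(mo$x, mi$x, -mx$x, -mx$x), dims = c(nn, nn))
  }

  elec <- lapply(mesh$elec, function(e) {
    am <- e$area_um2 * 1e-12
    mt <- mass_triplets(e$tri, e$tri, am)
    M <- Matrix::sparseMatrix(i = mt$i, j = mt$j, x = mt$x, dims = c(nn, nn))
    b <- numeric(nn)
    for (cidx in 1:3) {
      agg <- rowsum(am / 3, group = e$tri[, cidx])
      idx <- as.integer(rownames(agg))
      b[idx] <- b[idx] + agg[, 1]
    }
    list(M = M, b = b, area_m2 = sum(am),
         nominal_area_m2 = e$nominal_area_um2 * 1e-12, role = e$role,
         face_nodes = e$tie_nodes)
  })

  list(n = nn, K_med = sm$K, K_cyto = K_cyto, M_jump = M_jump,
       elec = elec, grads = grads)
}

get_operator <- function(mesh) {
  op <- attr(mesh, "fem_operator", exact = TRUE)
  if (is.null(op)) op <- fem_operator(mesh)
  op
}

#' Precompute the frequency-independent FEM operator of a mesh
#'
#' Assembling the geometric stiffness and surface-coupling matrices is the
#' dominant cost of [assemble_system()]; this attaches them to the mesh so
#' that spectra and parameter studies over many frequencies reuse them.
#'
#' @param mesh a [generate_mesh()] result.
#' @return the mesh with the operator cached in an attribute.
#' @export
precompute_operator <- function(mesh) {
  attr(mesh, "fem_operator") <- get_operator(mesh)
  mesh
}

# -- per-frequency assembly --------------------------------------------------

#' Assemble the complex FEM system at one frequency
#'
#' Forms the complex symmetric system for the quasi-static potential with
#' region-wise complex conductivity `sigma + j w eps0 eps_r`, the membrane
#' thin-layer jump condition, and the complete electrode model: every
#' electrode face is coupled to an equipotential terminal through its
#' distributed interface impedance.  Grounding is applied at solve time by
#' [solve_drive()], so any electrode pair can be driven.
#'
#' @param mesh a [generate_mesh()] result (ideally after
#'   [precompute_operator()]).
#' @param materials a [material_props()] object.
#' @param interfaces list with entries `electrode` (an
#'   [electrode_interface_params()]) and `membrane` (a [membrane_params()]).
#'   `electrode = NULL` means ideal (zero-impedance) electrode faces.
#' @param f frequency, Hz (> 0).
#' @param insulate character vector of electrode ids whose faces are treated
#'   as plain insulating boundary (no interface film, no terminal, no metal
#'   shunt).  Their "terminal voltage" is recovered afterwards as the
#'   area-averaged potential over the face -- the reading of an ideal
#'   infinite-impedance amplifier on an electrode that does not perturb the
#'   field.  This is how floating recording electrodes are represented in
#'   the four-electrode measurement model.
#' @return An object of class `fem_system` (opaque; pass to
#'   [solve_drive()]).
#' @export
assemble_system <- function(mesh, materials = material_props(),
                            interfaces = list(
                              electrode = electrode_interface_params(),
                              membrane = membrane_params()),
                            f, insulate = character(0)) {
  stopifnot(inherits(mesh, "mea_mesh"))
  if (f <= 0) stop("assembly requires f > 0")
  op <- get_operator(mesh)
  nn <- op$n
  ids <- names(op$elec)
  nt <- length(ids)
  if (nt < 2) stop("assembly error: need at least two electrodes (no ground possible)")
  N <- nn + nt

  tri_i <- list(); tri_j <- list(); tri_r <- list(); tri_m <- list()
  add <- function(M, scale_r, scale_i) {
    Mt <- as(M, "TsparseMatrix")
    tri_i[[length(tri_i) + 1]] <<- Mt@i + 1L
    tri_j[[length(tri_j) + 1]] <<- Mt@j + 1L
    tri_r[[length(tri_r) + 1]] <<- scale_r * Mt@x
    tri_m[[length(tri_m) + 1]] <<- scale_i * Mt@x
  }

  k_med <- complex_conductivity(materials, "medium", f)
  add(op$K_med, Re(k_med), Im(k_med))
  if (!is.null(op$K_cyto)) {
    k_cy <- complex_conductivity(materials, "cytoplasm", f)
    add(op$K_cyto, Re(k_cy), Im(k_cy))
  }
  if (!is.null(op$M_jump)) {
    if (is.null(interfaces$membrane))
      stop("mesh has membrane facets but no membrane model was supplied")
    ym <- 1 / membrane_surface_impedance_si(f, interfaces$membrane)  # S/m^2
    add(op$M_jump, Re(ym), Im(ym))
  }

  ideal <- is.null(interfaces$electrode)
  if (length(setdiff(insulate, ids)))
    stop("unknown electrode id(s) in insulate: ",
         paste(setdiff(insulate, ids), collapse = ", "))
  ys <- setNames(rep(NA_complex_, nt), ids)
  for (l in seq_len(nt)) {
    e <- op$elec[[l]]
    ti <- nn + l
    if (ids[l] %in% insulate) {
      # bare insulating face: natural BC, decoupled terminal placeholder
      tri_i[[length(tri_i) + 1]] <- ti
      tri_j[[length(tri_j) + 1]] <- ti
      tri_r[[length(tri_r) + 1]] <- 1
      tri_m[[length(tri_m) + 1]] <- 0
    } else if (!ideal) {
      zs <- surface_impedance_electrode(f, interfaces$electrode,
                                        e$nominal_area_m2 * 1e12)
      y <- 1 / zs
      ys[[l]] <- y
      add(e$M, Re(y), Im(y))
      nz <- which(e$b != 0)
      vv <- e$b[nz]
      tri_i[[length(tri_i) + 1]] <- c(nz, rep(ti, length(nz)), ti)
      tri_j[[length(tri_j) + 1]] <- c(rep(ti, length(nz)), nz, ti)
      tri_r[[length(tri_r) + 1]] <- c(-Re(y) * vv, -Re(y) * vv, Re(y) * e$area_m2)
      tri_m[[length(tri_m) + 1]] <- c(-Im(y) * vv, -Im(y) * vv, Im(y) * e$area_m2)
    }
  }

  ii <- unlist(tri_i); jj <- unlist(tri_j)
  merged <- integer(0)
  if (ideal) {
    # ideal electrodes: condense each face's nodes into its terminal dof
    # (exact equipotential constraint by index merging)
    remap <- seq_len(N)
    for (l in seq_len(nt)) {
      if (ids[l] %in% insulate) next
      nz <- op$elec[[l]]$face_nodes
      remap[nz] <- nn + l
      merged <- c(merged, nz)
    }
    ii <- remap[ii]; jj <- remap[jj]
    # keep merged node dofs well-posed (decoupled identity rows; their
    # potential is recovered from the terminal afterwards)
    ii <- c(ii, merged); jj <- c(jj, merged)
    tri_r[[length(tri_r) + 1]] <- rep(1, length(merged))
    tri_m[[length(tri_m) + 1]] <- numeric(length(merged))
  }
  Kr <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(tri_r), dims = c(N, N))
  Ki <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(tri_m), dims = c(N, N))

  structure(list(Kr = Kr, Ki = Ki, n_nodes = nn, ids = ids,
                 mesh = mesh, materials = materials, interfaces = interfaces,
                 f = f, op = op, ys = ys, ideal = ideal, merged = merged,
                 insulate = insulate),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("FEM system at %g Hz: %d nodes + %d terminals (%s electrodes)\n",
              x$f, x$n_nodes, length(x$ids),
              if (x$ideal) "ideal" else "film-coupled"))
  invisible(x)
}

# complex BiCGStab with SPD Cholesky preconditioner M = (Kr + Ki)
solve_complex <- function(Kr, Ki, b, rtol = 1e-10, maxit = 400) {
  P <- Matrix::Cholesky(Matrix::forceSymmetric(Kr + Ki), LDL = FALSE,
                        super = TRUE)
  matv <- function(x) {
    xr <- Re(x); xi <- Im(x)
    complex(real = as.numeric(Kr %*% xr - Ki %*% xi),
            imaginary = as.numeric(Kr %*% xi + Ki %*% xr))
  }
  prec <- function(x)
    complex(real = as.numeric(Matrix::solve(P, Re(x), system = "A")),
            imaginary = as.numeric(Matrix::solve(P, Im(x), system = "A")))
  n <- length(b)
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(list(x = complex(real = numeric(n)),
                           iters = 0L, relres = 0))
  x <- best_x <- complex(real = numeric(n))
  best_res <- 1
  r <- b; r0 <- r
  rho <- alpha <- omg <- 1 + 0i
  v <- p <- x
  it <- 0L; fresh <- TRUE
  restart <- function() {
    r <<- b - matv(x); r0 <<- r
    rho <<- alpha <<- omg <<- 1 + 0i
    v <<- p <<- complex(real = numeric(n)); fresh <<- TRUE
  }
  while (it < maxit) {
    it <- it + 1L
    rho1 <- sum(Conj(r0) * r)
    rnorm2 <- sum(Mod(r)^2)
    if (!is.finite(rnorm2)) { x <- best_x; restart(); next }
    if (sqrt(rnorm2) / nb < rtol) break
    if (Mod(rho1) < 1e-12 * rnorm2 && !fresh) { restart(); next }
    fresh <- FALSE
    beta <- (rho1 / rho) * (alpha / omg); rho <- rho1
    p <- r + beta * (p - omg * v)
    ph <- prec(p); v <- matv(ph)
    den_a <- sum(Conj(r0) * v)
    if (!is.finite(Mod(den_a)) || Mod(den_a) == 0) { restart(); next }
    alpha <- rho / den_a
    s <- r - alpha * v
    sh <- prec(s); tt <- matv(sh)
    den_o <- sum(Conj(tt) * tt)
    if (!is.finite(Mod(den_o)) || Mod(den_o) == 0) { restart(); next }
    omg <- sum(Conj(tt) * s) / den_o
    x <- x + alpha * ph + omg * sh
    r <- s - omg * tt
    rn <- sqrt(sum(Mod(r)^2)) / nb
    if (is.finite(rn) && rn < best_res) { best_res <- rn; best_x <- x }
    if (is.finite(rn) && rn < rtol) break
  }
  if (!all(is.finite(Re(x)) & is.finite(Im(x)))) x <- best_x
  res <- sqrt(sum(Mod(matv(x) - b)^2)) / nb
  if (!is.finite(res) || res > rtol * 100) {
    bx <- best_x
    bres <- sqrt(sum(Mod(matv(bx) - b)^2)) / nb
    if (is.finite(bres) && bres < res) { x <- bx; res <- bres }
  }
  list(x = x, iters = it, relres = res)
}

# direct solve of the complex system via its real 2n x 2n block form;
# slow but unconditional -- the fallback when the iteration stagnates
solve_complex_direct <- function(Kr, Ki, b) {
  A <- rbind(cbind(Kr, -Ki), cbind(Ki, Kr))
  xy <- Matrix::solve(A, c(Re(b), Im(b)))
  n <- length(b)
  x <- complex(real = xy[seq_len(n)], imaginary = xy[n + seq_len(n)])
  nb <- sqrt(sum(Mod(b)^2))
  r <- complex(real = as.numeric(Kr %*% Re(x) - Ki %*% Im(x)),
               imaginary = as.numeric(Kr %*% Im(x) + Ki %*% Re(x))) - b
  list(x = x, iters = NA_integer_, relres = sqrt(sum(Mod(r)^2)) / nb)
}

#' Terminal drive specification
#'
#' @param source electrode id fed with `+I_T`.
#' @param sink electrode id grounded (current return).
#' @param I_T terminal current, A (default 1: unit-current lead-field drive).
#' @return A `drive_spec` object.
#' @export
drive_spec <- function(source, sink, I_T = 1) {
  if (identical(source, sink)) stop("source and sink must differ")
  if (I_T == 0) stop("I_T must be nonzero")
  structure(list(source = source, sink = sink, I_T = I_T),
            class = "drive_spec")
}

#' Solve one terminal drive
#'
#' Feeds `I_T` into the source terminal with the sink terminal grounded and
#' solves the complex system to a relative residual of 1e-10 (default).
#' Returns the complex nodal potential, element current densities evaluated
#' at element centroids, and every terminal voltage (floating recording
#' electrodes carry zero net current by construction).
#'
#' @param system an [assemble_system()] result.
#' @param drive a [drive_spec()] whose source/sink are electrode ids of the
#'   system.
#' @param rtol solver relative residual tolerance.
#' @return An object of class `field_solution` with entries `f`, `phi`
#'   (complex, per node), `J` (complex m x 3 matrix, A/m^2, per element),
#'   `terminals` (complex named vector, V), `drive`, `solver`.
#' @export
solve_drive <- function(system, drive, rtol = 1e-10) {
  stopifnot(inherits(system, "fem_system"), inherits(drive, "drive_spec"))
  for (id in c(drive$source, drive$sink)) {
    if (!id %in% system$ids) stop("unknown electrode id: ", id)
    if (id %in% system$insulate)
      stop("electrode ", id, " is insulated in this system and cannot be driven")
  }
  nn <- system$n_nodes
  N <- nrow(system$Kr)
  b <- complex(real = numeric(N))
  b[nn + match(drive$source, system$ids)] <- drive$I_T

  # ground the sink terminal
  drop <- nn + match(drive$sink, system$ids)
  keep <- setdiff(seq_len(N), drop)
  sol <- solve_complex(system$Kr[keep, keep], system$Ki[keep, keep],
                       b[keep], rtol)
  if (sol$relres > rtol * 100)   # stagnation: fall back to the direct solve
    sol <- solve_complex_direct(system$Kr[keep, keep], system$Ki[keep, keep],
                                b[keep])
  if (sol$relres > 1e-6)
    stop(sprintf("solver did not converge: relative residual %.2e after %d iterations",
                 sol$relres, sol$iters))
  x <- complex(real = numeric(N)); x[keep] <- sol$x

  phi <- x[seq_len(nn)]
  terminals <- setNames(x[nn + seq_along(system$ids)], system$ids)
  if (system$ideal)   # merged face nodes carry their terminal's potential
    for (l in seq_along(system$ids)) {
      if (system$ids[l] %in% system$insulate) next
      phi[system$op$elec[[l]]$face_nodes] <- terminals[[l]]
    }
  # insulated faces: amplifier reading = area-averaged surface potential
  for (id in system$insulate) {
    e <- system$op$elec[[id]]
    terminals[[id]] <- sum(e$b * phi) / e$area_m2
  }
  J <- element_current_density(system, phi)

  structure(list(f = system$f, phi = phi, J = J, terminals = terminals,
                 drive = drive, mesh = system$mesh,
                 solver = list(iters = sol$iters, relres = sol$relres)),
            class = "field_solution")
}

# J = -(sigma + j w eps) grad(phi) at element centroids, A/m^2
element_current_density <- function(system, phi) {
  op <- system$op
  m <- nrow(system$mesh$tets)
  J <- matrix(0 + 0i, m, 3)
  sel_list <- list(medium = system$mesh$region == "medium",
                   cytoplasm = system$mesh$region == "cytoplasm")
  for (rg in names(op$grads)) {
    gd <- op$grads[[rg]]
    kk <- complex_conductivity(system$materials, rg, system$f)
    tt <- gd$tt
    for (d in 1:3) {
      gphi <- gd$grads[, 1, d] * phi[tt[, 1]] + gd$grads[, 2, d] * phi[tt[, 2]] +
              gd$grads[, 3, d] * phi[tt[, 3]] + gd$grads[, 4, d] * phi[tt[, 4]]
      J[sel_list[[rg]], d] <- -kk * gphi
    }
  }
  J
}

#' Terminal currents of a field solution
#'
#' Recovers the net current through each electrode film,
#' `I_l = y_l (A_l U_l - integral of phi over the face)`.  Source and sink
#' currents reproduce `+I_T` / `-I_T` (discrete current conservation);
#' floating electrodes carry zero net current.  Only available for
#' film-coupled (non-ideal) electrodes.
#'
#' @param solution a [solve_drive()] result.
#' @param system the [assemble_system()] used to produce it.
#' @return complex named vector, A.
#' @export
terminal_currents <- function(solution, system) {
  if (system$ideal)
    stop("terminal currents via the film are undefined for ideal electrodes")
  out <- setNames(rep(0 + 0i, length(system$ids)), system$ids)
  for (id in system$ids) {
    e <- system$op$elec[[id]]
    y <- system$ys[[id]]
    U <- solution$terminals[[id]]
    out[id] <- y * (e$area_m2 * U - sum(e$b * solution$phi))
  }
  out
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Field solution at %g Hz (drive %s -> %s, I_T = %g A)\n",
              x$f, x$drive$source, x$drive$sink, x$drive$I_T))
  cat("  terminal voltages (V):\n")
  for (id in names(x$terminals))
    cat(sprintf("    %s: %.6g %+.6gi\n", id, Re(x$terminals[[id]]),
                Im(x$terminals[[id]])))
  cat(sprintf("  solver: %d iterations, relative residual %.2e\n",
              x$solver$iters, x$solver$relres))
  invisible(x)
}
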