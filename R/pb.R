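#' Construct a uniform finite-difference grid
#'
#' Rectangular node lattice centred on \code{center} with spacing \code{h};
#' requested side lengths are rounded to an integer number of cells.
#'
#' @param L side lengths (3-vector or scalar), Angstrom.
#' @param h node spacing, Angstrom.
#' @param center grid centre coordinates (default the origin, which is the
#'   midpoint between the two nanoparticles).
#' @return an object of class \code{pb_grid} with origin, spacing, dims.
#' @export
pb_grid <- function(L, h, center = c(0, 0, 0)) {
  if (length(L) == 1) L <- rep(L, 3)
  dims <- as.integer(round(L / h)) + 1L
  if (any(dims < 2)) stop("grid needs at least 2 nodes per dimension")
  L <- (dims - 1L) * h
  structure(list(origin = center - L / 2, h = h, dims = dims, L = L,
                 center = center),
            class = "pb_grid")
}

#' @export
print.pb_grid <- function(x, ...) {
  cat(sprintf("pb_grid: %d x %d x %d nodes, h = %g A, box %.1f x %.1f x %.1f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$L[1], x$L[2], x$L[3]))
  invisible(x)
}

grid_nnodes <- function(grid) prod(grid$dims)

grid_axes <- function(grid) {
  list(x = grid$origin[1] + grid$h * (seq_len(grid$dims[1]) - 1),
       y = grid$origin[2] + grid$h * (seq_len(grid$dims[2]) - 1),
       z = grid$origin[3] + grid$h * (seq_len(grid$dims[3]) - 1))
}

# squared node distances to a point, as a flat vector in node order
# (x fastest, then y, then z)
grid_dist2 <- function(grid, center) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  as.vector(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

# flat vector of one coordinate of every node
grid_coord <- function(grid, axis = 1) {
  ax <- grid_axes(grid)[[axis]]
  d <- grid$dims
  switch(axis,
         rep(ax, times = d[2] * d[3]),
         rep(rep(ax, each = d[1]), times = d[3]),
         rep(ax, each = d[1] * d[2]))
}

# trapezoidal quadrature weights (fractions of h^3): face nodes carry 1/2
# per face dimension, so volume integrals are second-order accurate up to
# the domain boundary
grid_quad_weights <- function(grid) {
  d <- grid$dims
  wx <- rep(1, d[1]); wx[c(1, d[1])] <- 0.5
  wy <- rep(1, d[2]); wy[c(1, d[2])] <- 0.5
  wz <- rep(1, d[3]); wz[c(1, d[3])] <- 0.5
  as.vector(outer(outer(wx, wy), wz))
}

# logical mask of face (Dirichlet) nodes
grid_face_mask <- function(grid) {
  d <- grid$dims
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  ix == 1L | ix == d[1] | iy == 1L | iy == d[2] | iz == 1L | iz == d[3]
}

# node coordinates of the face nodes only
grid_face_points <- function(grid, mask = grid_face_mask(grid)) {
  cbind(grid_coord(grid, 1)[mask], grid_coord(grid, 2)[mask],
        grid_coord(grid, 3)[mask])
}

#' Distribute fixed point charges onto the grid
#'
#' Each nanoparticle is modelled as a central point charge partitioned
#' trilinearly onto its eight surrounding nodes, so the mapped charge sums
#' exactly to the source charge.
#'
#' @param centers n x 3 matrix of charge positions, Angstrom.
#' @param charges charge of each source, e.
#' @param grid a \code{\link{pb_grid}}.
#' @return fixed-charge density rho_f at every node, e/Angstrom^3 (flat
#'   vector in node order).
#' @export
map_fixed_charges <- function(centers, charges, grid) {
  centers <- matrix(centers, ncol = 3)
  d <- grid$dims
  rho <- numeric(grid_nnodes(grid))
  for (s in seq_len(nrow(centers))) {
    u <- (centers[s, ] - grid$origin) / grid$h
    if (any(u < -1e-9) || any(u > d - 1 + 1e-9))
      stop("fixed charge lies outside the grid")
    i0 <- pmin(pmax(floor(u + 1e-12), 0), d - 2)
    f <- u - i0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- (if (cx) f[1] else 1 - f[1]) *
           (if (cy) f[2] else 1 - f[2]) *
           (if (cz) f[3] else 1 - f[3])
      idx <- (i0[1] + cx) + d[1] * ((i0[2] + cy) + d[2] * (i0[3] + cz)) + 1
      rho[idx] <- rho[idx] + charges[s] * w / grid$h^3
    }
  }
  rho
}

#' Mark ion-accessible grid nodes
#'
#' A thin layer of one ion radius is added to the nanoparticle surface:
#' nodes closer than \code{r_excl} = nanoparticle radius + ion radius to
#' either centre are excluded from the mobile-ion term.
#'
#' @param centers n x 3 matrix of nanoparticle centres.
#' @param grid a \code{\link{pb_grid}}.
#' @param r_excl exclusion radius, Angstrom (default 10 + 2 = 12).
#' @return logical vector, TRUE where ions may reside.
#' @export
build_accessibility <- function(centers, grid, r_excl = 12) {
  centers <- matrix(centers, ncol = 3)
  acc <- rep(TRUE, grid_nnodes(grid))
  for (s in seq_len(nrow(centers)))
    acc <- acc & (grid_dist2(grid, centers[s, ]) >= r_excl^2)
  acc
}

#' Debye-Hueckel potential of screened spheres
#'
#' Linearized single-sphere solution, superposed over sources:
#' phi(r) = sum_p q_p lB exp(-kappa (d_p - R)) / ((1 + kappa R) d_p),
#' with R the distance of closest ion approach (nanoparticle radius + ion
#' radius).  Used as the analytic outer boundary condition and as the
#' weak-coupling oracle.
#'
#' @param pts m x 3 matrix of evaluation points.
#' @param centers n x 3 matrix of source centres.
#' @param charges source charges, e.
#' @param kappa inverse Debye length, 1/Angstrom.
#' @param lB Bjerrum length, Angstrom.
#' @param R ion-exclusion radius, Angstrom.
#' @param dmin floor on the source distance (used when evaluating on nodes
#'   that coincide with a source, e.g. for initial guesses; a grid cannot
#'   resolve the potential below its spacing).
#' @return potential in kBT/e at each point.
#' @export
dh_potential <- function(pts, centers, charges, kappa, lB, R = 12,
                         dmin = 1e-6) {
  pts <- matrix(pts, ncol = 3)
  centers <- matrix(centers, ncol = 3)
  out <- numeric(nrow(pts))
  for (s in seq_len(nrow(centers))) {
    d <- sqrt((pts[, 1] - centers[s, 1])^2 + (pts[, 2] - centers[s, 2])^2 +
              (pts[, 3] - centers[s, 3])^2)
    d <- pmax(d, dmin)
    out <- out + charges[s] * lB * exp(-kappa * (d - R)) / ((1 + kappa * R) * d)
  }
  out
}

# bare Coulomb superposition (no-salt reference field boundary)
coulomb_potential <- function(pts, centers, charges, lB, dmin = 1e-6) {
  dh_potential(pts, centers, charges, kappa = 0, lB = lB, R = 0, dmin = dmin)
}

#' Solve the nonlinear Poisson-Boltzmann equation on one grid
#'
#' 7-point finite-difference discretization in a uniform dielectric with the
#' mobile-ion term of a symmetric z:z salt evaluated on accessible nodes
#' only.  Face nodes are Dirichlet values taken from \code{psi0}; interior
#' nodes are relaxed by Gauss-Seidel-Newton sweeps with over-relaxation
#' until the largest per-sweep change falls below \code{tol} (kBT/e).  On
#' divergence the sweep is restarted with a smaller relaxation factor, and
#' an error carrying the change history is raised if no factor converges.
#'
#' @param grid a \code{\link{pb_grid}}.
#' @param rho fixed-charge density from \code{\link{map_fixed_charges}}.
#' @param acc accessibility mask from \code{\link{build_accessibility}}.
#' @param z salt valence.
#' @param c0 bulk concentration, mol/L (0 gives the no-salt field).
#' @param lB Bjerrum length, Angstrom.
#' @param psi0 initial potential (face values double as the boundary
#'   condition), kBT/e.
#' @param tol convergence tolerance on the max node change, kBT/e.
#' @param omega over-relaxation factor.
#' @param maxiter iteration cap.
#' @return list with \code{psi}, \code{iterations}, \code{final_change},
#'   \code{history}, \code{converged}.
#' @export
solve_pb_grid <- function(grid, rho, acc, z, c0, lB, psi0,
                          tol = 1e-4, omega = NULL, maxiter = 30000) {
  A <- grid$h^2 * 4 * pi * lB * 2 * z * number_density(c0)
  rhs <- grid$h^2 * 4 * pi * lB * rho
  if (is.null(omega)) omega <- 1.2
  for (om in unique(c(omega, 1.2, 1.0, 0.7))) {
    psi <- psi0 + 0  # force a copy; the kernel relaxes in place
    res <- pb_relax_cpp(psi, grid$dims, rhs, acc, A, z, om, tol, maxiter,
                        dclamp = 5)
    if (res$converged)
      return(list(psi = psi, iterations = res$iterations,
                  final_change = res$final_change, history = res$history,
                  converged = TRUE, omega = om))
    if (!res$diverged) {
      # ran out of iterations without diverging: report rather than retry
      stop(sprintf(
        "PB relaxation did not reach tol %.1e in %d iterations (last change %.2e)",
        tol, res$iterations, res$final_change))
    }
  }
  stop("PB relaxation diverged for every relaxation factor tried")
}

#' Grid-focusing schedule
#'
#' Ordered list of (box, resolution) levels, strictly shrinking and
#' refining.  The default reproduces the three-step focusing procedure: a
#' concentration-adapted coarse level whose faces sit at least six Debye
#' lengths from the nanoparticle surfaces, a (160, 120, 120) A level at
#' 1.0 A per grid, and a (100, 60, 60) A final level whose resolution is
#' set by \code{final_h}.  The level-1 box is sized for \code{x_ref} and
#' reused for every separation so that all grids stay geometrically
#' identical and grid self-energies cancel in PMF differences.
#'
#' @param spec a \code{\link{system_spec}}.
#' @param final_h resolution of the final level, Angstrom.
#' @param tol solver convergence tolerance, kBT/e.
#' @param levels optional explicit list of \code{list(L =, h =)} levels
#'   overriding the default (used for reduced test schedules).
#' @return an object of class \code{focusing_schedule}.
#' @export
focusing_schedule <- function(spec, final_h = 0.5, tol = 1e-4,
                              levels = NULL) {
  if (is.null(levels)) {
    l3 <- list(L = c(100, 60, 60), h = final_h)
    l2 <- list(L = c(160, 120, 120), h = 1.0)
    s1 <- max(spec$x_ref + 2 * spec$np_radius + 12 * spec$debye,
              max(l2$L) + 20)
    h1 <- max(l2$h, s1 / 96)
    l1 <- list(L = rep(s1, 3), h = h1)
    levels <- list(l1, l2, l3)
  }
  # drop outer levels that are not coarser than their child
  keep <- vapply(seq_along(levels), function(i) {
    i == length(levels) || levels[[i]]$h > levels[[i + 1]]$h
  }, TRUE)
  levels <- levels[keep]
  for (i in seq_along(levels)) {
    if (i > 1 && any(levels[[i]]$L >= levels[[i - 1]]$L))
      stop("focusing boxes must shrink strictly")
  }
  fin <- levels[[length(levels)]]
  if (fin$L[1] < spec$x_ref + 2 * (spec$np_radius + spec$ion_radius) ||
      min(fin$L[2:3]) < 2 * (spec$np_radius + spec$ion_radius))
    stop("final level must enclose both nanoparticles plus exclusion layers")
  structure(list(levels = levels, tol = tol), class = "focusing_schedule")
}

#' @export
print.focusing_schedule <- function(x, ...) {
  cat("focusing_schedule:\n")
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: box %.0f x %.0f x %.0f A at h = %.3g A\n",
                i, l$L[1], l$L[2], l$L[3], l$h))
  }
  cat(sprintf("  convergence tolerance %g kBT/e\n", x$tol))
  invisible(x)
}

#' Reduced focusing schedule
#'
#' A cheaper schedule for exploratory work and fast test runs: a coarse
#' concentration-adapted outer level, a mid level at 2 A, and the standard
#' (100, 60, 60) A final box at \code{final_h} (default 1 A).  Same
#' structure as the production schedule, lower resolution throughout.
#'
#' @inheritParams focusing_schedule
#' @param final_h final-level resolution, Angstrom.
#' @return a \code{\link{focusing_schedule}}.
#' @export
reduced_schedule <- function(spec, final_h = 1.0, tol = 1e-4) {
  s1 <- max(spec$x_ref + 2 * spec$np_radius + 12 * spec$debye, 230)
  h1 <- max(2.5, s1 / 96)
  focusing_schedule(spec, tol = tol, levels = list(
    list(L = rep(s1, 3), h = h1),
    list(L = c(200, 140, 140), h = 2.0),
    list(L = c(100, 60, 60), h = final_h)))
}

#' Focused solve of the nonlinear PB equation for one state point
#'
#' Level 1 is solved with the analytic Debye-Hueckel superposition as both
#' boundary condition and initial guess; each finer level takes its face
#' values and initial interior guess by trilinear interpolation from its
#' parent.  Alongside the full nonlinear potential psi, the no-salt
#' reference field psi_f (same discrete operator, ion term zeroed, analytic
#' Coulomb boundary) is solved on the final level, as required by the
#' free-energy functional; on the coarser levels, whose free-energy role is
#' limited to far-field complement integrals, psi_f is the analytic Coulomb
#' superposition.
#'
#' @param spec a \code{\link{system_spec}} (its \code{x} sets the
#'   nanoparticle positions -x/2 and +x/2 on the grid axis).
#' @param schedule a \code{\link{focusing_schedule}}.
#' @param verbose print per-level iteration counts.
#' @param flip_charges put -Z on the low-x particle instead of +Z (global
#'   charge conjugation; in a symmetric salt the free energy is invariant).
#' @return an object of class \code{pb_solution}: per-level grids, psi,
#'   psi_f, rho_f, accessibility and solver diagnostics.
#' @export
focusing_solve <- function(spec, schedule = focusing_schedule(spec),
                           verbose = FALSE, flip_charges = FALSE) {
  stopifnot(inherits(spec, "system_spec"),
            inherits(schedule, "focusing_schedule"))
  centers <- rbind(c(-spec$x / 2, 0, 0), c(spec$x / 2, 0, 0))
  charges <- if (flip_charges) c(-spec$Z, spec$Z) else c(spec$Z, -spec$Z)
  kappa <- 1 / spec$debye
  r_excl <- spec$np_radius + spec$ion_radius
  levels <- list()
  for (i in seq_along(schedule$levels)) {
    lv <- schedule$levels[[i]]
    grid <- pb_grid(lv$L, lv$h)
    if (i > 1) {
      pg <- levels[[i - 1]]$grid
      lo <- grid$origin; hi <- grid$origin + grid$L
      plo <- pg$origin; phi <- pg$origin + pg$L
      if (any(lo < plo - 1e-9) || any(hi > phi + 1e-9))
        stop("focusing level extends beyond its parent box")
    }
    rho <- map_fixed_charges(centers, charges, grid)
    acc <- build_accessibility(centers, grid, r_excl)
    pts <- cbind(grid_coord(grid, 1), grid_coord(grid, 2),
                 grid_coord(grid, 3))
    if (i == 1) {
      psi0 <- dh_potential(pts, centers, charges, kappa, spec$lB, r_excl,
                           dmin = grid$h)
    } else {
      pg <- levels[[i - 1]]$grid
      psi0 <- trilinear_cpp(levels[[i - 1]]$psi, pg$dims, pg$origin, pg$h, pts)
    }
    # near-optimal SOR factor for the Poisson part of the operator; the
    # screened/nonlinear terms only add diagonal dominance
    om <- min(1.9, 2 / (1 + sin(pi / max(grid$dims))))
    sol <- solve_pb_grid(grid, rho, acc, spec$z, spec$c0, spec$lB, psi0,
                         tol = schedule$tol, omega = om)
    # no-salt reference field psi_f: solved on the discrete operator at the
    # final level, where it enters the self-consistent ion-field term; the
    # coarser levels only contribute far-field complement integrals, where
    # the analytic Coulomb superposition equals the discrete field to O(h^2)
    psif0 <- coulomb_potential(pts, centers, charges, spec$lB, dmin = grid$h)
    if (i == length(schedule$levels)) {
      solf <- solve_pb_grid(grid, rho, acc, spec$z, 0, spec$lB, psif0,
                            tol = schedule$tol, omega = om)
      psi_f <- solf$psi
      itf <- solf$iterations; chf <- solf$final_change
    } else {
      psi_f <- psif0
      itf <- 0L; chf <- NA_real_
    }
    if (verbose)
      message(sprintf("  level %d (%s): psi %d iters, psi_f %d iters",
                      i, paste(grid$dims, collapse = "x"),
                      sol$iterations, itf))
    levels[[i]] <- list(grid = grid, psi = sol$psi, psi_f = psi_f,
                        rho = rho, acc = acc,
                        iterations = c(psi = sol$iterations, psi_f = itf),
                        final_change = c(psi = sol$final_change,
                                         psi_f = chf))
  }
  structure(list(levels = levels, spec = spec, schedule = schedule,
                 centers = centers, charges = charges),
            class = "pb_solution")
}

#' @export
print.pb_solution <- function(x, ...) {
  cat(sprintf("pb_solution: |Z| = %ge, %g:%g salt at %g M, x = %g A\n",
              x$spec$Z, x$spec$z, x$spec$z, x$spec$c0, x$spec$x))
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: %s nodes, psi converged in %d iterations\n",
                i, paste(l$grid$dims, collapse = "x"), l$iterations["psi"]))
  }
  invisible(x)
}

# free-energy integrands of a symmetric z:z salt at reduced potential phi
# (vectors); returns list(charge = sum_i z_i c_i, entropy = sum_i
# [c ln(c/c0) - c + c0]) in e/A^3 and 1/A^3
pb_integrands <- function(phi, z, c0n) {
  a <- pmin(pmax(z * phi, -300), 300)
  em <- exp(-a)  # cation factor
  ep <- exp(a)   # anion factor
  cplus <- c0n * em
  cminus <- c0n * ep
  list(charge = z * (cplus - cminus),
       entropy = (cplus * (-a) - cplus + c0n) + (cminus * a - cminus + c0n))
}

#' Electrostatic free energy of a focused PB solution
#'
#' Evaluates the mean-field charging free energy
#' G = 1/2 int sum_i c_i z_i e (psi + psi_f) d3r
#'   + kBT int sum_i [c_i ln(c_i/c_i0) - c_i + c_i0] d3r + U_NN,
#' with c_i = c_i0 exp(-z_i psi) on ion-accessible nodes and zero on
#' excluded nodes, by trapezoidal node quadrature on the final focusing
#' level; each coarser level adds the contribution of its region outside
#' its child box.  The bare nanoparticle-nanoparticle
#' Coulomb term U_NN = -Z^2 lB / x is analytic.
#'
#' @param sol a \code{\link{pb_solution}}.
#' @return object of class \code{pb_free_energy}: the ion-field term, the
#'   ion-entropy term, U_NN, and their sum, all in kBT.
#' @export
pb_free_energy <- function(sol) {
  stopifnot(inherits(sol, "pb_solution"))
  spec <- sol$spec
  c0n <- number_density(spec$c0)
  nlev <- length(sol$levels)
  t_field <- t_entropy <- 0
  by_level <- data.frame(level = integer(), field = numeric(),
                         entropy = numeric())
  for (i in rev(seq_len(nlev))) {
    l <- sol$levels[[i]]
    g <- l$grid
    sel <- l$acc
    if (i < nlev) {
      cg <- sol$levels[[i + 1]]$grid
      lo <- cg$origin; hi <- cg$origin + cg$L
      outside <- grid_coord(g, 1) < lo[1] - 1e-9 |
                 grid_coord(g, 1) > hi[1] + 1e-9 |
                 grid_coord(g, 2) < lo[2] - 1e-9 |
                 grid_coord(g, 2) > hi[2] + 1e-9 |
                 grid_coord(g, 3) < lo[3] - 1e-9 |
                 grid_coord(g, 3) > hi[3] + 1e-9
      sel <- sel & outside
    }
    ig <- pb_integrands(l$psi[sel], spec$z, c0n)
    w <- grid_quad_weights(g)[sel] * g$h^3
    f_i <- 0.5 * sum(w * ig$charge * (l$psi[sel] + l$psi_f[sel]))
    s_i <- sum(w * ig$entropy)
    t_field <- t_field + f_i
    t_entropy <- t_entropy + s_i
    by_level <- rbind(by_level,
                      data.frame(level = i, field = f_i, entropy = s_i))
  }
  u_nn <- -spec$Z^2 * spec$lB / spec$x
  structure(list(ion_field = t_field, ion_entropy = t_entropy, u_nn = u_nn,
                 total = t_field + t_entropy + u_nn, by_level = by_level),
            class = "pb_free_energy")
}

#' @export
print.pb_free_energy <- function(x, ...) {
  cat(sprintf(
    "pb_free_energy: field %.4f + entropy %.4f + U_NN %.4f = %.4f kBT\n",
    x$ion_field, x$ion_entropy, x$u_nn, x$total))
  invisible(x)
}

#' Poisson-Boltzmann potential of mean force
#'
#' One focused solve per separation on geometrically identical grids (same
#' dims and spacing at every level, nanoparticles repositioned), so grid
#' self-energies cancel in the free-energy differences;
#' dG(x) = G(x) - G(x_ref) with dG(x_ref) exactly zero.
#'
#' @inheritParams mc_pmf
#' @param schedule optional \code{\link{focusing_schedule}}, or a function
#'   of the reference \code{system_spec} returning one (e.g.
#'   \code{reduced_schedule}); defaults to the three-level schedule with
#'   \code{final_h}.
#' @param final_h resolution of the final level, Angstrom.
#' @param keep_solutions separations whose full solutions are retained (for
#'   ion-profile observables).
#' @return an object of class \code{pb_pmf} containing the \code{pmf_curve}
#'   and any retained \code{pb_solution}s.
#' @export
pb_pmf <- function(Z, z, c0, x_values = c(22, 40), schedule = NULL,
                   final_h = 0.5, keep_solutions = 22, eps = 78,
                   temperature = 298.15, x_ref = 40, verbose = FALSE) {
  x_values <- sort(unique(c(x_values, x_ref)))
  spec_ref <- system_spec(Z, z, c0, x = x_ref, eps = eps,
                          temperature = temperature, x_ref = x_ref)
  if (is.null(schedule)) schedule <- focusing_schedule(spec_ref, final_h)
  else if (is.function(schedule)) schedule <- schedule(spec_ref)
  g_tot <- numeric(length(x_values))
  sols <- list()
  for (i in seq_along(x_values)) {
    spec_i <- system_spec(Z, z, c0, x = x_values[i], eps = eps,
                          temperature = temperature, x_ref = x_ref,
                          box = spec_ref$box)
    sol <- focusing_solve(spec_i, schedule, verbose = verbose)
    fe <- pb_free_energy(sol)
    g_tot[i] <- fe$total
    if (verbose)
      message(sprintf("  x = %4.1f A: G_PB = %.4f kBT", x_values[i], fe$total))
    if (any(abs(keep_solutions - x_values[i]) < 1e-9))
      sols[[as.character(x_values[i])]] <- sol
  }
  g_ref <- g_tot[which(abs(x_values - x_ref) < 1e-9)]
  curve <- structure(data.frame(x = x_values, dG = g_tot - g_ref,
                                dG_err = 0),
                     class = c("pmf_curve", "data.frame"),
                     method = "PB", x_ref = x_ref, temperature = temperature,
                     Z = Z, z = z, c0 = c0)
  structure(list(curve = curve, G = g_tot, solutions = sols,
                 schedule = schedule, Z = Z, z = z, c0 = c0),
            class = "pb_pmf")
}

#' @export
print.pb_pmf <- function(x, ...) {
  cat(sprintf("pb_pmf: |Z| = %ge, %g:%g salt at %g M\n", x$Z, x$z, x$z, x$c0))
  print(x$curve)
  invisible(x)
}

#' Export a grid scalar field in OpenDX format
#'
#' Writes the standard OpenDX regular-grid scalar file understood by
#' molecular-visualization tools.
#'
#' @param grid a \code{\link{pb_grid}}.
#' @param field node values (flat vector in node order).
#' @param path output file.
#' @param name data label.
#' @export
write_opendx <- function(grid, field, path, name = "potential") {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s (kBT/e) exported by ionpmf", name),
    sprintf("object 1 class gridpositions counts %d %d %d", d[3], d[2], d[1]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6e 0.0 0.0", grid$h),
    sprintf("delta 0.0 %.6e 0.0", grid$h),
    sprintf("delta 0.0 0.0 %.6e", grid$h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[3], d[2], d[1]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(field))), con)
  # OpenDX expects the last index fastest; our storage has x fastest
  arr <- array(field, dim = d)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  n3 <- length(vals) %/% 3 * 3
  if (n3 > 0)
    writeLines(sprintf("%.6e %.6e %.6e", vals[seq(1, n3, 3)],
                       vals[seq(2, n3, 3)], vals[seq(3, n3, 3)]), con)
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.6e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}
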