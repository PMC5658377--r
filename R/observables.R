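# Bound-ion observables computed identically from MC samples and PB fields:
# the net ion charge fraction Q(r), the relative PMF deviation, the apparent
# coupling parameter |Z| dQ*, equivalent-salt mapping and 2D charge-density
# landscapes.

default_r_bins <- function() seq(0, 24, by = 0.5)

#' Net ion charge fraction from Monte Carlo samples
#'
#' Q(r) = -(1/Z) <sum of ion charges within distance r of a nanoparticle
#' centre and on its side of the bisector plane>.  The plane midway between
#' the two centres splits the cell into the half-spaces dominated by each
#' particle; the profile is computed around both nanoparticles (they are
#' charge conjugates) and their average is returned, with block-averaged
#' errors over frames.
#'
#' @param chain an \code{mc_chain} with stored frames, sampled at the
#'   separation of interest.
#' @param r_bins radial bin edges, Angstrom (must include 14 for the
#'   apparent parameter).
#' @param block_count blocks for the error estimate.
#' @return data frame of class \code{ion_charge_profile} with columns
#'   \code{r}, \code{Q}, \code{Q_err}; per-side profiles are attached as
#'   attributes for symmetry checks.
#' @export
net_charge_fraction_mc <- function(chain, r_bins = default_r_bins(),
                                   block_count = 20) {
  stopifnot(inherits(chain, "mc_chain"))
  fr <- chain$frames
  if (nrow(fr) == 0) stop("chain has no stored frames")
  Z <- abs(chain$charge[1])
  ni <- chain$n_ion
  nf <- nrow(fr)
  np1 <- fr[, 1:3, drop = FALSE]
  np2 <- fr[, 4:6, drop = FALSE]
  if (ni == 0) {
    out <- data.frame(r = r_bins, Q = 0, Q_err = 0)
    return(structure(out, class = c("ion_charge_profile", "data.frame"),
                     method = "MC", Z = Z, x = chain$spec$x))
  }
  ic <- 2 + seq_len(ni)
  xs <- fr[, 3 * (ic - 1) + 1, drop = FALSE]
  ys <- fr[, 3 * (ic - 1) + 2, drop = FALSE]
  zs <- fr[, 3 * (ic - 1) + 3, drop = FALSE]
  qi <- matrix(chain$charge[ic], nf, ni, byrow = TRUE)
  mid <- (np1[, 1] + np2[, 1]) / 2
  d1 <- (xs - np1[, 1])^2 + (ys - np1[, 2])^2 + (zs - np1[, 3])^2
  d2 <- (xs - np2[, 1])^2 + (ys - np2[, 2])^2 + (zs - np2[, 3])^2
  side1 <- xs < mid
  s_pos <- abs(chain$charge[1]) == chain$charge[1]  # particle 1 carries +Z
  qpos <- qneg <- matrix(0, nf, length(r_bins))
  for (b in seq_along(r_bins)) {
    r2 <- r_bins[b]^2
    qpos[, b] <- rowSums(qi * (side1 & d1 < r2))
    qneg[, b] <- rowSums(qi * (!side1 & d2 < r2))
  }
  if (!s_pos) { tmp <- qpos; qpos <- qneg; qneg <- tmp }
  q_pos <- -colMeans(qpos) / Z   # around the +Z particle
  q_neg <- colMeans(qneg) / Z    # around the -Z particle (conjugate)
  qavg_frames <- (-qpos / Z + qneg / Z) / 2
  Q <- colMeans(qavg_frames)
  Q_err <- apply(qavg_frames, 2, function(v)
    if (nf >= block_count) block_stderr(v, block_count)
    else stats::sd(v) / sqrt(nf))
  out <- data.frame(r = r_bins, Q = Q, Q_err = Q_err)
  structure(out, class = c("ion_charge_profile", "data.frame"),
            method = "MC", Z = Z, x = chain$spec$x,
            Q_pos = q_pos, Q_neg = q_neg)
}

#' Net ion charge fraction from a PB solution
#'
#' Half-space integral of the Boltzmann ion charge density
#' -(1/Z) int_{<r} sum_i z_i c_i(r) d3r on the final focusing level, with
#' c_i = c_i0 exp(-z_i psi) on accessible nodes.  Nodes exactly on the
#' bisector plane contribute half to each side; the two conjugate profiles
#' are averaged.
#'
#' @param sol a \code{\link{pb_solution}} at the separation of interest.
#' @param r_bins radial bin edges, Angstrom.
#' @return data frame of class \code{ion_charge_profile}.
#' @export
net_charge_fraction_pb <- function(sol, r_bins = default_r_bins()) {
  stopifnot(inherits(sol, "pb_solution"))
  spec <- sol$spec
  l <- sol$levels[[length(sol$levels)]]
  g <- l$grid
  c0n <- number_density(spec$c0)
  rho <- pb_integrands(l$psi, spec$z, c0n)$charge
  rho[!l$acc] <- 0
  gx <- grid_coord(g, 1)
  w_pos <- (gx < -1e-9) + 0.5 * (abs(gx) <= 1e-9)
  w_neg <- (gx > 1e-9) + 0.5 * (abs(gx) <= 1e-9)
  d1 <- grid_dist2(g, sol$centers[1, ])
  d2 <- grid_dist2(g, sol$centers[2, ])
  h3 <- g$h^3
  Z <- spec$Z
  Q <- numeric(length(r_bins))
  for (b in seq_along(r_bins)) {
    r2 <- r_bins[b]^2
    q1 <- -sum(rho * w_pos * (d1 < r2)) * h3 / Z    # around +Z
    q2 <- +sum(rho * w_neg * (d2 < r2)) * h3 / Z    # around -Z
    Q[b] <- (q1 + q2) / 2
  }
  out <- data.frame(r = r_bins, Q = Q, Q_err = 0)
  structure(out, class = c("ion_charge_profile", "data.frame"),
            method = "PB", Z = Z, x = spec$x)
}

#' @export
print.ion_charge_profile <- function(x, ...) {
  cat(sprintf("ion_charge_profile (%s): Q at r = 14 A: %.4f; at r = 22 A: %.4f\n",
              attr(x, "method"), profile_at(x, 14), profile_at(x, 22)))
  invisible(x)
}

#' Interpolate a charge profile at a radius
#'
#' @param profile an \code{ion_charge_profile}.
#' @param r radius, Angstrom.
#' @return Q(r).
#' @export
profile_at <- function(profile, r) {
  i <- which(abs(profile$r - r) < 1e-9)
  if (length(i) == 1) return(profile$Q[i])
  stats::approx(profile$r, profile$Q, xout = r)$y
}

#' Relative PMF deviation between the two routes
#'
#' ddg = |(dG_MC(x0) - dG_PB(x0)) / dG_MC(x0)|, the dimensionless relative
#' deviation of the mean-field PMF from the explicit-ion PMF at a reference
#' separation (x0 = 22 A throughout).
#'
#' @param dg_mc,dg_pb PMF values at x0, kBT.
#' @return the absolute relative deviation.
#' @export
delta_delta_g <- function(dg_mc, dg_pb) {
  if (!is.finite(dg_mc) || dg_mc == 0)
    stop("relative deviation undefined: dG_MC is zero")
  abs((dg_mc - dg_pb) / dg_mc)
}

#' Apparent coupling parameter |Z| dQ*
#'
#' |Z| times the absolute difference of the MC and PB net ion charge
#' fractions at r = 14 A, where the profile difference peaks.  This single
#' number tracks the PMF deviation across salt conditions and charge
#' densities.
#'
#' @param profile_mc,profile_pb \code{ion_charge_profile}s sharing bins that
#'   include r = 14 A.
#' @param Z nanoparticle charge magnitude, e (default from the profiles).
#' @param r_star radius of the comparison, Angstrom.
#' @return |Z| * |Q_MC(r*) - Q_PB(r*)|.
#' @export
apparent_parameter <- function(profile_mc, profile_pb,
                               Z = attr(profile_mc, "Z"), r_star = 14) {
  for (p in list(profile_mc, profile_pb))
    if (!any(abs(p$r - r_star) < 1e-9))
      stop(sprintf("profile bins do not include r = %g A", r_star))
  abs(Z) * abs(profile_at(profile_mc, r_star) - profile_at(profile_pb, r_star))
}

#' Equivalent 1:1 salt concentration
#'
#' Given a ladder of an observable (dG(22 A) or Q(22 A)) against 1:1
#' concentration, returns the 1:1 concentration whose observable matches a
#' 2:2 target, by piecewise-linear interpolation in (log10 c0, value).
#' Targets outside the ladder's range are refused rather than extrapolated.
#'
#' @param ladder data frame with columns \code{c0} (mol/L) and \code{value}.
#' @param target observable value to match.
#' @return equivalent concentration, mol/L.
#' @export
equivalent_salt <- function(ladder, target) {
  stopifnot(is.data.frame(ladder), all(c("c0", "value") %in% names(ladder)),
            nrow(ladder) >= 2)
  ladder <- ladder[order(ladder$c0), ]
  dv <- diff(ladder$value)
  if (!(all(dv > 0) || all(dv < 0)))
    stop("ladder observable is not monotone in concentration")
  if (target < min(ladder$value) || target > max(ladder$value))
    stop("target outside the range of the ladder; refusing to extrapolate")
  lg <- stats::approx(ladder$value, log10(ladder$c0), xout = target)$y
  10^lg
}

#' MC-vs-PB comparison statistics at one state point
#'
#' @param dg_mc,dg_pb PMF values at x0, kBT.
#' @param profile_mc,profile_pb charge profiles at separation x0.
#' @param Z nanoparticle charge magnitude, e.
#' @param x0 comparison separation, Angstrom.
#' @return object of class \code{comparison_report} with \code{ddg},
#'   \code{dQ_star}, and \code{apparent} = |Z| dQ*.
#' @export
comparison_report <- function(dg_mc, dg_pb, profile_mc, profile_pb, Z,
                              x0 = 22) {
  dq <- abs(profile_at(profile_mc, 14) - profile_at(profile_pb, 14))
  structure(list(ddg = delta_delta_g(dg_mc, dg_pb), dQ_star = dq,
                 apparent = abs(Z) * dq, x0 = x0,
                 dg_mc = dg_mc, dg_pb = dg_pb, Z = Z),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report at x0 = %g A (|Z| = %ge):\n", x$x0, x$Z))
  cat(sprintf("  dG_MC = %.3f kBT, dG_PB = %.3f kBT\n", x$dg_mc, x$dg_pb))
  cat(sprintf("  ddg = %.3f (%.1f%%), dQ* = %.3f, |Z| dQ* = %.3f\n",
              x$ddg, 100 * x$ddg, x$dQ_star, x$apparent))
  invisible(x)
}

#' Net ion charge density landscape
#'
#' The 2D distribution of net ion charge density around the nanoparticle
#' pair, on the plane through both centres.  The MC estimate is averaged
#' cylindrically about the inter-particle axis to reduce variance; the PB
#' field is binned onto the same (axial, radial) raster.
#'
#' @param obj an \code{mc_chain} with frames or a \code{pb_solution}.
#' @param plane_resolution bin width, Angstrom.
#' @param u_max,rho_max axial half-extent and radial extent of the raster,
#'   Angstrom.
#' @return data frame of class \code{charge_landscape} with columns
#'   \code{u} (axial, bin centre relative to the midpoint), \code{rho}
#'   (radial bin centre) and \code{density} (e/Angstrom^3).
#' @export
charge_density_landscape <- function(obj, plane_resolution = 1,
                                     u_max = NULL, rho_max = 30) {
  UseMethod("charge_density_landscape")
}

landscape_bins <- function(x_sep, plane_resolution, u_max, rho_max) {
  if (is.null(u_max)) u_max <- x_sep / 2 + 18
  u_edges <- seq(-u_max, u_max, by = plane_resolution)
  r_edges <- seq(0, rho_max, by = plane_resolution)
  list(u = u_edges, r = r_edges)
}

#' @rdname charge_density_landscape
#' @export
charge_density_landscape.mc_chain <- function(obj, plane_resolution = 1,
                                              u_max = NULL, rho_max = 30) {
  fr <- obj$frames
  if (nrow(fr) == 0) stop("chain has no stored frames")
  b <- landscape_bins(obj$spec$x, plane_resolution, u_max, rho_max)
  nu <- length(b$u) - 1; nr <- length(b$r) - 1
  acc <- matrix(0, nu, nr)
  ni <- obj$n_ion
  if (ni > 0) {
    ic <- 2 + seq_len(ni)
    qi <- obj$charge[ic]
    for (f in seq_len(nrow(fr))) {
      ctr <- (fr[f, 1:3] + fr[f, 4:6]) / 2
      ux <- fr[f, 3 * (ic - 1) + 1] - ctr[1]
      rr <- sqrt((fr[f, 3 * (ic - 1) + 2] - ctr[2])^2 +
                 (fr[f, 3 * (ic - 1) + 3] - ctr[3])^2)
      iu <- findInterval(ux, b$u, rightmost.closed = TRUE)
      ir <- findInterval(rr, b$r, rightmost.closed = TRUE)
      ok <- iu >= 1 & iu <= nu & ir >= 1 & ir <= nr
      if (any(ok))
        for (k in which(ok)) acc[iu[k], ir[k]] <- acc[iu[k], ir[k]] + qi[k]
    }
  }
  du <- diff(b$u)[1]
  vol <- outer(rep(du, nu), pi * diff(b$r^2))
  dens <- acc / (vol * max(1, nrow(fr)))
  out <- data.frame(u = rep((b$u[-1] + b$u[-length(b$u)]) / 2, nr),
                    rho = rep((b$r[-1] + b$r[-length(b$r)]) / 2, each = nu),
                    density = as.vector(dens))
  structure(out, class = c("charge_landscape", "data.frame"), method = "MC",
            x = obj$spec$x, resolution = plane_resolution)
}

#' @rdname charge_density_landscape
#' @export
charge_density_landscape.pb_solution <- function(obj, plane_resolution = 1,
                                                 u_max = NULL, rho_max = 30) {
  l <- obj$levels[[length(obj$levels)]]
  g <- l$grid
  spec <- obj$spec
  b <- landscape_bins(spec$x, plane_resolution, u_max, rho_max)
  nu <- length(b$u) - 1; nr <- length(b$r) - 1
  rho_net <- pb_integrands(l$psi, spec$z, number_density(spec$c0))$charge
  rho_net[!l$acc] <- 0
  ux <- grid_coord(g, 1)
  rr <- sqrt(grid_coord(g, 2)^2 + grid_coord(g, 3)^2)
  iu <- findInterval(ux, b$u, rightmost.closed = TRUE)
  ir <- findInterval(rr, b$r, rightmost.closed = TRUE)
  ok <- iu >= 1 & iu <= nu & ir >= 1 & ir <= nr
  key <- (ir[ok] - 1) * nu + iu[ok]
  sums <- tapply(rho_net[ok], key, sum)
  cnts <- tapply(rho_net[ok], key, length)
  dens <- matrix(0, nu, nr)
  dens[as.integer(names(sums))] <- sums / cnts
  out <- data.frame(u = rep((b$u[-1] + b$u[-length(b$u)]) / 2, nr),
                    rho = rep((b$r[-1] + b$r[-length(b$r)]) / 2, each = nu),
                    density = as.vector(dens))
  structure(out, class = c("charge_landscape", "data.frame"), method = "PB",
            x = spec$x, resolution = plane_resolution)
}

#' Deviation map between two landscapes on the same raster
#'
#' @param map_pb,map_mc \code{charge_landscape}s with identical bins.
#' @return a \code{charge_landscape} of PB minus MC density.
#' @export
landscape_deviation <- function(map_pb, map_mc) {
  stopifnot(nrow(map_pb) == nrow(map_mc),
            all(abs(map_pb$u - map_mc$u) < 1e-9),
            all(abs(map_pb$rho - map_mc$rho) < 1e-9))
  out <- data.frame(u = map_pb$u, rho = map_pb$rho,
                    density = map_pb$density - map_mc$density)
  structure(out, class = c("charge_landscape", "data.frame"),
            method = "PB-MC", x = attr(map_pb, "x"),
            resolution = attr(map_pb, "resolution"))
}
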