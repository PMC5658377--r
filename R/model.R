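#' A charged hard sphere
#'
#' The primitive model represents nanoparticles and salt ions alike as
#' charged hard spheres in a uniform dielectric.  Nanoparticles have radius
#' 10 A and charge +Z or -Z; ions have radius 2 A and charge +z or -z.
#'
#' @param center numeric length-3, sphere centre in Angstrom.
#' @param radius hard-sphere radius, Angstrom.
#' @param charge charge in units of the elementary charge e.
#' @param kind one of "nanoparticle", "cation", "anion".
#' @return an object of class \code{charged_sphere}.
#' @export
charged_sphere <- function(center, radius, charge,
                           kind = c("nanoparticle", "cation", "anion")) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("'center' must be a finite 3-vector")
  if (!is.finite(radius) || radius <= 0) stop("'radius' must be positive")
  structure(list(center = center, radius = as.numeric(radius),
                 charge = as.numeric(charge), kind = kind),
            class = "charged_sphere")
}

#' Define one physical state point
#'
#' Collects everything that defines a single (Z, z, c0, x) system: the two
#' nanoparticle charges +Z/-Z, the salt valence and bulk concentration, the
#' centre-to-centre separation, the solvent dielectric and temperature, the
#' simulation cell, and the pseudo-spring parameters.  The default cell is
#' cubic with side x + 6 Debye lengths, the box-sizing rule used to keep
#' boundary effects negligible.
#'
#' @param Z nanoparticle charge magnitude, in e (the pair carries +Z and -Z).
#' @param z salt valence: 1 (1:1 salt) or 2 (2:2 salt).
#' @param c0 bulk salt concentration, mol/L.
#' @param x centre-to-centre separation, Angstrom; must lie in [22, x_ref].
#' @param eps relative solvent dielectric constant.
#' @param temperature absolute temperature, K.
#' @param box cell side lengths (3-vector, Angstrom); default x + 6 Debye
#'   lengths in every dimension.
#' @param k_spring spring constant of the tether, nN/A.
#' @param x_ref outer reference separation where the PMF is zeroed, Angstrom.
#' @param np_radius,ion_radius hard-sphere radii, Angstrom.
#' @return an object of class \code{system_spec}.
#' @export
system_spec <- function(Z, z, c0, x, eps = 78, temperature = 298.15,
                        box = NULL, k_spring = 9, x_ref = 40,
                        np_radius = 10, ion_radius = 2) {
  if (!is.finite(Z) || Z <= 0) stop("'Z' must be a positive charge magnitude")
  if (!z %in% c(1, 2)) stop("'z' must be 1 or 2")
  if (!is.finite(c0) || c0 <= 0) stop("'c0' must be positive")
  if (!is.finite(eps) || eps <= 0) stop("'eps' must be positive")
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive")
  if (!is.finite(x) || x < 22 || x > x_ref)
    stop("'x' must lie in [22, x_ref]")
  lD <- debye_length(z, c0, eps, temperature)
  min_side <- x + 6 * lD
  if (is.null(box)) {
    # default cell: the x + 6 lambda_D floor, widened so that (i) every wall
    # sits at least max(3 lambda_D, 25 A) beyond a nanoparticle surface and
    # (ii) for divalent salt the cell holds at least 6 Z / z ion pairs, so
    # the condensed layers (about Z/z pairs per particle) do not measurably
    # deplete the reservoir.  Both extensions come from a finite-size study
    # of F(22 A) and Q(r); see the package vignette.
    m <- max(3 * lD, 25)
    lx <- max(min_side, x + 2 * np_radius + 2 * m)
    lyz <- max(min_side, 2 * np_radius + 2 * m)
    box <- c(lx, lyz, lyz)
    if (z >= 2) {
      n_min <- ceiling(6 * Z / z)
      v_need <- n_min / number_density(c0)
      f <- (v_need / prod(box))^(1 / 3)
      if (f > 1) box <- box * f
    }
  }
  box <- as.numeric(box)
  if (length(box) != 3) stop("'box' must have 3 side lengths")
  if (any(box < min_side - 1e-9))
    stop(sprintf("box sides must be >= x + 6*lambda_D = %.1f A", min_side))
  structure(list(Z = Z, z = z, c0 = c0, x = x, eps = eps,
                 temperature = temperature, box = box, k_spring = k_spring,
                 x_ref = x_ref, np_radius = np_radius,
                 ion_radius = ion_radius, debye = lD,
                 lB = bjerrum_length(eps, temperature)),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf(
    "system_spec: |Z| = %ge, %g:%g salt at %g M, x = %g A (x_ref = %g A)\n",
    x$Z, x$z, x$z, x$c0, x$x, x$x_ref))
  cat(sprintf("  box %.1f x %.1f x %.1f A, eps = %g, T = %g K, k = %g nN/A\n",
              x$box[1], x$box[2], x$box[3], x$eps, x$temperature, x$k_spring))
  cat(sprintf("  lB = %.3f A, Debye length = %.2f A\n", x$lB, x$debye))
  invisible(x)
}

#' Pairwise energy of two charged hard spheres
#'
#' Coulomb plus hard-core interaction in kBT units: q_a q_b lB / r for
#' r >= sigma_a + sigma_b, and +Inf (the overlap sentinel) otherwise.
#'
#' @param a,b \code{charged_sphere} objects.
#' @param lB Bjerrum length, Angstrom.
#' @return energy in kBT, or \code{Inf} on overlap.
#' @export
pair_energy <- function(a, b, lB) {
  if (!is.finite(lB) || lB <= 0) stop("'lB' must be positive")
  r <- sqrt(sum((a$center - b$center)^2))
  if (r < a$radius + b$radius) return(Inf)
  qq <- a$charge * b$charge
  if (qq == 0) return(0)
  qq * lB / r
}

#' Total configurational energy
#'
#' Sum of the pair energies over all unordered pairs, in kBT; \code{Inf} if
#' any pair overlaps.
#'
#' @param cfg an \code{ion_config} (see \code{\link{build_system}}).
#' @param lB Bjerrum length, Angstrom; defaults to the value stored in the
#'   configuration.
#' @return energy in kBT.
#' @export
total_energy <- function(cfg, lB = cfg$lB) {
  total_energy_cpp(cfg$pos, cfg$radius, cfg$charge, lB)
}

#' Build an initial configuration for one state point
#'
#' Places the two nanoparticles at (centre -/+ x/2, 0, 0) along the x axis of
#' the cell (+Z on the low-x side) and inserts
#' \code{round(c0 * N_A * V_accessible)} neutral cation/anion pairs uniformly
#' at random without overlaps.  V_accessible excludes the wall layer
#' (ion centres keep one ion radius off every wall) and the two
#' nanoparticle exclusion spheres.  Ion depletion by binding is not
#' corrected; with cells at least six Debye lengths beyond the separation
#' this is a small perturbation at the salt concentrations studied.
#'
#' @param spec a \code{\link{system_spec}}.
#' @param seed integer seed; the construction is deterministic given
#'   (spec, seed).
#' @param max_tries placement attempts per ion before giving up.
#' @return an object of class \code{ion_config}: positions (N x 3), radii,
#'   charges, kinds, cell, and cached total energy.
#' @export
build_system <- function(spec, seed = 1, max_tries = 5000) {
  stopifnot(inherits(spec, "system_spec"))
  set.seed(as.integer(seed))
  L <- spec$box
  ctr <- L / 2
  a <- spec$np_radius
  ri <- spec$ion_radius
  np1 <- ctr + c(-spec$x / 2, 0, 0)
  np2 <- ctr + c(+spec$x / 2, 0, 0)
  if (any(np1 < a) || any(np2 > L - a))
    stop("box too small to contain both nanoparticles")

  # accessible volume for ion centres
  v_box <- prod(L - 2 * ri)
  r_ex <- a + ri
  v_sph <- 4 / 3 * pi * r_ex^3
  v_lens <- if (spec$x < 2 * r_ex)
    pi * (4 * r_ex + spec$x) * (2 * r_ex - spec$x)^2 / 12 else 0
  v_acc <- v_box - (2 * v_sph - v_lens)
  n_pairs <- round(number_density(spec$c0) * v_acc)

  n <- 2 + 2 * n_pairs
  pos <- matrix(0, n, 3)
  pos[1, ] <- np1
  pos[2, ] <- np2
  radius <- c(a, a, rep(ri, 2 * n_pairs))
  charge <- c(spec$Z, -spec$Z,
              rep(spec$z, n_pairs), rep(-spec$z, n_pairs))
  kind <- c("nanoparticle", "nanoparticle",
            rep("cation", n_pairs), rep("anion", n_pairs))

  if (n_pairs > 0) {
    for (i in seq_len(2 * n_pairs)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        p <- ri + stats::runif(3) * (L - 2 * ri)
        if (sum((p - np1)^2) < r_ex^2 || sum((p - np2)^2) < r_ex^2) next
        if (i > 1) {
          d2 <- rowSums(sweep(pos[3:(2 + i - 1), , drop = FALSE], 2, p)^2)
          if (any(d2 < (2 * ri)^2)) next
        }
        pos[2 + i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed)
        stop("ion placement failed: packing too dense for rejection sampling")
    }
  }

  cfg <- structure(list(pos = pos, radius = radius, charge = charge,
                        kind = kind, cell = L, n_pairs = n_pairs,
                        lB = spec$lB, spec = spec),
                   class = "ion_config")
  cfg$energy <- total_energy(cfg)
  cfg
}

#' @export
print.ion_config <- function(x, ...) {
  cat(sprintf(
    "ion_config: 2 nanoparticles (+/-%ge) + %d ion pairs (z = %g) in %.0f x %.0f x %.0f A cell\n",
    x$spec$Z, x$n_pairs, x$spec$z, x$cell[1], x$cell[2], x$cell[3]))
  cat(sprintf("  total energy %.3f kBT\n", x$energy))
  invisible(x)
}

#' Write a configuration as an XYZ snapshot
#'
#' Element column encodes the particle kind (P/Q for the +/- nanoparticles,
#' C for cations, A for anions).
#'
#' @param cfg an \code{ion_config}.
#' @param path output file.
#' @export
write_xyz <- function(cfg, path) {
  sym <- c(nanoparticle = "P", cation = "C", anion = "A")
  el <- sym[cfg$kind]
  el[cfg$kind == "nanoparticle" & cfg$charge < 0] <- "Q"
  lines <- c(sprintf("%d", nrow(cfg$pos)),
             sprintf("ionpmf snapshot cell %.4f %.4f %.4f",
                     cfg$cell[1], cfg$cell[2], cfg$cell[3]),
             sprintf("%s %.6f %.6f %.6f", el,
                     cfg$pos[, 1], cfg$pos[, 2], cfg$pos[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a configuration as JSON (lossless round trip)
#'
#' @param cfg an \code{ion_config}.
#' @param path file path.
#' @export
write_config_json <- function(cfg, path) {
  obj <- list(pos = cfg$pos, radius = cfg$radius, charge = cfg$charge,
              kind = cfg$kind, cell = cfg$cell, n_pairs = cfg$n_pairs,
              lB = cfg$lB)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- structure(list(pos = matrix(obj$pos, ncol = 3),
                        radius = obj$radius, charge = obj$charge,
                        kind = obj$kind, cell = obj$cell,
                        n_pairs = obj$n_pairs, lB = obj$lB, spec = NULL),
                   class = "ion_config")
  cfg$energy <- total_energy(cfg)
  cfg
}
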