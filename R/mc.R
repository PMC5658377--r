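#' Monte Carlo sampling parameters
#'
#' Sweep counts, step sizes, and sampling strides for the Metropolis chain.
#' One sweep attempts one displacement per ion plus \code{np_attempts}
#' x-axis displacements of the tethered nanoparticle.  Step sizes are
#' auto-tuned toward ~40\% acceptance during equilibration and frozen for
#' production, so detailed balance holds throughout the sampled part of the
#' chain.
#'
#' @param n_equil equilibration sweeps.
#' @param n_prod production sweeps.
#' @param ion_step initial maximum ion displacement, Angstrom.
#' @param np_step initial maximum nanoparticle displacement, Angstrom.
#' @param np_attempts tethered-nanoparticle move attempts per sweep.
#' @param frame_stride store an ion snapshot every this many production
#'   sweeps (0 disables frames).
#' @param block_count number of blocks for block-averaged error bars.
#' @param tune auto-tune step sizes during equilibration.
#' @return an object of class \code{mc_params}.
#' @export
mc_params <- function(n_equil = 20000, n_prod = 60000, ion_step = 10,
                      np_step = 0.1, np_attempts = 8, frame_stride = 20,
                      block_count = 20, tune = TRUE) {
  stopifnot(n_equil > 0, n_prod > 0, ion_step > 0, np_step > 0,
            np_attempts >= 1, block_count > 0)
  structure(list(n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 ion_step = ion_step, np_step = np_step,
                 np_attempts = as.integer(np_attempts),
                 frame_stride = as.integer(frame_stride),
                 block_count = as.integer(block_count), tune = tune),
            class = "mc_params")
}

#' Run one Metropolis chain
#'
#' Canonical Metropolis sampling of a configuration: acceptance
#' min(1, exp(-beta dU)) where dU includes all Coulomb/hard-core pair terms
#' and, for nanoparticle moves, the pseudo-spring energy k(sep - x)^2 / 2.
#' One nanoparticle is frozen; the other moves along the x axis only.
#' The chain is reproducible under a fixed R random seed (call
#' \code{set.seed} or pass \code{seed}).
#'
#' @param cfg an \code{ion_config} from \code{\link{build_system}} (or a
#'   fixture).
#' @param spec the matching \code{\link{system_spec}}; defaults to the one
#'   stored in \code{cfg}.
#' @param params an \code{\link{mc_params}} object.
#' @param seed optional integer seed set before sampling.
#' @param mobile if FALSE the second particle is not tethered/moved (used by
#'   fixtures with a single nanoparticle).
#' @param store_frames keep thinned ion snapshots for observables.
#' @return an object of class \code{mc_chain}: the spring-extension series
#'   \code{dx} (Angstrom, one value per production sweep), snapshot frames,
#'   acceptance diagnostics, tuned step sizes, and an energy-bookkeeping
#'   check.  A warning is recorded in \code{diagnostics} if an acceptance
#'   rate leaves [0.1, 0.9].
#' @export
run_chain <- function(cfg, spec = cfg$spec, params = mc_params(),
                      seed = NULL, mobile = TRUE, store_frames = TRUE) {
  stopifnot(inherits(cfg, "ion_config"), inherits(params, "mc_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (mobile && nrow(cfg$pos) < 2)
    stop("a tethered chain needs two nanoparticles")
  k_kt <- if (mobile) spring_kbt(spec$k_spring, spec$temperature) else 0
  n_np <- if (mobile) 2L else 1L
  res <- mc_chain_cpp(cfg$pos, cfg$radius, cfg$charge, cfg$cell, cfg$lB,
                      mobile, k_kt, if (mobile) spec$x else 0, n_np,
                      params$n_equil, params$n_prod, params$ion_step,
                      params$np_step, params$np_attempts,
                      params$frame_stride, params$tune, store_frames)
  warn <- character()
  for (nm in c("acc_ion", "acc_np")) {
    a <- res[[nm]]
    if (!is.na(a) && (a < 0.1 || a > 0.9))
      warn <- c(warn, sprintf("%s acceptance %.2f outside [0.1, 0.9]", nm, a))
  }
  drift <- abs(res$energy_running - res$energy_recomputed) /
    max(1, abs(res$energy_recomputed))
  structure(list(
    dx = res$dx, frames = res$frames[seq_len(res$n_frames), , drop = FALSE],
    pos_final = res$pos_final, n_ion = res$n_ion,
    charge = cfg$charge, kind = cfg$kind, cell = cfg$cell,
    spec = spec, params = params, mobile = mobile,
    diagnostics = list(acc_ion = res$acc_ion, acc_np = res$acc_np,
                       ion_step = res$ion_step, np_step = res$np_step,
                       energy_drift = drift, warnings = warn)),
    class = "mc_chain")
}

#' @export
print.mc_chain <- function(x, ...) {
  cat(sprintf("mc_chain: %d production sweeps, %d frames kept\n",
              length(x$dx), nrow(x$frames)))
  d <- x$diagnostics
  cat(sprintf("  acceptance: ions %.2f, nanoparticle %.2f (steps %.2f / %.3f A)\n",
              d$acc_ion, d$acc_np, d$ion_step, d$np_step))
  cat(sprintf("  energy bookkeeping drift: %.2e (relative)\n", d$energy_drift))
  if (length(d$warnings)) cat("  warnings:", paste(d$warnings, collapse = "; "), "\n")
  invisible(x)
}

# block-averaged standard error of the mean of a series
block_stderr <- function(series, block_count) {
  nb <- as.integer(block_count)
  n <- length(series)
  if (n < nb) stop("series shorter than the number of blocks")
  m <- n %/% nb
  bm <- colMeans(matrix(series[seq_len(m * nb)], nrow = m))
  stats::sd(bm) / sqrt(nb)
}

#' Spring-force estimate at one separation
#'
#' The pseudo-spring estimator: the mean force between the nanoparticles at
#' separation x equals k times the mean spring extension.  Attraction
#' compresses the spring, so attractive forces are negative and integrate to
#' a negative PMF.
#'
#' @param dx spring-extension series, Angstrom (one value per sweep).
#' @param k spring constant, nN/A.
#' @param block_count blocks for the error estimate.
#' @param x separation label, Angstrom (carried through to the PMF).
#' @return an object of class \code{force_sample} with the force in nN and
#'   its block-averaged standard error.
#' @export
estimate_force <- function(dx, k = 9, block_count = 20, x = NA_real_) {
  if (length(dx) == 0 || all(is.na(dx))) stop("empty extension series")
  mean_dx <- mean(dx)
  se <- if (length(dx) >= block_count) block_stderr(dx, block_count) else stats::sd(dx) / sqrt(length(dx))
  if (is.na(se)) se <- 0
  structure(list(x = x, mean_dx = mean_dx, F = k * mean_dx,
                 stderr_F = k * se, n_samples = length(dx)),
            class = "force_sample")
}

#' @export
print.force_sample <- function(x, ...) {
  cat(sprintf("force_sample at x = %g A: F = %.5f +/- %.5f nN (<dx> = %.5f A, n = %d)\n",
              x$x, x$F, x$stderr_F, x$mean_dx, x$n_samples))
  invisible(x)
}

#' Integrate spring forces into a potential of mean force
#'
#' Trapezoidal quadrature of the mean force from each separation up to the
#' reference separation: dG(x) = integral_x^x_ref F(x') dx', converted from
#' nN*Angstrom to kBT.  dG(x_ref) is exactly zero and statistical errors are
#' propagated in quadrature through the trapezoid weights.
#'
#' @param forces data frame with columns \code{x}, \code{F_nN},
#'   \code{F_err} (or a list of \code{force_sample}s), sorted by x and
#'   including \code{x_ref}.
#' @param x_ref reference separation, Angstrom.
#' @param temperature temperature for the kBT conversion, K.
#' @return an object of class \code{pmf_curve}: data frame with \code{x},
#'   \code{dG} (kBT) and \code{dG_err}, with method metadata attached.
#' @export
integrate_pmf <- function(forces, x_ref = 40, temperature = 298.15) {
  if (is.list(forces) && !is.data.frame(forces) &&
      all(vapply(forces, inherits, TRUE, "force_sample"))) {
    forces <- data.frame(x = vapply(forces, `[[`, 0, "x"),
                         F_nN = vapply(forces, `[[`, 0, "F"),
                         F_err = vapply(forces, `[[`, 0, "stderr_F"))
  }
  stopifnot(is.data.frame(forces), all(c("x", "F_nN") %in% names(forces)))
  if (is.null(forces$F_err)) forces$F_err <- 0
  if (is.unsorted(forces$x, strictly = TRUE))
    stop("force samples must be sorted by x without duplicates")
  if (!any(abs(forces$x - x_ref) < 1e-9))
    stop("force samples must include x_ref")
  forces <- forces[forces$x <= x_ref + 1e-9, ]
  n <- nrow(forces)
  u <- nn_angstrom_in_kbt(temperature)
  dG <- dG_var <- numeric(n)
  for (i in seq_len(n)) {
    if (i == n) { dG[i] <- 0; dG_var[i] <- 0; next }
    idx <- i:n
    xs <- forces$x[idx]
    w <- numeric(length(idx))
    dxs <- diff(xs)
    w[1] <- dxs[1] / 2
    w[length(idx)] <- dxs[length(dxs)] / 2
    if (length(idx) > 2)
      w[2:(length(idx) - 1)] <- (xs[3:length(idx)] - xs[1:(length(idx) - 2)]) / 2
    dG[i] <- sum(w * forces$F_nN[idx]) * u
    dG_var[i] <- sum((w * forces$F_err[idx] * u)^2)
  }
  structure(data.frame(x = forces$x, dG = dG, dG_err = sqrt(dG_var)),
            class = c("pmf_curve", "data.frame"),
            method = "MC", x_ref = x_ref, temperature = temperature)
}

#' Convergence diagnostics for a separation series
#'
#' Running mean plus a split-half comparison: the chain is flagged converged
#' when the two half means agree within twice their combined block-averaged
#' standard errors.
#'
#' @param sep separation (or any scalar observable) series.
#' @param block_count blocks per half for the error estimate.
#' @return a list of class \code{convergence_report}.
#' @export
convergence_report <- function(sep, block_count = 10) {
  n <- length(sep)
  stopifnot(n >= 2 * block_count)
  h1 <- sep[seq_len(n %/% 2)]
  h2 <- sep[(n %/% 2 + 1):n]
  m1 <- mean(h1); m2 <- mean(h2)
  se <- sqrt(block_stderr(h1, block_count)^2 + block_stderr(h2, block_count)^2)
  structure(list(running_mean = cumsum(sep) / seq_len(n),
                 half_means = c(m1, m2), half_diff = m1 - m2,
                 combined_se = se,
                 converged = abs(m1 - m2) < 2 * se),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report: half means %.5f / %.5f (diff %.2e, 2*se %.2e) -> %s\n",
              x$half_means[1], x$half_means[2], x$half_diff,
              2 * x$combined_se,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Monte Carlo potential of mean force
#'
#' The full pseudo-spring pipeline for one (Z, z, c0) system: for every
#' separation on the force grid a system is built, equilibrated and sampled,
#' the spring force is estimated, and the forces are integrated from x_ref
#' inward.  Chains at separations listed in \code{samples_at} keep their ion
#' snapshots for bound-ion observables.
#'
#' @param Z nanoparticle charge magnitude, e.
#' @param z salt valence.
#' @param c0 bulk concentration, mol/L.
#' @param x_values force-grid separations, Angstrom (must include x_ref).
#' @param params an \code{\link{mc_params}}.
#' @param seed integer; window w uses seed + 97 * w.
#' @param samples_at separations whose chains are retained with frames.
#' @param eps,temperature,k_spring,x_ref physical parameters, see
#'   \code{\link{system_spec}}.
#' @param verbose print per-window progress.
#' @return an object of class \code{mc_pmf} containing the \code{pmf_curve},
#'   the force table, retained chains, and per-window diagnostics
#'   (acceptance rates, tuned steps, and a split-half convergence flag for
#'   the separation series).
#' @export
mc_pmf <- function(Z, z, c0, x_values = seq(22, 40, by = 2),
                   params = mc_params(), seed = 1, samples_at = 22,
                   eps = 78, temperature = 298.15, k_spring = 9, x_ref = 40,
                   verbose = FALSE) {
  x_values <- sort(unique(x_values))
  forces <- data.frame(x = x_values, F_nN = NA_real_, F_err = NA_real_)
  chains <- list()
  diag <- list()
  for (w in seq_along(x_values)) {
    xw <- x_values[w]
    spec <- system_spec(Z, z, c0, x = xw, eps = eps,
                        temperature = temperature, k_spring = k_spring,
                        x_ref = x_ref)
    wseed <- as.integer(seed) + 97L * w
    cfg <- build_system(spec, seed = wseed)
    keep <- any(abs(samples_at - xw) < 1e-9)
    ch <- run_chain(cfg, spec, params, store_frames = keep)
    fs <- estimate_force(ch$dx, k = k_spring, block_count = params$block_count,
                         x = xw)
    forces$F_nN[w] <- fs$F
    forces$F_err[w] <- fs$stderr_F
    diag[[as.character(xw)]] <- ch$diagnostics
    diag[[as.character(xw)]]$converged <-
      convergence_report(ch$dx + xw)$converged
    if (keep) chains[[as.character(xw)]] <- ch
    if (verbose)
      message(sprintf("  x = %4.1f A: F = %+0.5f +/- %.5f nN (acc ion %.2f np %.2f)",
                      xw, fs$F, fs$stderr_F, ch$diagnostics$acc_ion,
                      ch$diagnostics$acc_np))
  }
  curve <- integrate_pmf(forces, x_ref = x_ref, temperature = temperature)
  attr(curve, "Z") <- Z; attr(curve, "z") <- z; attr(curve, "c0") <- c0
  structure(list(curve = curve, forces = forces, chains = chains,
                 diagnostics = diag, Z = Z, z = z, c0 = c0, seed = seed),
            class = "mc_pmf")
}

#' @export
print.mc_pmf <- function(x, ...) {
  cat(sprintf("mc_pmf: |Z| = %ge, %g:%g salt at %g M\n", x$Z, x$z, x$z, x$c0))
  print(x$curve)
  invisible(x)
}

#' Read a PMF curve at a given separation
#'
#' Exact grid value where available, linear interpolation otherwise.
#'
#' @param curve a \code{pmf_curve}.
#' @param x separation, Angstrom.
#' @return dG(x) in kBT.
#' @export
pmf_at <- function(curve, x) {
  i <- which(abs(curve$x - x) < 1e-9)
  if (length(i) == 1) return(curve$dG[i])
  stats::approx(curve$x, curve$dG, xout = x)$y
}
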