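# Orchestration: full MC-vs-PB comparison at a state point, configuration
# files, sweeps with a resumable manifest, and deterministic fixtures.

#' Full MC-vs-PB comparison at one state point
#'
#' Runs the spring-force Monte Carlo PMF and the focused Poisson-Boltzmann
#' PMF for one (Z, z, c0) system, computes the bound-ion charge profiles by
#' both routes at the comparison separation, and assembles the deviation
#' report.
#'
#' @inheritParams mc_pmf
#' @param x_values MC force-grid separations (must include x_ref).
#' @param x0 comparison separation, Angstrom.
#' @param pb_final_h final-level PB resolution, Angstrom.
#' @param schedule optional explicit \code{\link{focusing_schedule}}.
#' @param r_bins radial bins for the charge profiles.
#' @return an object of class \code{pmf_comparison}: \code{mc}, \code{pb},
#'   \code{profile_mc}, \code{profile_pb}, \code{report}.
#' @export
compare_methods <- function(Z, z, c0, x_values = seq(22, 40, by = 2),
                            params = mc_params(), seed = 1, x0 = 22,
                            pb_final_h = 0.5, schedule = NULL,
                            r_bins = default_r_bins(), eps = 78,
                            temperature = 298.15, k_spring = 9, x_ref = 40,
                            verbose = FALSE) {
  mc <- mc_pmf(Z, z, c0, x_values = x_values, params = params, seed = seed,
               samples_at = x0, eps = eps, temperature = temperature,
               k_spring = k_spring, x_ref = x_ref, verbose = verbose)
  pb <- pb_pmf(Z, z, c0, x_values = c(x0, x_ref), schedule = schedule,
               final_h = pb_final_h, keep_solutions = x0, eps = eps,
               temperature = temperature, x_ref = x_ref, verbose = verbose)
  pmc <- net_charge_fraction_mc(mc$chains[[as.character(x0)]], r_bins,
                                block_count = params$block_count)
  ppb <- net_charge_fraction_pb(pb$solutions[[as.character(x0)]], r_bins)
  rep <- comparison_report(pmf_at(mc$curve, x0), pmf_at(pb$curve, x0),
                           pmc, ppb, Z, x0 = x0)
  structure(list(mc = mc, pb = pb, profile_mc = pmc, profile_pb = ppb,
                 report = rep, Z = Z, z = z, c0 = c0, seed = seed),
            class = "pmf_comparison")
}

#' @export
print.pmf_comparison <- function(x, ...) {
  cat(sprintf("pmf_comparison: |Z| = %ge, %g:%g salt at %g M\n",
              x$Z, x$z, x$z, x$c0))
  print(x$report)
  invisible(x)
}

# canonical md5 of an R object (via its deparsed form on disk)
object_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj, control = "all"), f)
  unname(tools::md5sum(f))
}

# deterministic per-combination seed below 2^31
combo_seed <- function(seed_base, combo) {
  h <- object_hash(combo)
  seed_base + strtoi(substr(h, 1, 7), base = 16L)
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections \code{physical} (eps, temperature,
#' radii, k_spring, x_ref), \code{mc} (\code{\link{mc_params}} fields),
#' \code{pb} (final_h, tol), \code{sweep} (lists of Z, z, c0 and the MC
#' force grid x_values), \code{output_dir} and \code{seed_base}.  Missing
#' fields receive the standard defaults (eps 78, radii 10/2 A, k = 9 nN/A,
#' x_ref = 40 A); every sweep combination is validated against the system
#' invariants before anything runs.
#'
#' @param path YAML file.
#' @return a validated list of class \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  phys_def <- list(eps = 78, temperature = 298.15, np_radius = 10,
                   ion_radius = 2, k_spring = 9, x_ref = 40)
  phys <- utils::modifyList(phys_def, raw$physical %||% list())
  for (k in names(raw$physical %||% list()))
    if (!k %in% names(phys_def)) stop("unknown physical key: ", k)
  mc_def <- formals(mc_params)
  mc <- utils::modifyList(lapply(mc_def, eval), raw$mc %||% list())
  for (k in names(raw$mc %||% list()))
    if (!k %in% names(mc_def)) stop("unknown mc key: ", k)
  pb <- utils::modifyList(list(final_h = 0.5, tol = 1e-4, reduced = FALSE),
                          raw$pb %||% list())
  sweep <- raw$sweep %||% list()
  if (is.null(sweep$Z) || is.null(sweep$z) || is.null(sweep$c0))
    stop("sweep must list Z, z and c0")
  sweep$x_values <- sweep$x_values %||% seq(22, 40, by = 2)
  # validate every combination (box rule, separation range, ...)
  for (Z in sweep$Z) for (zz in sweep$z) for (c0 in sweep$c0)
    for (x in sweep$x_values)
      system_spec(Z, zz, c0, x = x, eps = phys$eps,
                  temperature = phys$temperature, k_spring = phys$k_spring,
                  x_ref = phys$x_ref)
  cfg <- list(physical = phys, mc = do.call(mc_params, mc), pb = pb,
              sweep = sweep,
              output_dir = raw$output_dir %||% "ionpmf-results",
              seed_base = as.integer(raw$seed_base %||% 1L))
  structure(cfg, class = "run_config")
}

#' Save a run configuration back to YAML
#'
#' @param cfg a \code{run_config}.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  out <- list(physical = cfg$physical, mc = unclass(cfg$mc), pb = cfg$pb,
              sweep = cfg$sweep, output_dir = cfg$output_dir,
              seed_base = cfg$seed_base)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full comparison sweep
#'
#' Executes \code{\link{compare_methods}} for every (Z, z, c0) combination
#' of the sweep, writing per-point CSV/JSON artifacts and a manifest with
#' content hashes.  Completed points (matching manifest hash) are skipped on
#' rerun; individual point failures are recorded and the sweep continues.
#' When a sweep contains both 1:1 ladders and 2:2 points at the same Z, an
#' equivalent-salt table is emitted.
#'
#' @param cfg a \code{run_config} from \code{\link{load_config}}.
#' @param verbose print progress.
#' @return data frame summarising every point (invisibly also written to
#'   \code{summary.csv}).
#' @export
run_comparison <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  combos <- expand.grid(Z = cfg$sweep$Z, z = cfg$sweep$z, c0 = cfg$sweep$c0,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    combo <- as.list(combos[ci, ])
    tag <- sprintf("Z%g_z%g_c%g", combo$Z, combo$z, combo$c0)
    chash <- object_hash(c(combo, cfg$mc, cfg$pb,
                           list(x = cfg$sweep$x_values,
                                seed = cfg$seed_base)))
    entry <- manifest[[tag]]
    if (!is.null(entry) && identical(entry$config_hash, chash) &&
        all(file.exists(file.path(cfg$output_dir, unlist(entry$files))))) {
      if (verbose) message(tag, ": complete, skipping")
      rows[[tag]] <- as.data.frame(entry$summary)
      next
    }
    seed <- combo_seed(cfg$seed_base, combo)
    sched <- if (isTRUE(cfg$pb$reduced))
      function(spec) reduced_schedule(spec, final_h = cfg$pb$final_h,
                                      tol = cfg$pb$tol) else NULL
    res <- tryCatch(
      compare_methods(combo$Z, combo$z, combo$c0,
                      x_values = cfg$sweep$x_values, params = cfg$mc,
                      seed = seed, pb_final_h = cfg$pb$final_h,
                      schedule = sched,
                      eps = cfg$physical$eps,
                      temperature = cfg$physical$temperature,
                      k_spring = cfg$physical$k_spring,
                      x_ref = cfg$physical$x_ref, verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest[[tag]] <- list(config_hash = chash, error = conditionMessage(res))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA)
      warning(tag, " failed: ", conditionMessage(res))
      next
    }
    files <- write_point_artifacts(res, cfg, tag, seed)
    summ <- data.frame(Z = combo$Z, z = combo$z, c0 = combo$c0,
                       dg_mc = res$report$dg_mc, dg_pb = res$report$dg_pb,
                       ddg = res$report$ddg, dQ_star = res$report$dQ_star,
                       apparent = res$report$apparent, seed = seed)
    hashes <- as.list(tools::md5sum(file.path(cfg$output_dir, files)))
    names(hashes) <- files
    manifest[[tag]] <- list(config_hash = chash, files = as.list(files),
                            hashes = hashes, summary = as.list(summ))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
    rows[[tag]] <- summ
    if (verbose) message(sprintf("%s: ddg = %.3f", tag, res$report$ddg))
  }
  summary <- do.call(rbind, rows)
  if (!is.null(summary)) {
    utils::write.csv(summary, file.path(cfg$output_dir, "summary.csv"),
                     row.names = FALSE)
    write_equivalent_salt_tables(summary, cfg)
  }
  invisible(summary)
}

write_point_artifacts <- function(res, cfg, tag, seed) {
  od <- cfg$output_dir
  pmf_file <- paste0(tag, "_pmf.csv")
  pmf <- rbind(
    data.frame(x_A = res$mc$curve$x, F_nN = res$mc$forces$F_nN,
               F_err = res$mc$forces$F_err, dG_kT = res$mc$curve$dG,
               dG_err = res$mc$curve$dG_err, method = "MC"),
    data.frame(x_A = res$pb$curve$x, F_nN = NA, F_err = NA,
               dG_kT = res$pb$curve$dG, dG_err = res$pb$curve$dG_err,
               method = "PB"))
  pmf$Z <- res$Z; pmf$z <- res$z; pmf$c0_M <- res$c0; pmf$seed <- seed
  utils::write.csv(pmf, file.path(od, pmf_file), row.names = FALSE)
  prof_file <- paste0(tag, "_qprofile.csv")
  prof <- rbind(
    data.frame(r = res$profile_mc$r, Q = res$profile_mc$Q,
               Q_err = res$profile_mc$Q_err, method = "MC"),
    data.frame(r = res$profile_pb$r, Q = res$profile_pb$Q,
               Q_err = res$profile_pb$Q_err, method = "PB"))
  utils::write.csv(prof, file.path(od, prof_file), row.names = FALSE)
  rep_file <- paste0(tag, "_report.json")
  jsonlite::write_json(
    c(unclass(res$report)[c("ddg", "dQ_star", "apparent", "x0",
                            "dg_mc", "dg_pb", "Z")],
      list(z = res$z, c0 = res$c0, seed = seed,
           mc_params = unclass(res$mc$chains[[1]]$params %||% cfg$mc))),
    file.path(od, rep_file), auto_unbox = TRUE, digits = NA)
  c(pmf_file, prof_file, rep_file)
}

write_equivalent_salt_tables <- function(summary, cfg) {
  out <- list()
  for (Z in unique(summary$Z)) {
    lad <- summary[summary$Z == Z & summary$z == 1, ]
    tgt <- summary[summary$Z == Z & summary$z == 2, ]
    if (nrow(lad) < 2 || nrow(tgt) == 0) next
    for (i in seq_len(nrow(tgt))) {
      eq <- tryCatch(
        equivalent_salt(data.frame(c0 = lad$c0, value = lad$dg_mc),
                        tgt$dg_mc[i]),
        error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        Z = Z, c0_22 = tgt$c0[i], dg_22 = tgt$dg_mc[i], c0_equiv_11 = eq)
    }
  }
  if (length(out)) {
    utils::write.csv(do.call(rbind, out),
                     file.path(cfg$output_dir, "equivalent_salt.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Deterministic miniature fixtures with oracle expectations
#'
#' Tiny analytically checkable systems used throughout the test-suite:
#' \describe{
#'   \item{spring_only}{two neutral spheres joined by the 9 nN/A spring;
#'     the extension must be Gaussian with sd sqrt(kBT/k) ~ 0.068 A.}
#'   \item{ideal_gas}{neutral ions in a box; density uniform over the
#'     accessible volume.}
#'   \item{one_ion}{one fixed charged nanoparticle plus a single cation;
#'     the radial density follows the one-particle Boltzmann factor.}
#'   \item{dh_sphere}{an isolated weakly charged sphere in 10 mM 1:1 salt
#'     with the linearized screened-potential table attached.}
#'   \item{tiny_pair}{both nanoparticles plus one ion pair, with the total
#'     energy worked out term by term.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed for the stochastic placements.
#' @return list with the configuration/spec and an \code{expected} list of
#'   oracle values.
#' @export
make_fixture <- function(name = c("spring_only", "ideal_gas", "one_ion",
                                  "dh_sphere", "tiny_pair"), seed = 1) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "spring_only") {
    L <- c(80, 60, 60)
    pos <- rbind(c(25, 30, 30), c(55, 30, 30))
    cfg <- structure(list(pos = pos, radius = c(10, 10), charge = c(0, 0),
                          kind = rep("nanoparticle", 2), cell = L,
                          n_pairs = 0, lB = bjerrum_length(), spec = NULL),
                     class = "ion_config")
    cfg$energy <- 0
    spec <- system_spec(1, 1, 1, x = 30, box = L, x_ref = 40)
    return(list(name = name, cfg = cfg, spec = spec,
                expected = list(
                  dx_sd = sqrt(1 / spring_kbt(9)), dx_mean = 0)))
  }
  if (name == "ideal_gas") {
    L <- c(40, 40, 40)
    n <- 40
    pos <- rbind(c(5, 20, 20),
                 matrix(2 + stats::runif(3 * n) * (40 - 4), ncol = 3))
    cfg <- structure(list(pos = pos, radius = c(0.5, rep(0, n)),
                          charge = rep(0, n + 1),
                          kind = c("nanoparticle", rep("cation", n)),
                          cell = L, n_pairs = 0, lB = bjerrum_length(),
                          spec = NULL),
                     class = "ion_config")
    cfg$energy <- 0
    return(list(name = name, cfg = cfg,
                expected = list(mean_pos = rep(20, 3), n_ion = n)))
  }
  if (name == "one_ion") {
    L <- c(50, 50, 50)
    pos <- rbind(c(25, 25, 25), c(40, 25, 25))
    cfg <- structure(list(pos = pos, radius = c(10, 2), charge = c(6, -1),
                          kind = c("nanoparticle", "anion"), cell = L,
                          n_pairs = 0, lB = bjerrum_length(), spec = NULL),
                     class = "ion_config")
    cfg$energy <- total_energy(cfg)
    return(list(name = name, cfg = cfg,
                expected = list(boltzmann_weight = function(r)
                  exp(6 * bjerrum_length() / r))))
  }
  if (name == "dh_sphere") {
    kappa <- inv_debye(1, 0.01)
    r <- seq(14, 30, by = 1)
    psi <- dh_potential(cbind(r, 0, 0), rbind(c(0, 0, 0)), 1, kappa,
                        bjerrum_length(), R = 12)
    return(list(name = name, Z = 1, z = 1, c0 = 0.01, kappa = kappa,
                expected = list(r = r, psi = psi)))
  }
  # tiny_pair: +1/-1 nanoparticles at 30 A plus one salt pair, by-hand energy
  L <- c(120, 120, 120)
  pos <- rbind(c(45, 60, 60), c(75, 60, 60), c(60, 75, 60), c(60, 45, 60))
  charge <- c(1, -1, 1, -1)
  cfg <- structure(list(pos = pos, radius = c(10, 10, 2, 2),
                        charge = charge,
                        kind = c("nanoparticle", "nanoparticle", "cation",
                                 "anion"),
                        cell = L, n_pairs = 1, lB = bjerrum_length(),
                        spec = NULL),
                   class = "ion_config")
  lB <- bjerrum_length()
  pairs <- utils::combn(4, 2)
  u <- sum(apply(pairs, 2, function(p) {
    r <- sqrt(sum((pos[p[1], ] - pos[p[2], ])^2))
    charge[p[1]] * charge[p[2]] * lB / r
  }))
  cfg$energy <- total_energy(cfg)
  list(name = name, cfg = cfg, expected = list(energy = u))
}
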