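test_that("estimate_force is k times the mean extension with block errors", {
  # constant extension of 0.01 A at k = 9 nN/A
  f <- estimate_force(rep(0.01, 1000), k = 9, x = 30)
  expect_equal(f$F, 0.09)
  expect_equal(f$stderr_F, 0)
  expect_equal(estimate_force(rep(0, 500))$F, 0)
  expect_error(estimate_force(numeric(0)), "empty")
  # i.i.d. Gaussian series: recover k*mean within errors, stderr near theory
  set.seed(1)
  n <- 40000
  dx <- stats::rnorm(n, mean = 0.02, sd = 0.07)
  f <- estimate_force(dx, k = 9, block_count = 20)
  expect_lt(abs(f$F - 9 * 0.02), 4 * f$stderr_F)
  expect_lt(abs(f$stderr_F - 9 * 0.07 / sqrt(n)), 0.3 * 9 * 0.07 / sqrt(n))
})

test_that("PMF integration is exact trapezoid quadrature, zero at x_ref", {
  u <- 1e-19 / (1.380649e-23 * 298.15)  # nN*A in kBT
  # zero force, zero PMF
  z <- integrate_pmf(data.frame(x = seq(22, 40, 2), F_nN = 0, F_err = 0))
  expect_true(all(z$dG == 0))
  # constant attractive force c: dG(22) = c * 18 (unit-converted)
  cst <- integrate_pmf(data.frame(x = seq(22, 40, 2), F_nN = -0.05,
                                  F_err = 0))
  expect_equal(cst$dG[1], -0.05 * 18 * u, tolerance = 1e-12)
  expect_identical(cst$dG[nrow(cst)], 0)
  # linear force: trapezoid equals the analytic integral exactly
  xs <- seq(22, 40, 3)
  a <- -0.01; b <- 0.37
  lin <- integrate_pmf(data.frame(x = xs, F_nN = a * xs + b, F_err = 0))
  exact <- function(x) (a / 2 * (40^2 - x^2) + b * (40 - x)) * u
  expect_equal(lin$dG, exact(xs), tolerance = 1e-12)
  # contract violations
  expect_error(integrate_pmf(data.frame(x = c(22, 22, 40), F_nN = 0)),
               "sorted")
  expect_error(integrate_pmf(data.frame(x = c(22, 30), F_nN = 0)), "x_ref")
  # error propagation: single interval, quadrature sum of weights
  e <- integrate_pmf(data.frame(x = c(22, 40), F_nN = c(-1, -1),
                                F_err = c(0.1, 0.2)))
  expect_equal(e$dG_err[1], 9 * u * sqrt(0.1^2 + 0.2^2), tolerance = 1e-12)
})

test_that("convergence report flags drifting chains and passes stationary ones", {
  set.seed(2)
  expect_true(convergence_report(stats::rnorm(20000, 30, 0.07))$converged)
  expect_false(convergence_report(30 + seq(0, 0.5, length.out = 20000) +
                                  stats::rnorm(20000, 0, 0.02))$converged)
})

test_that("chains are deterministic under a fixed seed", {
  spec <- system_spec(6, 1, 0.1, x = 24)
  cfg <- build_system(spec, seed = 5)
  p <- mc_params(n_equil = 300, n_prod = 800, frame_stride = 100)
  c1 <- run_chain(cfg, spec, p, seed = 99)
  c2 <- run_chain(cfg, spec, p, seed = 99)
  c3 <- run_chain(cfg, spec, p, seed = 100)
  expect_identical(c1$dx, c2$dx)
  expect_identical(c1$frames, c2$frames)
  expect_false(identical(c1$dx, c3$dx))
})

test_that("spring-only system samples the equipartition extension", {
  # two neutral tethered spheres: dx ~ N(0, kBT/k), sd = 0.0676 A at
  # k = 9 nN/A and T = 298.15 K
  fx <- make_fixture("spring_only")
  ch <- run_chain(fx$cfg, fx$spec, mc_params(n_equil = 4000, n_prod = 120000,
                                             np_attempts = 4,
                                             frame_stride = 0),
                  seed = 21, store_frames = FALSE)
  expect_equal(stats::sd(ch$dx), fx$expected$dx_sd, tolerance = 0.05)
  expect_lt(abs(mean(ch$dx)),
            4 * stats::sd(ch$dx) / sqrt(length(ch$dx) / 20))
})

test_that("uncharged ions sample the cell uniformly", {
  fx <- make_fixture("ideal_gas")
  ch <- run_chain(fx$cfg, NULL, mc_params(n_equil = 2000, n_prod = 20000,
                                          frame_stride = 10),
                  seed = 31, mobile = FALSE)
  ic <- 1 + seq_len(ch$n_ion)  # single fixed sphere, then ions
  xs <- as.vector(ch$frames[, 3 * (ic - 1) + 1])
  # mean of a uniform on [0, 40]; allow 4 sigma with a crude n_eff
  n_eff <- length(xs) / 20
  expect_lt(abs(mean(xs) - 20), 4 * (40 / sqrt(12)) / sqrt(n_eff))
  # occupancy of the two halves of the cell balances
  frac <- mean(xs < 20)
  expect_lt(abs(frac - 0.5), 4 * 0.5 / sqrt(n_eff))
})

test_that("one-ion radial density follows the Boltzmann factor", {
  # single cation around a fixed nanoparticle: compare binned radial
  # occupancy against dense deterministic quadrature of exp(-U(r)) over the
  # accessible cell volume
  fx <- make_fixture("one_ion")
  cfg <- fx$cfg
  ch <- run_chain(cfg, NULL, mc_params(n_equil = 5000, n_prod = 150000,
                                       ion_step = 6, frame_stride = 5),
                  seed = 41, mobile = FALSE)
  ir <- sqrt(rowSums(sweep(ch$frames[, 4:6, drop = FALSE], 2,
                           cfg$pos[1, ])^2))
  edges <- c(12, 14, 16, 19, 23)
  counts <- table(cut(ir, edges))
  # quadrature oracle on a 0.5 A grid of the box
  gx <- seq(2.25, cfg$cell[1] - 2.25, by = 0.5)
  w <- expand.grid(x = gx, y = gx, z = gx)
  r <- sqrt((w$x - cfg$pos[1, 1])^2 + (w$y - cfg$pos[1, 2])^2 +
            (w$z - cfg$pos[1, 3])^2)
  boltz <- ifelse(r >= 12, exp(-cfg$charge[1] * cfg$charge[2] *
                               cfg$lB / r), 0)
  probs <- sapply(seq_len(length(edges) - 1), function(b)
    sum(boltz[r >= edges[b] & r < edges[b + 1]]))
  inside <- r >= edges[1] & r < edges[length(edges)]
  probs <- probs / sum(boltz[inside])
  obs <- as.numeric(counts) / sum(counts)
  n_eff <- sum(counts) / 30  # generous autocorrelation allowance
  for (b in seq_along(probs)) {
    se <- sqrt(probs[b] * (1 - probs[b]) / n_eff)
    expect_lt(abs(obs[b] - probs[b]), 5 * se + 0.01)
  }
})

test_that("weak-coupling MC force is consistent with screened-Coulomb theory", {
  # |Z| = 1 at 0.05 M 1:1: the spring force must agree with the derivative
  # of the Debye-Hueckel pair potential within model tolerance (20%) plus
  # statistical error
  Z <- 1; z <- 1; c0 <- 0.05; x <- 24
  spec <- system_spec(Z, z, c0, x = x)
  cfg <- build_system(spec, seed = 51)
  ch <- run_chain(cfg, spec, mc_params(n_equil = 10000, n_prod = 60000,
                                       np_attempts = 8, frame_stride = 0),
                  seed = 52, store_frames = FALSE)
  fs <- estimate_force(ch$dx, x = x)
  kappa <- 1 / spec$debye
  lB <- spec$lB
  # F(x) = -dU/dx of the screened pair energy (attraction negative),
  # converted from kBT/A to nN
  eps_h <- 1e-4
  dU <- (dlvo_energy(x + eps_h, Z, kappa, lB) -
         dlvo_energy(x - eps_h, Z, kappa, lB)) / (2 * eps_h)
  u <- 1e-19 / (1.380649e-23 * spec$temperature)  # kBT per nN*A
  f_theory <- -dU / u
  expect_lt(abs(fs$F - f_theory), 0.2 * abs(f_theory) + 3 * fs$stderr_F)
})
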