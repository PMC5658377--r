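make_profile_spec <- function() system_spec(6, 2, 0.02, x = 24)

test_that("MC net charge fraction reproduces a hand count on frozen frames", {
  spec <- make_profile_spec()
  # one frozen frame: nanoparticles at (+/-12, 0, 0) + box centre; ions
  # placed by hand around the +Z particle (charge +6 at low x)
  ctr <- spec$box / 2
  np1 <- ctr + c(-12, 0, 0); np2 <- ctr + c(12, 0, 0)
  ions <- rbind(np1 + c(-13, 0, 0),   # anion, r = 13, positive side
                np1 + c(0, 15, 0),    # anion, r = 15, positive side
                np1 + c(0, 0, 30),    # cation, r = 30, positive side
                np2 + c(13, 0, 0),    # cation, r = 13, negative side
                np2 + c(0, -16, 0))   # cation, r = 16, negative side
  frames <- matrix(c(np1, np2, t(ions)), nrow = 1)
  charge <- c(6, -6, -2, -2, 2, 2, 2)
  kind <- c("nanoparticle", "nanoparticle", "anion", "anion", "cation",
            "cation", "cation")
  ch <- manual_chain(frames, charge, kind, spec)
  q <- net_charge_fraction_mc(ch, r_bins = c(11, 14, 17, 31), block_count = 1)
  # hand counts: around +6 within 14: one -2 anion -> -(-2)/6 = 1/3
  # around -6 within 14: one +2 cation -> +2/6 = 1/3 -> average 1/3
  expect_equal(q$Q[q$r == 11], 0)             # inside the contact distance
  expect_equal(q$Q[q$r == 14], 1 / 3)
  # within 17: (-4)/6 and (+4)/-6... both sides 2 bound ions -> 2/3
  expect_equal(q$Q[q$r == 17], 2 / 3)
  # within 31 the cation near +Z enters with opposite sign: (,-4+2)/6 -> 1/3
  # on the positive side; negative side still 2/3 -> average 1/2
  expect_equal(q$Q[q$r == 31], 1 / 2)
  # no ions at all -> identically zero
  ch0 <- manual_chain(matrix(c(np1, np2), nrow = 1), charge[1:2], kind[1:2],
                      spec)
  q0 <- net_charge_fraction_mc(ch0, r_bins = c(11, 14))
  expect_true(all(q0$Q == 0))
})

test_that("PB charge fraction is zero for a vanishing field", {
  spec <- make_profile_spec()
  sch <- focusing_schedule(spec, levels = list(list(L = c(64, 48, 48),
                                                    h = 2)))
  sol <- focusing_solve(spec, sch)
  # overwrite with the zero field: cations and anions cancel exactly
  sol$levels[[1]]$psi[] <- 0
  q <- net_charge_fraction_pb(sol, r_bins = c(5, 14, 20))
  expect_true(all(q$Q == 0))
})

test_that("relative PMF deviation follows its definition", {
  expect_equal(delta_delta_g(-10, -10), 0)
  expect_equal(delta_delta_g(-10, -12), 0.2)
  expect_equal(delta_delta_g(-10, -8), 0.2)
  expect_error(delta_delta_g(0, -5), "zero")
})

test_that("apparent parameter is |Z| times the profile gap at 14 A", {
  mk <- function(q14) {
    p <- data.frame(r = c(12, 14, 16), Q = c(0, q14, q14 + 0.1), Q_err = 0)
    structure(p, class = c("ion_charge_profile", "data.frame"), Z = 12,
              method = "MC")
  }
  expect_equal(apparent_parameter(mk(0.3), mk(0.3)), 0)
  expect_equal(apparent_parameter(mk(0.4), mk(0.3), Z = 12), 1.2)
  bad <- mk(0.3); bad$r <- c(12, 15, 16)
  expect_error(apparent_parameter(bad, mk(0.3)), "14")
})

test_that("equivalent-salt interpolation is exact, monotone and bounded", {
  # exactly linear in log10(c0): interpolation recovers any target exactly
  lad <- data.frame(c0 = c(0.001, 0.01, 0.1, 0.3),
                    value = -10 + 4 * log10(c(0.001, 0.01, 0.1, 0.3)))
  expect_equal(equivalent_salt(lad, lad$value[2]), 0.01, tolerance = 1e-12)
  tgt <- -10 + 4 * log10(0.037)
  expect_equal(equivalent_salt(lad, tgt), 0.037, tolerance = 1e-9)
  # monotone in the target
  t1 <- equivalent_salt(lad, -16); t2 <- equivalent_salt(lad, -14)
  expect_true(t2 > t1)
  # refusal outside the covered range
  expect_error(equivalent_salt(lad, -30), "extrapolate")
  # non-monotone ladders are rejected
  bad <- lad; bad$value[2] <- -25
  expect_error(equivalent_salt(bad, -16), "monotone")
})

test_that("charge-density landscapes behave on trivial and symmetric input", {
  spec <- make_profile_spec()
  ctr <- spec$box / 2
  np1 <- ctr + c(-12, 0, 0); np2 <- ctr + c(12, 0, 0)
  # zero-charge system -> zero map
  frames <- matrix(c(np1, np2, np1 + c(0, 20, 0), np2 + c(0, -20, 0)),
                   nrow = 1)
  ch0 <- manual_chain(frames, c(0, 0, 0, 0),
                      c("nanoparticle", "nanoparticle", "cation", "anion"),
                      spec)
  m0 <- charge_density_landscape(ch0, plane_resolution = 2)
  expect_true(all(m0$density == 0))
  # bookkeeping: total binned charge equals the placed ion charges
  ch1 <- manual_chain(frames, c(6, -6, -2, 2),
                      c("nanoparticle", "nanoparticle", "anion", "cation"),
                      spec)
  m1 <- charge_density_landscape(ch1, plane_resolution = 2)
  du <- 2
  vols <- pi * ((m1$rho + 1)^2 - (m1$rho - 1)^2) * du
  expect_equal(sum(m1$density * vols), 0, tolerance = 1e-9)  # -2 + 2
  neg_side <- m1$u < 0
  expect_equal(sum((m1$density * vols)[neg_side]), -2, tolerance = 1e-9)
  # PB landscape: antisymmetric under u -> -u (charge conjugation mirror)
  sch <- focusing_schedule(spec, tol = 1e-7,
                           levels = list(list(L = c(64, 48, 48), h = 2)))
  sol <- focusing_solve(spec, sch)
  # bin edges at odd coordinates so the (even) node abscissae fall on bin
  # centres symmetrically
  mp <- charge_density_landscape(sol, plane_resolution = 2, u_max = 23,
                                 rho_max = 20)
  a <- mp[order(mp$u, mp$rho), ]
  b <- mp[order(-mp$u, mp$rho), ]
  expect_lt(max(abs(a$density + b$density)), 1e-4 * max(abs(mp$density)))
})
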