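# Independent oracles used across the suite.  These deliberately re-derive
# quantities by the dumbest correct route (double loops, closed forms,
# dense quadrature) so they share no code with the implementation paths
# they check.

# brute-force total energy: explicit double loop over pairs
brute_force_energy <- function(pos, radius, charge, lB) {
  n <- nrow(pos)
  u <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r < radius[i] + radius[j]) return(Inf)
    u <- u + charge[i] * charge[j] * lB / r
  }
  u
}

# closed-form trilinear weights of a fractional offset inside a unit cell
trilinear_weights <- function(f) {
  w <- numeric(8)
  k <- 1
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w[k] <- (if (cx) f[1] else 1 - f[1]) *
            (if (cy) f[2] else 1 - f[2]) *
            (if (cz) f[3] else 1 - f[3])
    k <- k + 1
  }
  w
}

# analytic net-charge fraction of a linearized (Debye-Hueckel) sphere with
# ion-exclusion radius R: Q(r) = [ (1+kR) - (1+kr) e^{-k(r-R)} ] / (1+kR)
dh_charge_fraction <- function(r, kappa, R = 12) {
  ((1 + kappa * R) - (1 + kappa * r) * exp(-kappa * (r - R))) /
    (1 + kappa * R)
}

# screened-pair (DLVO-type) interaction of two spheres with exclusion
# radius R, in kBT
dlvo_energy <- function(x, Z, kappa, lB, R = 12) {
  -Z^2 * lB * exp(-kappa * (x - 2 * R)) / (x * (1 + kappa * R)^2)
}

# build a small hand-rolled ion_config without build_system
manual_config <- function(pos, radius, charge, kind, cell, spec = NULL) {
  cfg <- structure(list(pos = pos, radius = radius, charge = charge,
                        kind = kind, cell = cell,
                        n_pairs = sum(charge > 0 & kind != "nanoparticle"),
                        lB = bjerrum_length(), spec = spec),
                   class = "ion_config")
  cfg$energy <- total_energy(cfg)
  cfg
}

# hand-rolled mc_chain wrapper around fixed frames, for observable oracles
manual_chain <- function(frames, charge, kind, spec, cell = spec$box) {
  structure(list(dx = numeric(0), frames = frames,
                 n_ion = length(charge) - 2, charge = charge, kind = kind,
                 cell = cell, spec = spec, mobile = TRUE,
                 diagnostics = list()),
            class = "mc_chain")
}
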