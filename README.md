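# ionpmf

Ion-mediated potentials of mean force between oppositely charged
nanospheres, computed two ways — explicit-ion Monte Carlo and nonlinear
Poisson–Boltzmann theory — with the statistics that quantify where the
mean-field picture breaks down.

## The problem

Two nanospheres of radius 10 Å carrying charges +Ze and −Ze in a symmetric
z:z electrolyte (implicit water, ε = 78) attract each other through a
salt-screened effective interaction.  The central quantity is the potential
of mean force

ΔG(x) = G(x) − G(x_ref),  x_ref = 40 Å,

as a function of the centre-to-centre separation x ∈ [22, 40] Å.  The
package computes ΔG(x) by:

* **Metropolis Monte Carlo of the primitive model** (ions as charged hard
  spheres of radius 2 Å) with the *pseudo-spring* estimator: a stiff tether
  (k = 9 nN/Å) links the particles, the mean spring extension measures the
  mean force F(x) = k⟨Δx⟩, and ΔG(x) = ∫ₓ^40 F dx′;
* **the nonlinear Poisson–Boltzmann (PB) equation**, solved by finite
  differences with three-level grid focusing and an ion-exclusion layer,
  and the free-energy functional
  G = ½∫Σᵢcᵢzᵢe(ψ+ψ_f) d³r + k_BT∫Σᵢ[cᵢ ln(cᵢ/cᵢ⁰) − cᵢ + cᵢ⁰] d³r + U_N−N.

Because the mean-field route ignores ion–ion correlations it underestimates
divalent counterion binding and *overestimates* the attraction in 2:2 salt.
The deviation statistics are

ΔΔg = |(ΔG_MC(22 Å) − ΔG_PB(22 Å)) / ΔG_MC(22 Å)|,
|Z|ΔQ\* = |Z| · |Q_MC(14 Å) − Q_PB(14 Å)|,

with Q(r) the net bound-ion charge fraction within r of a particle centre
(half-space restricted).  ΔΔg tracks |Z|ΔQ\* tightly across all salt
conditions: the bound-ion deficit is the proximate cause of the mean-field
PMF error.

## Worked example

A single strongly coupled state point, |Z| = 12e in 10 mM 2:2 salt, at
reduced sampling (a few minutes):

```r
library(ionpmf)
cmp <- compare_methods(Z = 12, z = 2, c0 = 0.01,
                       x_values = seq(22, 40, by = 3),
                       params = mc_params(n_equil = 2e4, n_prod = 1.5e5),
                       seed = 1, pb_final_h = 1.0,
                       schedule = function(s) reduced_schedule(s, 1.0))
cmp$report
```

```
comparison_report at x0 = 22 A (|Z| = 12e):
  dG_MC = -7.895 kBT, dG_PB = -8.518 kBT
  ddg = 0.079 (7.9%), dQ* = 0.073, |Z| dQ* = 0.881
```

Read: at this state point the explicit-ion PMF at contact-range separation
is −7.9 k_BT while mean-field theory gives −8.5 k_BT — it overestimates
the attraction by ~8 % at this sampling — and it under-counts the bound
divalent charge by ~0.07 of the nanoparticle charge (Q_MC(14 Å) ≈ 0.27 vs
Q_PB(14 Å) ≈ 0.20).  `plot(cmp)` overlays the two PMF curves;
`cmp$profile_mc` and `cmp$profile_pb` hold the Q(r) profiles.

Sweeps over (Z, z, c0) with resumable on-disk artifacts run through a YAML
configuration:

```r
cfg <- load_config(system.file("extdata", "example-config.yaml",
                               package = "ionpmf"))
run_comparison(cfg)
```

A thin CLI wrapping the same functions lives at `inst/cli/ionpmf.R`
(verbs: `simulate`, `solve`, `compare`, `fixtures`, `plot`).

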