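---
title: "Methods: explicit-ion and mean-field potentials of mean force between charged nanospheres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explicit-ion and mean-field potentials of mean force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ionpmf)
```

## The physical problem

Two rigid spheres of radius $a = 10$ Å carrying opposite net charges $+Z e$
and $-Z e$ sit at centre-to-centre separation $x$ in a symmetric $z\!:\!z$
electrolyte (monovalent or divalent, bulk concentration $c_0$).  The solvent
is an implicit uniform dielectric, $\varepsilon = 78$.  The quantity of
interest is the potential of mean force (PMF)

$$\Delta G(x) = G(x) - G(x_\mathrm{ref}), \qquad x_\mathrm{ref} = 40\ \text{Å},$$

the salt-averaged free energy of bringing the pair from the reference
separation to $x$.  `ionpmf` computes $\Delta G(x)$ by two independent
routes and quantifies their disagreement:

* **explicit ions** — canonical Metropolis Monte Carlo of the primitive
  model (ions are charged hard spheres of radius 2 Å), with the mean force
  read from a stiff harmonic tether;
* **mean field** — the nonlinear Poisson–Boltzmann (PB) equation solved by
  finite differences with multi-level grid focusing, and the electrostatic
  free energy of the converged field.

The mean-field route neglects ion–ion correlations.  For monovalent salt
this matters little; for divalent salt the correlations drive extra
counterion binding that mean-field theory misses, so PB systematically
*overestimates* the attraction.  The package's comparison statistics
(`delta_delta_g()`, `apparent_parameter()`) measure exactly this failure.

## Units and the single conversion point

All internal lengths are in Å, energies in $k_BT$, charges in units of $e$.
The only place SI constants enter is the Bjerrum length

$$\ell_B = \frac{e^2}{4\pi\varepsilon_0\varepsilon k_B T} \approx 7.19\ \text{Å}
\quad (\varepsilon = 78,\ T = 298.15\ \text{K}),$$

so every Coulomb energy is $q_i q_j \ell_B / r_{ij}$ in $k_BT$
(`bjerrum_length()`).  Temperature is not otherwise part
of the model definition; room temperature ($T = 298.15$ K, consistent with
$\varepsilon = 78$ water) is the package default and is exposed in
`system_spec()`.

## The explicit-ion route

### Sampling

`build_system()` places the nanoparticles at $(\mp x/2, 0, 0)$ relative to
the cell centre and inserts $N = \mathrm{round}(c_0 N_A V_\mathrm{acc})$
neutral cation/anion pairs uniformly at random without overlaps
($V_\mathrm{acc}$ excludes the wall layer and the two contact-exclusion
spheres).  The cell is closed (hard walls, no periodic images); Coulomb
sums are direct.  `run_chain()` performs Metropolis sweeps: one attempted
displacement per ion plus several attempted x-axis displacements of the
tethered nanoparticle, acceptance $\min(1, e^{-\beta\Delta U})$ with
$\Delta U$ including all pair terms and the spring energy.  Step sizes are
tuned toward ~40 % acceptance during equilibration only, then frozen, so
the production chain satisfies detailed balance exactly.  Moves that would
place any part of a sphere outside the cell are rejected.

### The pseudo-spring force estimator

One nanoparticle is frozen; the other moves along the axis under a
harmonic tether of stiffness $k = 9$ nN/Å with rest length $x$.  At
equilibrium the mean spring extension measures the mean inter-particle
force, $F(x) = k\langle\Delta x\rangle$ (`estimate_force()`).  Sign
convention: attraction pulls the mobile particle inward, compresses the
spring, and gives $\Delta x < 0$, hence $F < 0$; the PMF
$\Delta G(x) = \int_x^{x_\mathrm{ref}} F(x')\,dx'$ (`integrate_pmf()`,
trapezoid with propagated block errors) is then negative for attraction.
The bare thermal width of the extension is
$\sqrt{k_BT/k} \approx 0.068$ Å; statistical errors come from block
averaging (20 blocks by default), which the suite checks against
independent replicas.

### Finite-size policy (measured, not assumed)

The classic cell rule — sides at least $x + 6\lambda_D$ — controls the
*electrostatic* boundary effect, but two further finite-size effects were
measured to matter during development, both assessed by scanning the cell
size at fixed $(Z, z, c_0, x)$ until the spring force and the bound-ion
charge fraction plateau:

1. at high salt ($\lambda_D \lesssim 6$ Å) the rule leaves the wall only a
   couple of screening lengths from the particle *surface*, squeezing the
   double layer;
2. for divalent salt the condensed layers hold about $Z/z$ ion pairs per
   particle, and a cell sized by the minimal rule may simply not contain
   enough ions to feed them (canonical depletion).

The default cell is therefore rectangular:
$L_x = \max(x + 6\lambda_D,\ x + 2a + 2m)$ and
$L_{y,z} = \max(x + 6\lambda_D,\ 2a + 2m)$ with wall clearance
$m = \max(3\lambda_D, 25\ \text{Å})$, expanded isotropically for $z = 2$
until the cell holds at least $6Z/z$ ion pairs.  The minimal-rule floor is
always respected; an explicit `box` overrides the default.  A chunk
reproducing the finite-size scan:

```{r finite-size-scan}
probe <- function(scale, Z = 24, z = 2, c0 = 0.01) {
  spec0 <- system_spec(Z, z, c0, x = 22)
  spec <- system_spec(Z, z, c0, x = 22, box = spec0$box * scale)
  cfg <- build_system(spec, seed = 1)
  ch <- run_chain(cfg, spec, mc_params(n_equil = 4e4, n_prod = 1.5e5),
                  seed = 2)
  c(F = estimate_force(ch$dx, x = 22)$F,
    Q14 = profile_at(net_charge_fraction_mc(ch), 14))
}
sapply(c(1, 1.5, 2, 2.5), probe)
```

Residual depletion is still present by construction (the method is
canonical while PB is effectively grand canonical); with the default cells
it is held to the level where the plateau is reached within the
statistical resolution of the comparison.

### What limits precision

At strong coupling ($|Z| = 24e$ in divalent salt) the slow mode is the
rearrangement of the ~$Z/z$ condensed divalents; the spring force
decorrelates over tens of sweeps, and independent replicas are the
reliable error estimate.  The acceptance script pools three replicas per
window for that system.

## The mean-field route

### Discretization and solver

In reduced units ($\phi = e\psi/k_BT$) the PB equation for a symmetric
salt reads

$$\nabla^2\phi = -4\pi\ell_B\left[\rho_f/e - 2 z c_0 \sinh(z\phi)\,
\chi_\mathrm{acc}(\mathbf r)\right],$$

with $\rho_f$ the nanoparticle charge density and $\chi_\mathrm{acc}$ the
ion-accessibility indicator: a thin layer of one ion radius is added to
each nanoparticle surface, so nodes within $a + 2 = 12$ Å of either centre
carry no mobile-ion term (`build_accessibility()`).  Each nanoparticle is
a central point charge partitioned trilinearly onto its eight surrounding
nodes, conserving charge to machine precision (`map_fixed_charges()`).

The 7-point stencil system is relaxed by Gauss–Seidel–Newton sweeps: one
clamped Newton step per node per sweep, over-relaxed with
$\omega = \min(1.9,\ 2/(1 + \sin(\pi/n_\mathrm{max})))$.  The
$\sinh$/$\cosh$ pair is evaluated through a guarded exponential (series
path below $|z\phi| < 0.05$, argument clamped at $\pm 300$), and each
Newton step is limited to 5 $k_BT/e$, which keeps the iteration stable
from rough initial guesses even at $|Z| = 24e$.  Iteration stops when the
largest node change in a sweep falls below $10^{-4}\,k_BT/e$ (tighter
values are used where a test needs them).  Divergence triggers automatic restarts at
smaller $\omega$, then an error carrying the residual history.

### Focusing

`focusing_schedule()` defaults to three levels: a cubic outer level sized
so its faces are at least $6\lambda_D$ from the particle surfaces
(resolution adapted to the box, at most ~96 cells per side), a
(160, 120, 120) Å level at 1.0 Å, and a (100, 60, 60) Å final level.  The
outer level takes the analytic Debye–Hückel superposition (exclusion
radius $R = 12$ Å) as boundary condition and initial guess; each finer
level interpolates boundary values and initial interior values
trilinearly from its parent.  The level-1 box is sized once for
$x_\mathrm{ref}$ and reused for every separation so that all grids are
geometrically identical across $x$ and lattice artefacts cancel in PMF
differences; separations and the final spacing are chosen so the particle
centres sit exactly on grid nodes.

The final-level resolution is a cost/accuracy dial: the package default is
0.5 Å, with 0.25 Å available at about eight times the cost on the same box.  The refinement
behaviour is part of the test suite; see below.

### Free energy

`pb_free_energy()` evaluates

$$G_\mathrm{PB}(x) = \tfrac12\int\!\sum_i c_i z_i e\,(\psi + \psi_f)\,d^3r
 + k_BT\int\!\sum_i\left[c_i\ln\frac{c_i}{c_i^0} - c_i + c_i^0\right]d^3r
 + U_{N\!-\!N},$$

with $c_i = c_i^0 e^{-z_i\phi}$ on accessible nodes and zero on excluded
nodes, and $U_{N\!-\!N} = -Z^2\ell_B/x$ analytic.  The reference field
$\psi_f$ (same operator, ion term zeroed, analytic Coulomb boundary) is
solved on the final level, where it meets $\psi$ inside the near-field
integrand and lattice self-energy effects must cancel self-consistently;
the coarser levels enter only through far-field complement integrals
(region outside the child box), where the analytic Coulomb superposition
equals the discrete solution to $O(h^2)$ and is used directly.  Node
quadrature uses trapezoidal face weights; every coarser level adds its
complement region, so the integral effectively extends over the level-1
box.  $\Delta G_\mathrm{PB}(x) = G_\mathrm{PB}(x) -
G_\mathrm{PB}(x_\mathrm{ref})$ is exactly zero at the reference
separation by construction.

### Grid convergence and the exclusion staircase

The binary ion-exclusion layer is a staircase on the lattice.  Its
free-energy contribution fluctuates with $h$ rather than shrinking
smoothly, so a clean Richardson exponent for $\Delta G_\mathrm{PB}$ is not
observable at practical resolutions; what holds — and what the suite
asserts — is that $\Delta G_\mathrm{PB}$ is already grid-insensitive (below
the 1 % level on node-aligned lattices at $h = 2/1/0.5$ Å) compared with
every tolerance used in the comparison.  A smoothed, volume-fraction
exclusion would restore textbook convergence rates but would change the sharp-layer
model itself, so the binary mask is kept.

## Comparison observables

* **Net ion charge fraction** $Q(r) = -\frac{1}{Z}\int_{<r}\sum_i z_i
  c_i(\mathbf r)\,d^3\mathbf r$, accumulated within the half-space of each
  nanoparticle (the bisector plane splits the cell; ties on the plane get
  half weight in the PB integral and are decided by the sign of the ion's
  axial coordinate in MC, a zero-measure choice).  The two conjugate
  profiles are averaged.  Bin width 0.5 Å.  `net_charge_fraction_mc()`
  evaluates it over stored frames with block errors;
  `net_charge_fraction_pb()` integrates the Boltzmann densities on the
  final grid.
* **Relative PMF deviation** $\Delta\Delta g = |(\Delta G_\mathrm{MC} -
  \Delta G_\mathrm{PB})/\Delta G_\mathrm{MC}|$ at $x_0 = 22$ Å, where the
  deviation peaks.
* **Apparent coupling parameter** $|Z|\Delta Q^\ast$: $|Z|$ times the
  profile gap at $r = 14$ Å.  Across salt conditions and charge densities
  the deviation statistic rises monotonically with this single number —
  the bound-ion deficit of the mean-field description is the proximate
  cause of its PMF error.
* **Equivalent 1:1 concentration**: the 1:1 concentration whose
  $\Delta G(22\ \text{Å})$ (or $Q(22\ \text{Å})$) matches a 2:2 state
  point, by piecewise-linear interpolation in $(\log_{10} c_0,
  \Delta G)$; extrapolation outside the computed ladder is refused.
* **Charge-density landscapes**: net ion charge density on the plane
  through both centres, cylindrically averaged about the axis for MC
  (variance reduction), the PB field binned onto the same raster, and
  their difference map.

## What the generator emulates — and what it does not

`build_system()`/`system_spec()` define the study conditions: radii 10/2 Å, $\varepsilon = 78$ with no dielectric
discontinuity at the particle surface, charges $\pm Z$ with
$Z \in \{6, 9, 12, 18, 24\}$, symmetric 1:1 or 2:2 salt, spring constant
9 nN/Å, $x \in [22, 40]$ Å.  They do *not* model: dielectric images or
solvent granularity, ion polarizability, asymmetric salts, charge
regulation of the surface charge, or separations much beyond the particle
size.  Passing tests therefore validate the computational apparatus and
the mean-field/explicit-ion comparison on this idealized system — not
quantitative agreement with any particular experimental colloid.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes an explicit integer seed through R's
  RNG; identical (configuration, parameters, seed) reproduce trajectories
  bit for bit.
* Overlapping spheres yield the `+Inf` energy sentinel, never a division
  by zero; chains refuse to start from overlapping configurations.
* `equivalent_salt()` requires a strictly monotone ladder and refuses to
  extrapolate.
* PB solves refuse non-finite fields, restart at lower relaxation on
  divergence, and validate that each focusing level lies inside its
  parent and that the final level contains both particles plus exclusion
  layers.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` are
  reduced relative to publication-grade sampling: MC force grids of 7–10
  windows with $10^5$–$2\times10^5$ production sweeps per window (three
  pooled replicas for the strongest-coupling system), and PB final-level
  spacings of 0.5 Å (acceptance) or 1.0 Å (fast checks).  The comparison
  tolerances in the tests are set for that sampling; the same pipelines
  run at larger sizes simply by changing `mc_params()` and
  `focusing_schedule()`.

## Known limitations

* The canonical cell depletes the reservoir when many ions condense; the
  default cells bound this effect (see the finite-size policy) but do not
  eliminate it.
* The spring estimator's variance at strong coupling is dominated by slow
  condensed-ion rearrangements; error bars there rely on replica pooling,
  and publication-grade precision requires proportionally longer chains.
* The sharp exclusion layer limits the observable PB grid-convergence
  order (see above).
* Direct Coulomb sums make sweep cost quadratic in particle number; the
  intended regime (a few hundred ions) is comfortable, dense 1 M-scale
  boxes are the practical ceiling.
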