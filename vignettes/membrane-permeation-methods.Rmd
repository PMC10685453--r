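---
title: "Methods: permeation free energies, protomer coupling and permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permeation free energies, protomer coupling and permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

# The problem

A drug-like permeant crossing a lipid bilayer samples three environments —
bulk water, the headgroup/water interface, and the hydrophobic core — and
its permeability is controlled by the free energy surface (FES) along the
membrane normal and by the local diffusivity. For an ionizable molecule the
picture is protonation-dependent: the charged form dominates in water but
is strongly destabilized in the core, so permeation proceeds through the
neutral form, with protonation switching near the interface.

`memperm` implements the full analysis chain for this problem:

1. adaptive biasing (well-tempered metadynamics) along one or two
   collective variables (CVs),
2. FES reconstruction by reweighting, with block errors, symmetrization
   and an asymmetry diagnostic,
3. minimum free energy paths (MFEP) on 2D surfaces by the string method,
4. thermodynamic coupling of protomer surfaces through the aqueous
   acid-base equilibrium,
5. position-dependent diffusion estimation and the inhomogeneous
   solubility-diffusion (ISD) permeability.

Because microsecond atomistic trajectories cannot be regenerated at desk
scale, the package ships a synthetic-data module: analytic membrane-shaped
landscapes sampled by overdamped Langevin dynamics. Every estimator is
exercised, end to end, on data whose ground truth is known exactly.

Units are fixed package-wide: Angstrom, picosecond, kJ/mol, kelvin
(`kT = 0.0083144621 * T`), matching PLUMED conventions; permeabilities are
reported in cm/s (1 A/ps = 1e4 cm/s).

# Synthetic landscapes and dynamics

## Functional form

A landscape is a sum of one-dimensional Gaussian ridges/wells along unit
directions in CV space, plus an optional linear tilt and harmonic
restraints. Gaussians (rather than polynomials) keep every feature local,
give exact analytic gradients, and reproduce the topography permeation
surfaces actually show: two interfacial minima at `+-z_min`, a central core
barrier, and flat bulk plateaus. The two amplitudes are solved from a 2x2
linear system so that, despite feature overlap, the constructed values are
exact: `F(z_min) - F(bulk) = -interfacial_min_depth` and
`F(0) - F(z_min) = +core_barrier_height`.

The headline parameterization mimics a neutral chloroquine-like permeant:
interfacial wells 40 kJ/mol deep, an 11 kJ/mol rise to the core (a ~10
kJ/mol translocation barrier), minima near 10-12 A. In 2D the axes are the
membrane-normal distances of the ring and tail moieties; each axis carries
half-amplitude copies of the 1D features (so the diagonal is exact), and a
bounded coupling term `c * (1 - exp(-(a-b)^2 / 2w^2))` penalizes ring-tail
separation — the two moieties belong to one molecule. The coupling is
bounded rather than quadratic so that biased dynamics can still explore
off-diagonal configurations without the landscape growing without limit.

A charged protomer's landscape is the neutral one plus a core-localized
Gaussian penalty (default 64 kJ/mol at the centre, width 7.4 A, acting
along the tail axis in 2D, since the protonatable amine sits on the tail).
The penalty vanishes in bulk by construction, where the two protomers must
coincide up to the acid-base term.

## Dynamics

`simulate_overdamped()` integrates Euler-Maruyama Brownian dynamics in the
Ito convention,

```
dz = (-beta D(z) dF/dz + dD/dz) dt + sqrt(2 D(z) dt) dW,
```

with reflective boundaries at `|z| = z_max`. The explicit `dD/dz`
spurious-drift term is required for position-dependent diffusivity: without
it a flat landscape would not stay uniform. This is checked by a
Kolmogorov-Smirnov test on decorrelated samples. Default diffusivity is
0.5 A^2/ps, a realistic scale for a drug-sized solute in water/lipid; the
smooth profile variant interpolates between bulk and core values with a
Gaussian transition.

A pre-flight check warns when `dt * D * max|grad F| * beta` approaches the
smallest feature width, and any single step larger than ten feature widths
aborts with the step index. All randomness flows through R's RNG, so a
seed makes every run bit-reproducible.

# Well-tempered metadynamics and c(t)

Kernels of initial height `w0 = 1.2` kJ/mol and width `sigma = 0.5` A are
deposited every 2 ps by default, with heights tempered as
`w = w0 exp(-V(s,t) / ((gamma-1) kT))`; `gamma` defaults to 20 for a
neutral permeant and 25 for a charged one, where the barrier is higher.
The bias and its gradient are accumulated on a uniform grid (default
spacing 0.01 A; coarser grids are a config knob and are used in the test
suite for speed) and the force on the walker is the bilinearly
interpolated gradient of that grid. For grid accumulation during a run,
kernels are truncated at 6 sigma (relative error below 1e-7); the post-hoc
`evaluate_bias()` defaults to the exact untruncated sum, which is what the
brute-force oracle in the tests compares against at 1e-10.

After every deposition the reweighting factor

```
c(t) = (1/beta) ln [ Int e^{(gamma/(gamma-1)) beta V} ds /
                     Int e^{(1/(gamma-1)) beta V} ds ]
```

is recomputed from the current grid by trapezoid quadrature (edge nodes at
half weight). c(t) is recomputed in full rather than incrementally: it
keeps the estimator exact to grid resolution and matches the on-the-fly
semantics. The log-ratio form means c(t) is not mathematically forced to
be monotone step by step; in practice it rises steadily with a ripple of
at most a few thousandths of kJ/mol early in a run, and the property test
asserts exactly that.

# FES estimation

Frame weights are `exp(beta (V(s_i, t_i) - c(t_i)))`, with `V` read from
the engine's bias grid at the frame's own time (an evolving-grid replay,
exact to grid resolution) and `c` the step function of deposition times.
The FES is `-kT ln` of the weighted histogram. Defaults:

* **burn-in** 1/9 of the run — the fraction a 500 ns cut of a 4.5 us
  production run corresponds to; expressed as a fraction so it scales to
  desk-length runs;
* **histogram bin** 0.5 A (1 A for the scaled 2D runs) — the kernel-sigma
  scale; the 0.01 A bias grid is *not* a histogram grid;
* **errors** from three contiguous equal time blocks, each block
  re-referenced before comparison, standard error across blocks;
* **masking**: unvisited bins carry NA and are excluded from minima,
  paths and integrals; they are never imputed.

Two reference conventions exist: `min-zero` and `bulk-zero`. Bulk for a
2D ring/tail surface means both CVs beyond the cut *and on the same side*
of the membrane — opposite-sign corners are stretched, non-physical
configurations and are excluded from the bulk average.

Symmetrization averages in probability space,
`F_sym = -kT ln[(e^{-beta F(s)} + e^{-beta F(-s)})/2]`, which is exact for
populations and idempotent; whether to average probabilities or free
energies was an open choice, and probability space was chosen because the
quantity conserved by the bilayer mirror symmetry is the population. Where
only one bin of a mirror pair is visited its value is copied; the
`asymmetry()` diagnostic reports the worst mirror mismatch over complete
pairs and should be compared against the block error.

`bias_based_fes()` provides the independent cross-estimate
`F = -(gamma/(gamma-1)) V(s, t_end)`; it is systematically smoothed by the
kernel width, so it serves as a consistency check (the package tests
require barrier agreement within 1.5 kJ/mol) rather than the production
estimator.

# String-method MFEP

The zero-temperature string method on the gridded FES: interior images
move against the gradient component perpendicular to the path, then the
path is reparameterized to equal arc length; endpoints stay fixed at the
minima. The surface is interpolated by separable Catmull-Rom bicubic
convolution with analytic derivatives; masked bins are assigned a high
value (max visited F + 100 kJ/mol) so paths cannot cross unsampled
regions. Convergence is declared when the largest perpendicular gradient
at an interior image falls below `tol` (default 0.5 kJ/mol/A; 1.0 for
reconstructed noisy surfaces) or the images stop moving; 48 images by
default — doubling to 64 does not move the converged path on smooth test
surfaces, and a Dijkstra-style minimax oracle over grid paths confirms the
string selects the channel with the lowest saddle. Ties between
equal-depth channels resolve to whichever basin the straight-line
initialization falls into, deterministically.

# Protomer coupling

The neutral surface is first raised by the aqueous acid-base term
`kT ln(10) (pKa - pH)` — 20.18 kJ/mol at pKa 10.4, pH 7, 310 K, making
the neutral form a ~1-in-2500 minority in water. Populations are two-state
Boltzmann fractions per bin, and the combined surface is the exact
partition function `F_comb = -kT ln(e^{-beta F0'} + e^{-beta F+})`. The
log-sum-exp form (not the arithmetic population-weighted mean) is used
because it is the thermodynamically exact free energy of the two-state
union; the identity `F_comb = <F>_pop - T S_mix` is enforced in tests, as
are the mixing bounds `min(F) - kT ln 2 <= F_comb <= min(F)` and the
round-trip `F_i = F_comb - kT ln p_i`. Proton-transfer kinetics are not
modelled; the difference map's zero-crossing band (at the interface for
membrane-shaped landscapes) is reported as the natural locus for proton
exchange, nothing more. The diprotonated species is ignored: at pH 7 with
pKa1 8.1 it is a spectator for core energetics, and only the
neutral/monoprotonated pair is coupled.

# Diffusion and permeability

`estimate_D_at()` uses the restrained-window positional-autocorrelation
estimator `D = var(z)^2 / Int <dz(0) dz(t)> dt`, exact for an exponential
ACF (`D = var/tau`). The ACF is integrated to its first zero-crossing
sustained for five lags, else to ten times the initial decay time —
cutting before the noise-dominated tail. Windows use a 10 kJ/mol/A^2
spring (restraint width ~0.5 A, narrow enough to resolve a D(z) transition
of a few A); errors are standard errors over five contiguous sub-blocks,
and a split-half variance ratio outside [0.5, 2] rejects non-stationary
input. `build_D_profile()` assembles a ladder of windows and symmetrizes
D(z) with D(-z).

`isd_permeability()` evaluates `1/P = Int e^{beta F(z)} / D(z) dz` with F
referenced to bulk (|F| at the bounds must be below 1 kJ/mol), trapezoid
quadrature on the F grid with a half-resolution Richardson check, and
first-order error propagation from per-bin F and D errors. The resistance
integrand is interpolated linearly, so splitting the domain and summing
segment resistances is exact to rounding. For 2D runs the ISD input is the
Boltzmann marginal of the surface over the tail axis — the integral runs
over the membrane normal, not over MFEP arc length; the MFEP profile is
kept for mechanistic plots.

External fields enter two ways: as a linear `tilt` on the analytic
landscape, and as `apply_field_tilt()` on a reconstructed surface,
`F'(z) = F(z) - E mu c(z)` with an orientation-averaged coupling profile
`|c| <= 1`. The first-order energy scale `2 E mu` is 2.33 kJ/mol for a 10
mV/A field and a 5.8 D dipole — small against a 40 kJ/mol well, which is
the quantitative reason membrane potentials barely matter for this class
of permeant. An antisymmetric coupling of constant magnitude `c0` splits
the interfacial minima by exactly `2 E mu c0`; with `|c| <= 1` the split
cannot exceed 2.33 kJ/mol, so the ~3 kJ/mol figure sometimes quoted for
strongly oriented dipoles should be read as the same first-order scale,
not a bound this linear model can exceed.

# Problem sizes and what the tests show

The test-suite and acceptance runs use desk-scale problem sizes chosen
once:

* 1D double-well (10 kJ/mol barrier, minima at +-6 A, domain +-12 A):
  40 ns of Brownian dynamics (4e6 steps at 10 fs), kernels every 1 ps,
  bias grid 0.05 A. Reweighted barrier recovered within 1 kJ/mol across
  seeds; bias-based estimate within 1.5 kJ/mol.
* 2D chloroquine-like landscape (depth 40, rise 11 kJ/mol, minima at
  10 A, domain +-25 A): 300 ns (3e7 steps), sigma 1.5 A, bias/c(t) grid
  0.5 A, 1 A histogram bins, bulk cut 22 A. Depth and rise recovered
  within 2 kJ/mol; the kernel width only affects sampling, not the
  reweighted estimator's resolution, which is set by the histogram.
* Diffusion windows: 9 restrained runs of 4 ns each recover a constant D
  within 15% and a two-level D(z) within 20%.
* The shipped demo config is a 4 ns, +-12 A miniature of the whole chain
  (both protomers, MFEP, D(z), P) that completes in well under a minute.

What passing these tests shows — and does not show. The synthetic module
emulates the *statistical* structure of permeation data: metastable
interfacial states, a central barrier, rare crossings, position-dependent
diffusivity, protomer asymmetry. It does not emulate atomistic reality:
there is no membrane deformation, no water defects, no CV hysteresis from
slow orthogonal degrees of freedom, no force-field error. Passing
recovery tests therefore validates the *estimators* (bias bookkeeping,
reweighting, error analysis, path finding, quadrature), not the physics
of any particular membrane; the atomistic headline numbers (e.g.
permeabilities of tens of cm/s) require microsecond membrane MD and are
out of scope by design.

# Known limitations

* Single-run reweighting only; no WHAM/MBAR combination of runs and no
  multiple-walker metadynamics.
* The c(t) estimator is grid-based; extremely fine 2D grids make the
  per-deposition update the dominant cost (it is O(nodes) per kernel).
* The string method is the zero-temperature variant; no transition tubes
  or committors.
* `estimate_D_at()` assumes a quasi-harmonic window; strongly anharmonic
  restraint regions would need a finer ladder.
* Only two protomers are coupled; extending to n states is a
  straightforward generalization of the same log-sum-exp algebra.
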