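---
title: "Methods: a temperature-dependent coarse-grained model of LCST-type protein phase behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a temperature-dependent coarse-grained model of LCST-type protein phase behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Proteins with LCST-type phase behavior dissolve when cool and condense
on heating. The driving force is solvent entropy: ordering water around
hydrophobic residues becomes increasingly costly as temperature rises.
An implicit-solvent residue-level model can only capture this if its
interaction energies depend on temperature, because there are no water
molecules to pay the entropy bill explicitly.

`cgphase` implements such a model. One bead per residue; the potential
energy is a sum of harmonic bonds, screened electrostatics, and
Wang–Frenkel short-range terms.

### Electrostatics

The screened-Coulomb (Yukawa) interaction uses two analytic temperature
dependences:

* The dielectric constant, `eps(T) = 1 + rho_solv(T) d(T)`, with the
  solvent density from the Kell polynomial for liquid water (validity
  273–373 K, enforced) and the solvent parameter `d` linear in `T`. The
  two coefficients of `d(T)` are not universal constants; the packaged
  defaults are a least-squares fit against a table of smoothed
  experimental water dielectric values (`inst/extdata/
  water_dielectric.csv`, 0–99 °C) shipped with the package, and
  `fit_d_coefficients()` reproduces them from that table at any time.
  The fit gives `eps(298.15 K) = 78.62` and a strictly decreasing
  `eps(T)` over the whole window. Tests assert against the refit, not
  against a transcribed constant.
* The inverse Debye length,
  `kappa^2 = (e^2 / eps(T) eps0 kB T) * sum_j z_j^2 c_j`, evaluated in
  SI units and converted to 1/Angstrom. Pure water gives `kappa = 0`;
  150 mM 1:1 salt at 298.15 K gives a 7.86 Å screening length.

The Yukawa term is cut off at 35 Å (configurable) and energy-shifted to
zero at the cutoff by default, so the potential is continuous there;
forces are unaffected by the shift.

### Short-range interactions and their temperature scaling

The canonical Wang–Frenkel potential is used for all short-range pairs:
zero exactly at `sigma` and at the cutoff `R = 3 sigma`, with shape
exponents `mu, nu >= 1` and the canonical normalisation `alpha_ij` that
makes the well depth exactly `epsilon` — verified in the tests by
numerical minimisation rather than trusted algebra. The minimum sits at

```
r* = R [ (1 + 2 nu) / (1 + 2 nu (R/sigma)^(2 mu)) ]^(1/(2 mu))
```

which the implementation cross-checks against bracketed numerical
minimisation to 1e−8·sigma.

For pairs containing at least one hydrophobic residue (A, V, I, L, M),
the well depth is temperature-scaled:

```
eps_ij(T) = 0.5[eps_ii + alpha_i (mu_i(T) − mu_i(Tref))]
          + 0.5[eps_jj + alpha_j (mu_j(T) − mu_j(Tref))],
mu_X(T) = a_X T^2 + b_X T + c_X,  Tref = 298.15 K.
```

At `Tref` this reduces *exactly* to the arithmetic mean of the two self
well-depths — an identity the acceptance suite asserts for every scaled
pair of every packaged parameter set. `alpha_X` multiplies only the
`mu` difference (the printed form); all other placements would break
the `Tref` identity. Non-hydrophobic pairs keep their reference
`eps_ij` unchanged at every temperature: the temperature dependence of
charged interactions is already carried by the electrostatics. Sigma,
the shape exponents and the cutoffs are never scaled — temperature
enters the short-range table only through the well depth.

### The repulsive branch

A scaled `eps_ij(T)` can go negative. Plugging a negative well depth
into the Wang–Frenkel form makes the potential attractive and divergent
at contact, which is unphysical. The package therefore switches such
pairs to a WCA-style construction that keeps only a repulsive core and
preserves the bead diameter:

```
phi_rep(r) = −phi_WF(r; eps) − eps   for r < r*,   0 otherwise  (eps < 0)
```

This is continuous (exactly zero) at `r*`, strictly positive and
monotonically increasing as `r` decreases below `r*`, and divergent at
contact. A well depth of exactly zero contributes no short-range term.
Floating-point noise at the branch point (order 1e−16) is clamped to
zero so the non-negativity contract holds bitwise.

## Simulation engine

Canonical dynamics use BAOAB Langevin splitting with the production
timestep of 10 fs and a 5 ps thermostat relaxation time (friction
1/5000 fs⁻¹). With friction zero the scheme reduces to velocity
Verlet, which is how the NVE conservation oracle runs. Choices worth
recording:

* **Units** follow the LAMMPS `real` convention (Å, fs, amu, kcal/mol,
  e, K) so exported tables and data files are bit-compatible.
* **Neighbour search** is a cell list (cells at least the largest
  cutoff; requires ≥ 3 cells per dimension, otherwise the code falls
  back to the all-pairs reference automatically, e.g. in slab boxes
  whose x/y edges are small). The all-pairs path is kept as an
  independent oracle and the two are asserted equal to 1e−12 on
  ≤ 200-bead systems.
* **Exclusions**: directly bonded pairs are excluded from nonbonded
  terms.
* **Determinism**: the thermostat noise stream is a seeded
  `std::mt19937_64`; identical seeds give bit-identical trajectories.
* **Energy drift** is defined as the least-squares secular slope of the
  total energy, the standard MD measure. Velocity Verlet at 10 fs has a
  bounded energy *oscillation* (~2e−4 kcal/mol/bead on the test
  system); the *drift* is an order of magnitude below the 1e−4
  kcal/mol/bead acceptance bound.
* **Initial configurations from random packing overlap.** Builders are
  purely geometric (so bond-length contracts hold exactly); pipelines
  that hand a fresh build to the integrator first run a backtracking
  steepest-descent minimisation, and the slab compressor relaxes at a
  2 fs timestep between affine stages.

## Slab preparation

`build_slab()` follows the finite-size protocol: 64 (4×4×4) chain
replicates below 190 residues, 27 (3×3×3) at or above; chains packed as
confined random walks on a cubic lattice; compression to a dense slab
of 0.9 g/cm³ by default (midpoint of the conventional 0.8–1.0 range);
then the z-axis is extended so total mass over box volume equals the
target solution concentration. The compression substitutes staged
affine rescaling with minimisation and short Langevin bursts for a true
NPT barostat — defensible because nothing downstream consumes the
compression *path*, only the final dense density, which the affine step
sets exactly (mass is conserved by construction). The pre-compression
lattice geometry is not specified upstream; any packing reaching the
dense density is acceptable.

## Cloud-point detection (finite-size spike criterion)

At fixed concentration, the cloud point is the lowest temperature at
which the system turns turbid. In a finite slab at the experimental
concentration, condensation shows up as a sharp spike in the z-density
profile. "Sharp spike" is operationalised with two exposed knobs, since
no threshold is stated upstream: a frame spikes when its maximum bin
density is at least `spike_ratio` (default 5) times the overall mean
density, and a temperature is detected when the spike persists for at
least `persistence` (default 10) consecutive sampled frames. The
persistence rule covers both readings of "the first temperature at
which the density profile exhibited a sharp spike" (per-frame vs
sustained). Detection scans temperatures in ascending order and returns
the first hit.

**Desk-scale caveat.** The ratio threshold is calibrated for
paper-scale systems (thousands of beads). With the 80-bead acceptance
system, 5–10 Å bins hold ~2 beads each and shot noise alone produces
peak/mean ≈ 6 in a homogeneous gas. The desk-scale closed loop
therefore bins at 40 Å (≈ the slab width), where the gas sits at ≈ 3.4
and the condensed slab at ≥ 9. A green desk-scale test establishes that
the pipeline discriminates condensing from non-condensing parameter
sets under the stated criterion — not that the default bin width is
appropriate for arbitrary system sizes.

## Coexistence densities and the critical point

`coexistence_densities()` averages profiles at one temperature,
recentres the dense phase with a periodic (circular) mass-weighted
mean, takes the contiguous region above the half-height density as the
slab, and averages the slab core and the far field, excluding a 10 Å
interfacial margin on each side (margin exposed; not specified
upstream). `fit_binodal()` fits simultaneously

```
rho_dense − rho_dilute = A |T − T_c|^beta        (coexistence law)
(rho_dense + rho_dilute)/2 = rho_c + B (T − T_c) (rectilinear diameter)
```

with `beta = 0.325` (3D Ising) by default, the convention of this
fitting tradition; for LCST data the gap opens above `T_c`, and
`lcst = FALSE` mirrors the orientation. Given `T_c` both laws are
linear in their remaining parameters, so the fit profiles out
`A, B, rho_c` in closed form and optimises only `T_c` on a bracket
below the coldest two-phase point — no starting guesses, no
convergence tuning. Noiseless synthetic binodals are recovered to
0.1 K / 1e−4 g/cm³; under 5% multiplicative noise the median `T_c`
error over 100 seeds stays under 2 K.

## Flory exponent and the coil-to-globule temperature

For finite heteropolymers the package uses the radius-of-gyration
relation

```
S = sqrt( gamma (gamma+1) / (2 (gamma+2 nu)(gamma+2 nu+1)) ) · b · N^nu
```

with `b = 5.5 Å` (geometric mean of a 4.0 Å persistence length and the
3.8 Å C-alpha spacing) and `gamma = 1.1615` (Schultz distribution
exponent). The forward map is strictly increasing in `nu`, so the
solver inverts it by bracketed root finding on (0.05, 0.95); the
inversion is exact to 1e−8 everywhere tested. `nu(T)` is interpolated
linearly to its first crossing of `nu = 0.5` in ascending temperature —
the coil-to-globule transition for finite disordered chains sits below
the infinite-chain 0.588, and 0.5 is the stated convention. Non-
monotone series crossing more than once take the first crossing, with a
warning. An exact `nu = 0.5` grid point counts as a single crossing.

Block errors everywhere follow the three-block convention: contiguous
equal blocks (remainder to the last), mean of block means, standard
error across blocks.

## Synthetic fixtures: what they do and do not establish

Generators (`make_param_set`, `make_profiles`, `make_binodal`,
`make_rg_series`, `make_absorbance_curve`) emulate the *schema and
statistical shape* of real inputs, never any published fitted values,
so the tests cannot silently depend on tables this package does not
ship. Choices, made once:

* residue masses are the standard chemistry constants; charges −1 on
  D/E, +1 on K/R, +0.375 on H; sigmas seeded in 5.0–6.5 Å and reference
  well depths in 0.15–0.7 kcal/mol (the realistic coarse-grained
  range); Lorentz-like combination for pairs; integer shape exponents
  μ ∈ {1,2,3}, ν = 1.
* temperature scaling styles use a *linear* `mu_X` with slope
  ±0.02 kcal/(mol K): `attractive` adds ≈ +1.24 kcal/mol to hydrophobic
  well depths at 360 K (a strong LCST caricature); `repulsive_at_high_T`
  subtracts the same, guaranteeing a sign change between 280 and 360 K;
  `neutral` freezes everything; `repulsive` negates all reference well
  depths (a non-condensing control).
* the planted-spike profile fixture preserves the overall mean density
  exactly and hits its peak/mean ratio (default 20) exactly at zero
  noise.

A green closed-loop test establishes that each analysis inverts its
generator within tolerance — it does not establish that the real
supplementary parameter tables reproduce experimental cloud points,
which is out of scope here (that result requires the original tables
and cluster-scale coexistence runs).

## Known limitations

* No true NPT barostat; compression is affine + relaxation.
* Desk-scale engine only; production scale is delegated to LAMMPS via
  the exported tables/data files (energies and forces in the tables
  match the direct potential to < 1e−8 kcal/mol, printed at 15
  significant digits for that reason).
* No conformational (folding) response to temperature; disordered
  chains only; no rings or branched topologies.
* The dielectric model is fitted, not first-principles; its `d(T)` is
  linear by stated assumption and only valid over liquid water.
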