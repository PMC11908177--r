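# cgphase

Temperature-dependent coarse-grained simulation and analysis of protein
phase behavior, for people studying LCST-type (lower critical solution
temperature) phase separation of intrinsically disordered proteins:
sequences that are soluble when cool and condense on heating, as in heat
shock responses and elastin-like polypeptides.

## The model

Each residue is one bead with mass, charge, and size. The potential
energy has three terms:

* **Harmonic bonds** between consecutive beads, `U = k (r − r0)²`
  (defaults `r0 = 3.81 Å`, `k = 9.6 kcal/(mol Å²)`).
* **Screened electrostatics (Yukawa / Debye–Hückel)** between charged
  beads, `u(r) = C q_i q_j exp(−κ(T) r) / (ε(T) r)`, with a
  temperature-dependent dielectric constant `ε(T) = 1 + ρ_solv(T) d(T)`
  built on the Kell water density and a linear solvent parameter `d(T)`
  fitted to experimental dielectric data, and the inverse Debye length
  `κ² = (e²/ε(T)ε₀k_BT) Σ z_j² c_j` from the ionic composition.
* **Wang–Frenkel short-range interactions** with shape exponents (μ, ν),
  zero at σ and at the cutoff `R = 3σ`, and well depth ε. For pairs
  containing a hydrophobic residue (A, V, I, L, M) the well depth is a
  function of temperature,

  ```
  ε_ij(T) = ½[ε_ii + α_i(μ_i(T) − μ_i(T_ref))] + ½[ε_jj + α_j(μ_j(T) − μ_j(T_ref))]
  μ_X(T)  = a_X T² + b_X T + c_X,   T_ref = 298.15 K
  ```

  which encodes the growing entropic penalty of hydrating hydrophobic
  residues on heating. When ε_ij(T) goes negative the pair switches to a
  WCA-style purely repulsive branch that preserves the bead diameter:
  `φ_rep(r) = −φ_WF(r; ε) − ε` below the Wang–Frenkel minimum `r*`, zero
  beyond.

On top of the force field the package provides a desk-scale BAOAB
Langevin engine (10 fs timestep, 5 ps thermostat relaxation), slab
builders with the 64/27 replicate rule, finite-size cloud-point
detection from z-density profiles (the "sharp spike" criterion),
coexistence-density extraction and critical-point fitting via the laws
of coexistence densities and rectilinear diameters, Flory-exponent
analysis `S = sqrt(γ(γ+1) / (2(γ+2ν)(γ+2ν+1))) · b · N^ν`
(b = 5.5 Å, γ = 1.1615; the ν = 0.5 crossing is the coil-to-globule
temperature), and LAMMPS table/data export for production-scale runs.

## Worked example

A desk-scale cloud-point run: 8 replicates of the hydrophobic 10-mer
`ILVAGMLVAG` at 50 g/L under a synthetic "attractive" parameter set
whose well depths grow with temperature (an LCST caricature).

```r
library(cgphase)
ff <- make_param_set(seed = 11, style = "attractive")
epsilon_ij("L", "L", 280, ff)   # -0.0487  kcal/mol (repulsive branch)
epsilon_ij("L", "L", 360, ff)   #  1.5513  kcal/mol (strongly attractive)
dielectric_constant(300)        # 78.04
es <- electrostatics_params(data.frame(z = c(1, -1), c = c(0.15, 0.15)))
1 / inverse_debye_length(298.15, es)   # 7.86 Angstrom

prot <- simulation_protocol(equilibration = 0.5, production = 0.3,
                            sample_interval = 0.02,
                            temperature_grid = c(280, 320, 360), seed = 5)
out <- run_cloudpoint("ILVAGMLVAG", ff, concentration = 50, prot,
                      out_dir = "demo_out", bin_width = 40,
                      n_replicates = 8)
out$spike_stats
#>   temperature peak_over_mean    stderr
#> 1         280       4.157642 0.2965990
#> 2         320       9.222068 0.3798598
#> 3         360      11.000000 0.0000000
out$cloud_point
#> [1] 320
```

The peak/mean column is the spike statistic of the z-density profile
(block means of three blocks ± standard error): below the cloud point
the slab evaporates into a homogeneous gas (ratio ≈ 4, under the
detection threshold 5); at and above it the chains stay condensed and
the profile spikes. The detected cloud point is the lowest temperature
whose profiles spike in ≥ 10 consecutive frames.

Critical-point fitting on coexistence data:

```r
pts <- make_binodal(seed = 1, t_c = 300, rho_c = 0.3, A = 0.05,
                    B = 0.002, noise = 0.02)
fit_binodal(pts)
#> <binodal_fit> LCST T_c = 300.09 K, rho_c = 0.2980 g/cm^3 (beta = 0.325, rss = 0.000272)
```

## Command line

```sh
Rscript inst/cli/cgphase.R cloudpoint --fasta seq.fasta --ff params/ \
        --concentration 50 --out run1
Rscript inst/cli/cgphase.R tables --ff params/ --tmin 280 --tmax 360 --tstep 5 --out tables/
Rscript inst/cli/cgphase.R binodal --points coexistence.csv --out fit/
```

Exit codes: 0 success, 2 validation error, 3 numerical failure. Every
command writes a `manifest.json` (config, seed, package version, input
hashes) so a run can be reproduced exactly.

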