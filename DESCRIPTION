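Package: cgphase
Title: Temperature-Dependent Coarse-Grained Simulation and Analysis of
    Protein Phase Behavior
Version: 0.1.0
Authors@R:
    person("cgphase", "developers", email = "cgphase@example.org",
           role = c("aut", "cre"))
Description: Residue-level coarse-grained modelling of temperature-driven
    protein phase separation. Implements an implicit-solvent force field
    with Wang-Frenkel short-range interactions whose well depths are
    rescaled as parabolic functions of temperature for pairs containing a
    hydrophobic residue, Debye-Hueckel (Yukawa) electrostatics with a
    temperature-dependent dielectric constant built on the Kell water
    density, and a WCA-style repulsive variant for pairs whose effective
    well depth becomes negative. Ships a desk-scale Langevin dynamics
    engine, slab-geometry builders, cloud-point detection from density
    profiles of finite-size slab simulations, coexistence-density and
    critical-point (rectilinear diameter) fitting, Flory scaling exponent
    analysis of radius-of-gyration data, and LAMMPS table/data export for
    production runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
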