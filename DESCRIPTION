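Package: femvc
Title: Finite Element Modeling of Volume Conduction with Dispersive Tissue
    and Electrode Interfaces
Version: 0.1.0
Authors@R:
    person("femvc", "developers", email = "femvc@example.org", role = c("aut", "cre"))
Description: Forward modeling of extracellular potentials in volume
    conductors at EEG/ECoG/multi-electrode-array scale. Provides a
    tetrahedral mesh data model with Gmsh MSH input/output, synthetic
    layered-sphere and slab-in-bath fixture generators, conforming
    red-green refinement and submesh extraction; four-term Cole-Cole
    dielectric dispersion and complex admittivity (scalar or tensor);
    electrode-electrolyte interface models (constant-phase-angle
    pseudocapacitance, charge-transfer resistance and their parallel
    network); Lagrangian P1/P2 finite element assembly of the real and
    complex-block admittivity Poisson operator with Robin interface
    conditions and Lagrange-multiplier floating recording electrodes;
    conjugate-gradient and GMRES solvers with a zero-mean potential
    reference; an analytical four-layer concentric-sphere dipole series
    for validation; and a FEM-Fourier pipeline for transient stimulation
    waveforms in capacitive or dispersive media.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
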