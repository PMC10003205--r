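Package: cgbilayer
Title: Coarse-Grained Molecular Dynamics of pH-Sensitive Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, simulates and analyses coarse-grained (MARTINI-style)
    lipid bilayers containing POPC and imidazole-headgroup (ISUCA-derived)
    pH-sensitive lipids. Provides bead topologies for the five lipid species
    (neutral and protonated), a lattice bilayer builder with solvent,
    antifreeze particles and counterions, a minimal NPT molecular-dynamics
    engine (shifted Lennard-Jones, harmonic bonds, cosine-harmonic angles,
    Ewald electrostatics, Nose-Hoover thermostat, Andersen-type barostat),
    membrane characterisation metrics (area per lipid, hydrophobic thickness,
    second-rank order parameters P2b and P2t, lateral diffusion coefficient
    from mean-squared displacement), and a synthetic-trajectory generator
    with known ground truth so every analysis stage is verifiable without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
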