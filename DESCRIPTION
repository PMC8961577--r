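Package: ommtraj
Title: Structural and Dynamical Analysis of Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of lipid bilayers,
    built around multi-component outer-mitochondrial-membrane models
    (POPC/POPE/POPS/PI(3,4)P2 with Na+/Cl- counter ions). Computes area per
    lipid, partial density profiles and phosphate peak-to-peak thickness,
    deuterium order parameters (S_CD), lateral diffusion coefficients from
    multi-origin mean squared displacement, headgroup rotational
    autocorrelation functions, and water-membrane interface statistics
    (geometric hydrogen bonds, choline charge pairs, sodium-lipid contacts
    with multiplicity). Includes a synthetic bilayer trajectory generator
    with known ground truth (diffusion constants, rotational correlation
    times, per-carbon order parameters, thickness, constructed contact
    geometries) so that every analysis stage can be validated without
    running molecular dynamics. Reads GRO and PDB structures, DCD and
    multi-frame GRO trajectories.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
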