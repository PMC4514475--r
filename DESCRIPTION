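Package: porescope
Title: Gating Descriptors and Pore-Opening Restraints for Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural descriptors that distinguish collapsed from open
    conformations of pentameric ligand-gated ion channels (Cys-loop
    receptors) in molecular-dynamics trajectories: crossed distances
    between pore-lining M2 residues of non-adjacent subunits, axis-sampled
    pore radius profiles, pore hydration and water/protein hydrogen-bond
    persistence, M2 helix polar/azimuthal tilt decomposition, the
    quaternary twist between the ligand-binding and transmembrane domains,
    ligand-binding-site monitors, and ion axial distributions.  Includes
    the flat-bottom quadratic restraint on gate crossed distances (energy
    and analytic forces) used to hold such channels open, and a synthetic
    pentamer/trajectory generator with closed-form ground truth for
    testing every descriptor at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
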