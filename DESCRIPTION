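Package: gnreq
Title: Mechanobiologically Equilibrated Growth and Remodeling of the Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-independent, mechanobiologically equilibrated constrained-mixture
    model of arterial growth and remodeling for a cylindrical segment of the murine
    thoracic aorta. Provides the constitutive mixture model (elastin, smooth muscle,
    and four collagen fiber families with deposition prestretch and active tone),
    coupled mechanical and mechanobiological equilibrium solvers at a material point
    and on an axisymmetric nonlinear membrane finite-element mesh with follower
    pressure, Gaussian-like localized insult fields, a catalog of in silico
    "numerical knockout" scenarios (loss of elastic fiber integrity, collagen
    cross-linking or turnover defects, reduced smooth muscle contractility,
    dysfunctional mechanosensing or mechanoregulation, with superimposed
    hypertension and aging), and post-processing of evolved geometry, composition,
    stored energy, material stiffness, and simulated biaxial tests, with CSV and
    legacy-ASCII VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
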