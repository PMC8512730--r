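Package: cidscatter
Title: Circular Intensity Differential Scattering of Chromatin Solenoid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parameterized solenoid models of the 30 nm chromatin
    fiber (helical arrays of cylindrical or spherical nucleosomes), voxelizes
    them onto a cubic dipole lattice, and solves the coupled-dipole (discrete
    dipole approximation) scattering problem for plane-wave illumination.
    Computes angle-resolved Mueller matrices, circular intensity differential
    scattering (CIDS) profiles, total scattered intensity, and extinction
    efficiencies, in fixed orientation or averaged over particle orientations
    with Euler-angle quadrature. Includes an independent Lorenz-Mie oracle and
    closed-form small-system solutions for validation, ADDA/DDSCAT-style
    geometry exchange, and configuration-driven parameter sweeps over the
    chiral degrees of freedom of the fiber (pitch, radius, handedness, turns,
    nucleosome orientation and shape).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    pracma,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
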