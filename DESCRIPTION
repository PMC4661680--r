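Package: retisim
Title: Schematic-Eye Ray Tracing of Snellen Charts with Lens-Opacity
    Microstructures
Version: 0.1.0
Authors@R:
    person("Retisim", "Developers", email = "retisim@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo sequential ray tracing of a four-surface schematic
    human eye viewing an emissive Snellen chart. Retinal irradiance maps are
    degraded either by axial myopic defocus or by periodic hole-array
    opacities placed on the anterior lens surface, emulating cataract-like
    straylight damage. A flux-versus-diopter calibration curve, normalized
    to 1 at plano, is inverted to assign an equivalent myopia severity to
    any opacity configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
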