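Package: archflow
Title: Lumped-Parameter Hemodynamics of the Aortic Arch after Zone-2
    Endovascular Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of thoracic endovascular
    aortic repair (TEVAR) in proximal landing zone 2. Provides a
    zero-dimensional aortic-arch model with calibrated three-element
    Windkessel (RCR) outlet circuits, a pre/post-operative topology
    transform describing left-subclavian coverage with a
    carotid-to-subclavian bypass, integration of pressure and wall
    shear-stress tractions over triangulated stent-graft surfaces to obtain
    the hemodynamic displacement force, generators for pulsatile inflow
    waveforms and idealized graft geometries with analytic Poiseuille
    fields, and cohort arithmetic (means, ranges, percent changes,
    conservation checks, Pearson correlation) over an embedded four-patient
    clinical table set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
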