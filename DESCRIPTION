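Package: virtual4dct
Title: In-Silico Commissioning of 4DCT Phase-Binning Reconstruction for Moving Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates cine-mode four-dimensional computed tomography (4DCT) acquisition
    of digital rod and sphere phantoms undergoing anterior-posterior respiratory motion,
    reconstructs ten-percent phase-binned volumes together with maximum- and
    average-intensity projections, and measures motion-artifact metrics (apparent rod
    width and angle, sphere diameters, auto-threshold contour volumes and equivalent
    diameters). Provides breathing-trace generators (sinusoidal and irregular
    patient-like), a virtual cine scanner with per-couch-station timing, RPM-style phase
    assignment and binning, and a commissioning driver that reproduces a minimum-target-size
    QA procedure with washout flagging and internal-target construction for SBRT planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
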