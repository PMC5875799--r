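Package: coleokin
Title: Kinematics of Gravitropic Movement in Growing Plant Organs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the kinematic analysis of gravitropic movement in
    elongating plant axes such as grass coleoptiles. Extracts orientation,
    curvature, relative elongation growth rate (by one-dimensional digital
    image correlation on marker profiles) and the material derivative of
    curvature from midline time series; simulates the graviceptive-
    proprioceptive posture-control model and locates its overshoot
    threshold in the balance number; generates ground-truthed synthetic
    coleoptile datasets with propagating growth and curvature pulses;
    characterizes oscillation periods and pulse velocities on kymographs;
    computes morphometric balance numbers and overshoot classifications;
    and provides the exact contingency-table and rank statistics used to
    compare treatment groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
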