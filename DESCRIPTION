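Package: ammr
Title: Adaptive Multipole Models for On-Scalp MEG Interference Rejection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial and temporal interference rejection for optically pumped
    magnetometer (OPM) magnetoencephalography. Builds real spherical and
    prolate spheroidal harmonic bases on arbitrary sensor arrays, constructs
    the oblique signal-space-separation (SSS) projector and the orthogonal
    adaptive multipole model (AMM) projector, and provides a canonical
    correlation temporal cleaning stage with a principled correlation-limit
    heuristic. Includes a full simulation suite (scalp sensor arrays,
    current-dipole lead fields in a conducting sphere, homogeneous-field and
    first-order-gradient interference, structured sensor nonlinearity, white
    noise) and quantitative metrics (shielding factors, lead-field
    reconstruction correlation, white-noise reduction, Welch PSD shielding,
    epoch averages and t-statistics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
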