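Package: mobisense
Title: Passive Smartphone Sensing Pipelines for Digital Phenotyping Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Server-side processing for passively sensed smartphone data in
    remote-monitoring studies: JSON-Lines schemas for location, activity
    recognition, app usage and inertial sensor streams; keyed geolocation
    anonymization by tangent-plane rotation about a relocated anchor;
    fusion of location and activity streams into daily distance covered by
    foot; per-app foreground-usage aggregation; per-day per-modality
    completeness quality control; study enrollment artifacts with one-time
    codes and MD5 manifests; a multi-modality synthetic data generator
    with ground truth; and pooled Pearson correlation analysis of
    self-reported versus passively derived daily measures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
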