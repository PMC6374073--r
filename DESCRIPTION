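Package: zebellum
Title: Sensorimotor Encoding Analysis of Larval Zebrafish Cerebellar Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for cell-attached
    electrophysiology, fictive-swim behavior, and calcium imaging of the
    larval zebrafish cerebellum. Extracts complex and simple spikes from
    Purkinje cell recordings, detects fictive swim bouts from ventral-root
    envelopes, builds sensory and motor feature regressors (optionally
    convolved with a GCaMP response kernel), fits penalized encoding models
    (elastic net) to spiking and fluorescence signals, classifies complex
    spike response phenotypes, computes spike-interaction and peri-event
    statistics, clusters population responses with anatomical clustering and
    stereotypy indices, and counts fluorescently labelled nuclei in image
    volumes by 3D Gaussian template matching. A synthetic-data module
    generates stimulus protocols, behavior, spike trains, calcium traces,
    volumes, and morphologies with known ground truth so that every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    signal,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
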