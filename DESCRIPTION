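Package: vtmap3d
Title: 3-D Intramural Activation Mapping and Arrhythmia Mechanism Analysis
Version: 0.1.0
Authors@R:
    person("vtmap3d", "developers", email = "vtmap3d@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel plunge-needle electrogram
    recordings of ischemic ventricular tachycardia and fibrillation:
    maximum-dV/dt activation onset detection with good-channel templating
    and refractory enforcement, layer-adjacency sequencing and isochronal
    activation maps, focal versus reentrant mechanism classification with
    Purkinje-origin detection, electrogram-voltage ischemia assessment,
    microelectrode action-potential feature extraction with delayed
    afterdepolarization and triggered-activity detection, and study-level
    induction-block tallies with 2x2 contingency statistics. Includes a
    synthetic electrogram and action-potential generator with ground truth
    so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
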