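Package: cvepsim
Title: Simulation and Analysis of Code-Modulated VEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of a code-modulated visual evoked potential
    (cVEP) brain-computer interface speller: maximal-length stimulus sequences
    and their circularly shifted class codes, a synthetic multi-channel EEG
    generator with code-locked evoked responses over an occipito-parietal
    montage, canonical-correlation spatial-filter calibration, an online
    certainty-margin decoder, a three-step copy-speller with UNDO recovery, and
    an electrode-reduction study harness. Includes accuracy and Wolpaw
    information transfer rate metrics, McNemar and Cochran's Q tests for paired
    functionality outcomes, paired effect sizes with bootstrap intervals, and a
    packaged subject-level performance table for reproducing published summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
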