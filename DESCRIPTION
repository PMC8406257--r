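Package: mmpH
Title: Single-Cell Intracellular pH and Persister Phenotyping in
    Mother-Machine Time-Lapse Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring intracellular pH in individual bacteria
    from dual-fluorophore (ratiometric pHluorin/mCherry) mother-machine
    time-lapse microscopy, and for classifying each cell's fate after
    antibiotic treatment as persister, viable-but-non-culturable (VBNC),
    or susceptible (lysed or propidium-iodide positive).  Includes trench
    and cell segmentation, overlap-based lineage tracking,
    background-subtracted ratiometric photometry, linear ratio-to-pH
    calibration from CCCP-equilibrated standards, end-point phenotype
    calling, and population statistics (phenotype fractions, pH
    distributions and mode detection, Welch tests).  A fully seeded
    synthetic-scene generator with known per-cell ground truth stands in
    for the microscope, so the whole image-to-phenotype chain can be
    validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
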