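Package: ismsm
Title: Informational Spectrum Method for Small-Molecule Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Informational Spectrum Method extended to small
    molecules (ISM-SM). Proteins and SMILES-encoded compounds are rendered as
    electron-ion interaction potential (EIIP) series, shared spectral
    frequencies are detected by discrete-Fourier cross-spectrum analysis,
    contributing protein regions are localized by sliding-window spectra and
    a Morlet continuous wavelet transform, and compound libraries are ranked
    by combined spectral and druglikeness scores (Drug Score, Total Score,
    and an ADMET-cluster-based Total Score 2). Includes seeded synthetic
    fixture generators with planted spectral ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
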