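Package: murosearch
Title: Automated Identification, Cross-Link Typing and Quantification of
    Bacterial Peptidoglycan LC-MS/MS Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A search engine for bacterial peptidoglycan (muropeptide)
    LC-MS/MS: monoisotopic mass model for glycan chains and peptide stems
    including meso-diaminopimelic acid, enumeration of monomer, dimer and
    trimer candidate databases with amidation, glycoform and wildcard
    modifications, precursor matching at ppm tolerance, theoretical b/y, c/z,
    glycosidic and internal fragment prediction for cross-linked species,
    ETD/HCD-based disambiguation of 3-3 versus 4-3 cross-link topology,
    extracted-ion-chromatogram quantification with in-source-decay detection
    by co-elution, and a seeded synthetic-run simulator writing standard mzML
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mzR,
    xml2,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Proteomics, Software
RoxygenNote: 7.3.3
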