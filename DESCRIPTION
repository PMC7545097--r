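Package: talemap
Title: Cross-Link Mapping and Quantitative Assays for TALE Transcription Factor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level mapping of lysine-lysine (BS3) cross-links in
    PREP1-PBX1 and MEIS1-PBX1 heterodimers from cross-linking
    mass-spectrometry identification tables: parsing of pLink-style and
    compact peptide-pair notation, curation by E-value, consecutive
    fragment-ion runs and assigned-peak fraction, mapping of in-peptide
    link positions to absolute residues, inter/intra/loop classification,
    redundancy collapse, replicate aggregation and linear SVG maps.
    Includes coiled-coil heptad register annotation, in-silico
    Glu-C/trypsin double digestion with blocked cross-linked lysines,
    one-site saturation binding fits for ELISA dose-response data,
    time-resolved fluorescence immunoassay normalization with the
    associated one-tailed homoscedastic t-test convention, and the two
    image quantification procedures used for proximity-ligation foci
    counting (rolling-ball background, Find Maxima with prominence
    semantics, Huang thresholding) and nuclear/cytoplasmic GFP ratios
    (Otsu thresholding). A synthetic-data module generates
    identification tables, binding curves and microscopy fields with
    known ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    tiff,
    withr
Config/testthat/edition: 3
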