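Package: acidtol
Title: Polyproline Motif Scanning and Acetic-Acid Tolerance Analysis in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the translation factor eIF5A to acetic-acid
    tolerance in Saccharomyces cerevisiae: proteome-wide scanning and
    classification of consecutive-proline (polyproline) motifs, alias-aware
    integration of acid-sensitivity deletion-screen gene lists,
    transcription-factor direct-target calling by IUPAC consensus scanning of
    promoters (URS1-like sites), calibrator-normalised expression arithmetic
    (delta-delta-Cq relative transcription, GFP relative fluorescence units,
    translation efficiency), growth-curve variable extraction (lag, maximum
    specific growth rate, growth efficiency) and CFU survival rates, plus a
    synthetic-data generator with recorded ground truth so every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
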