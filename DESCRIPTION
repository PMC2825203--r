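Package: leascan
Title: Screening Nematode ESTs for LEA-Like Hydrophilic Protein Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence characterisation of expressed sequence tags (ESTs)
    from anhydrobiotic nematodes, aimed at identifying candidate late
    embryogenesis abundant (LEA) and related hydrophilic proteins. Provides
    polyA-tail trimming, spliced-leader detection against a catalogue of
    nematode SL1/SL2 leaders, open reading frame extraction with optional
    selenocysteine (UGA) read-through, physicochemical profiling (GRAVY on
    the Eisenberg consensus scale, molecular weight, isoelectric point,
    mean scaled hydropathy and mean net charge), charge-hydropathy disorder
    classification with a FoldIndex-style windowed profile, amino-acid
    periodicity detection (including the K11 signature of Group 3 LEA
    proteins), a rule-based LEA classifier, and a seeded synthetic EST
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
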