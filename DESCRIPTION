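Package: staplekit
Title: Design and Membrane-Trajectory Analysis of Hydrocarbon-Stapled
    Apolipoprotein Mimetic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing hydrocarbon-stapled amphipathic helical
    peptides and for analysing their behaviour on the surface of
    triglyceride-rich lipoprotein models. Covers an extended peptide
    sequence dialect with non-natural residues, staples and terminal caps;
    helical-wheel geometry, Eisenberg hydrophobic moments and staple-site
    proposal; Kolaskar-Tongaonkar antigenicity scanning; a deterministic
    rule engine for protease susceptibility and protection; statistics for
    phospholipid/triolein trilayer trajectories (leaflet assignment,
    phosphorus-plane insertion depth, distance-angle hydrogen-bond
    timeseries, switching-function triolein coordination and contact
    counts); a synthetic trilayer trajectory generator with planted ground
    truth; and post-processing of turbidity, dose-response and plasma
    lipid assay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
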