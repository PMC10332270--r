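Package: its2pipe
Title: ITS2 Amplicon Metabarcoding Pipeline with Normalized Bit Score Taxonomy
Version: 0.9.0
Authors@R:
    person("EPSAG", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of an ITS2 amplicon
    metabarcoding inference chain for soil-algae communities: paired-end
    read screening and merging, expected-error quality filtering,
    dereplication, de novo chimera flagging, greedy 97% centroid OTU
    clustering with a relative-abundance floor, normalized-bit-score (NB)
    consensus taxonomy with genotype/species identity calling, site-overlap
    classification, and community diversity statistics. Ships a synthetic
    amplicon simulator with complete ground truth so that every stage can
    be validated by parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
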