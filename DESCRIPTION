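Package: skimclone
Title: Clonal Copy-Number Evolution from Skim Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing the clonal evolution of a transmissible cancer
    lineage from ~1x skim whole-genome sequencing. Converts 100-kb bin read
    counts into denoised LogR profiles against a panel of normals, estimates
    tumour purity from fixed single-copy-loss and homozygous-deletion regions
    and from targeted-panel allele fractions, segments profiles by exact
    penalised least-squares (single- and multi-sample), assigns integer and
    subclonal half-integer copy-number states with a Bayesian hierarchical
    model cross-validated by a Poisson mixture, consolidates per-sample
    segments into a cross-cohort CNV catalogue with recurrence and
    back-mutation nomenclature, quantifies breakpoint reuse and CNV clustering
    against a circularised-genome permutation null, and genotypes molecular
    inversion probe (MIP) panels with purity- and contamination-aware
    thresholds. A synthetic-data module generates clone trees, ground-truth
    CNV events, Poisson bin counts with host-cell dilution and MIP read
    tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
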