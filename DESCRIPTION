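Package: DRRscan
Title: Differential Reactivity Region Analysis for RNA Structure Probing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially reactive regions (DRRs) between two
    groups of replicate RNA structure-probing reactivity profiles
    (SHAPE/DMS/PARS). Within-group and between-group variation are quantified
    per nucleotide with an arctan-transformed coefficient-of-variation
    dissimilarity score computed over homogeneous and heterogeneous sample
    subsets, candidate regions are screened from the smoothed difference of
    the two variation profiles, and candidates are tested with a one-sided
    Wilcoxon signed-rank test under Benjamini-Hochberg FDR control. Also
    provides reactivity calculation from probing counts (detection rates,
    background subtraction, 2-8 percent normalization, PARS scores), a
    structure-ensemble simulator of correlated replicate profiles with
    planted DRRs and count back-calculation, and a permutation-based
    riboSNitch scorer for PARS trio data.
License: BSD_2_clause + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
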