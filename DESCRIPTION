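Package: lchquant
Title: Quantification of Lesional T Cell Density and Neoantigen Screening
    Statistics for Langerhans Cell Histiocytosis
Version: 0.1.0
Authors@R:
    person("LCH", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying T cell infiltration in Langerhans Cell
    Histiocytosis (LCH) lesions and for screening BRAF V600E derived
    neoantigen candidates.  Includes simulators for multiplex
    immunofluorescence lesion images with known ground truth, patient
    cohorts, competition-binding titrations and targeted-peptidomics
    transition reports; automated colour-threshold area quantification
    with region-of-interest masking and per-image white balance;
    multi-observer manual counting with adjudication and semi-quantitative
    consensus scoring; HLA carrier case-control association statistics
    (exact Hardy-Weinberg and Fisher tests, Sidak correction, Woolf odds
    ratios with Haldane correction, Good's p-value standardization);
    cohort comparisons with median split, Kaplan-Meier/log-rank and
    univariate Cox regression; and peptide-level computations (mutation
    spanning k-mer enumeration, four-parameter-logistic IC50 fitting,
    light/heavy peak-area abundance ratios with detection calls).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
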