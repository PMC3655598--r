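Package: epitopetools
Title: HLA Class II Epitope Scoring, Cluster Detection, and T-Cell Assay
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An immunoinformatics pipeline for position-specific scoring
    matrix (PSSM) based prediction of HLA class II restricted T-cell
    epitopes and for the statistical analysis of the wet-lab assays used to
    validate them. Protein sequences are parsed into overlapping 9-mer
    frames and scored against per-allele coefficient matrices; raw scores
    are Z-normalized against a random-peptide background so that scores are
    comparable across alleles. Frames binding many alleles at once
    (EpiBars) and dense 12-25 residue epitope clusters are detected and
    scored. Downstream modules compute subject-individualized epitope
    measures (iTEM) restricted to a subject's HLA-DRB1 alleles, fit
    four-parameter logistic competition-binding curves to extract IC50
    values with censoring, and implement a two-step IFN-gamma ELISpot
    analysis with dual positivity criteria, per-peptide suppression calls,
    and cohort summaries. A synthetic-data module generates scoring
    matrices, proteins with planted epitope clusters, dilution series, and
    ELISpot datasets with known ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
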