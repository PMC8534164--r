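Package: oncophylo
Title: Tumor Evolution Analysis for Multi-Lesion Cancer Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs tumor evolution from multi-lesion somatic variant
    calls. Implements a somatic variant filter cascade (population allele
    frequency, common-SNP exclusion with ClinVar rescue, per-strand read
    support, variant allele fraction), driver pathogenicity classification,
    tumor mutational burden, directional copy-number filtering for oncogenes
    and tumor suppressors, 96-trinucleotide mutational-signature refitting by
    forward selection with hierarchical clustering of exposures,
    truncal/shared/private clonality partitioning, and exact maximum-parsimony
    phylogenies rooted on the matched normal with nonparametric bootstrap
    support. A synthetic multi-region cohort generator with known clonal
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
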