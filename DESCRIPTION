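Package: cocomplex
Title: Evaluating Co-Complex Protein Pairs from Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies putative co-complex protein pairs from Gene Ontology
    and InterPro annotations. A protein pair is represented by the cross
    product of the two proteins' annotation term sets (optionally closed over
    is_a/part_of ancestors), and scored with a Generalized Iterative Scaling
    maximum-entropy model, a Tanimoto-normalized linear-kernel support vector
    machine, a stacked maximum-entropy ensemble, or l2-norm multiple kernel
    learning. Includes training-set construction from complex catalogues
    (matrix and spoke expansion, homology transfer, constrained negative
    sampling), a repeated stratified hold-out evaluation protocol with
    standard classification metrics, and a fully seeded synthetic-data
    generator emulating every input format (OBO, GAF, InterPro TSV, complex
    and homolog tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    Matrix,
    igraph,
    e1071,
    jsonlite,
    ggplot2,
    methods,
    generics,
    digest,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
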