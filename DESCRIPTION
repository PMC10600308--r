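Package: pasl
Title: Pathway Activity Score Learning for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised dimensionality reduction for gene-expression
    matrices in which the learned dictionary atoms are constrained to known
    genesets (pathways), so that the latent coordinates are interpretable as
    pathway activity scores. Implements a greedy inference phase that orders
    genesets by Box-Cox size-normalized explained variance and extracts
    geneset-restricted principal components with deflation, a discovery phase
    of cardinality-constrained sparse principal components on the residual,
    out-of-sample projection via the dictionary pseudo-inverse, explained
    variance accounting with a column-permuted random-projection baseline,
    and permutation-based differential activation analysis between two
    sample classes. Includes a planted-model simulator for validation, GMT
    geneset input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
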