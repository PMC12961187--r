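Package: mitobarcode
Title: High-Resolution Taxonomic Assignment for Fish Mitochondrial Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fish environmental-DNA metabarcoding data from
    any mitochondrial marker. Curates reference databases of mitochondrial gene
    sequences with per-region (100 bp chunk) validation of taxonomy labels,
    flagging heterospecific (chimeric) segments; builds a clustered non-target
    background database; generates amplicon sequence variants from short
    accurate reads (dereplication plus abundance-skew denoising) or from noisy
    long reads (greedy 97 percent-identity clustering with consensus calling);
    assigns each variant to a species, an indistinguishable species complex, a
    higher taxon, or a non-fish source using a recursive top-hit search with a
    sensitive fallback, binomial-name and heterospecific-region filtering; and
    assembles multi-sample result matrices with positive/negative-control and
    single-replicate badges, habitat and occurrence annotation, and CSV export.
    A synthetic-fixture generator with known ground truth supports fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
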