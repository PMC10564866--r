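Package: repgut
Title: Intestinal and Blood B-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immunoglobulin heavy-chain repertoires from
    paired gut mucosal and peripheral blood samples: paired-end amplicon read
    merging, germline V/J assignment with BLAST-style E-values, CDR-H3
    extraction, quality filtering, somatic hypermutation counting, 99 percent
    identity dereplication, clonal family inference, single-nucleotide mutation
    networks, group-wise repertoire feature statistics (Fisher exact, Welch t,
    Benjamini-Hochberg), blood-gut clone sharing detection, and polyreactivity
    scoring from ELISA and protein-microarray readouts. Includes a synthetic
    V(D)J repertoire and read simulator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    mclust,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
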