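Package: mrgcn
Title: Mutual-Rank Gene Co-Expression Networks with Promoter Motif and
    Duplication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds mutual-rank (MR) gene co-expression networks from
    expression matrices and extracts gene-centric top-k clusters; tests
    clusters for over-representation of hierarchical functional categories
    and of cis-regulatory-element (CRE) containing promoters with
    Benjamini-Hochberg FDR control; scans promoters for degenerate IUPAC
    motifs and ranks them by a transcription-start-site position-bias
    Z-score; classifies gene duplication modes (singleton, dispersed,
    proximal, tandem, segmental) from gene positions and homology hits
    using collinear-block chaining. Includes a synthetic-data generator
    that plants co-expressed modules, position-biased promoter motifs,
    enriched annotation categories and duplication events with known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
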