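Package: hubdiag
Title: Hub Target Diagnosis from Paired Tumor/Control RNA-Seq and a Protein Interactome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts paired tumor/control RNA-seq expression profiles into a
    ranked list of hub protein targets among up-regulated genes, and scores the
    induced protein-protein interaction subnetwork by the Shannon entropy of its
    degree distribution. Implements RPKM, upper-quartile and tuned RPKM_upper
    count normalization with log-flattening transforms, a Gaussian-fit critical
    value threshold for up-regulation, interactome subnetwork construction and
    degree-entropy scoring, hub ranking by interactome connectivity, Welch
    two-sample statistics for cohort comparison, and entropy-versus-survival
    regression for validating normalization choices. Includes a synthetic-data
    generator producing scale-free interactomes and cohorts with known injected
    up-regulation for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
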