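Package: skimploid
Title: Genome-Skimming Phylogenomics of Allopolyploid Origins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving the parental origins of allopolyploid plants
    from low-coverage (genome-skimming) short-read data. Reads are partitioned
    into genomic compartments (chloroplast, mitochondrial, satellite DNA,
    ribosomal DNA, dispersed repeats, total), satellite and repeat content is
    quantified and compared across species, and alignment-free (shared k-mer)
    as well as alignment-based phylogenies are built per compartment to infer
    maternal and paternal progenitor lineages. Includes a synthetic
    allopolyploid data generator with full ground truth, a de novo assembler
    for high-copy circular organelle genomes, graph-based repeat clustering,
    tandem-repeat (satellite) detection, and an end-to-end reproducible
    pipeline with a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
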