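Package: gwasgrid
Title: Binned Transposed Manhattan Plots for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Renders genome-wide association summary statistics as a
    transposed, binned Manhattan plot. The genome is split into fixed-width
    chunks (rows) and -log10 p-values into fixed-width chunks (columns); the
    resulting count matrix is classified by a configurable rule table that
    flags cells containing low minor-allele-frequency or high-impact
    variants, a Benjamini-Hochberg false-discovery-rate boundary separates
    grey background from highlighted cells, and an annotation panel displays
    loci of interest either as a table or as repelled name labels. Includes
    a seeded synthetic-data generator with known ground truth and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    ggplot2,
    patchwork,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
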