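Package: ippr
Title: Interspecies Point Projection of Genomic Coordinates Through Bridging Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps genomic positions between highly diverged genomes by
    interpolating against syntenic anchor points taken from pairwise UCSC
    chain alignments, routing through multiple bridging species when direct
    alignment fails. Projections are classified as directly conserved (DC),
    indirectly conserved (IC) or nonconserved (NC) by their distance to
    anchor points, labelled for conserved functional activity against peak
    files, and ortholog pairs of cis-regulatory elements are compared for
    shared transcription-factor motif content and motif-order shuffling via
    the normalized Kendall tau rank distance with Cohen's d effect sizes.
    Includes a multispecies synthetic genome simulator with ground-truth
    ortholog positions so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
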