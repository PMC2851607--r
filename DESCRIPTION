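Package: cnvrecur
Title: Recurrent Copy-Number Variant Region Detection from Segmented Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies recurrent (common) copy-number variant regions across
    multiple individuals from segmented, confidence-scored CNV calls such as
    those produced by SNP-array callers. Implements two per-probe statistics:
    a count of overlapping high-confidence calls (COVER) and a
    confidence-weighted sum over all overlapping calls (COMPOSITE), with
    common regions extracted as maximal runs of consecutive probes above a
    threshold. Common regions can be refined into subregions by hierarchical
    clustering of supporting calls on Jaccard overlap dissimilarity
    (CLUSTER). Includes Hardy-Weinberg equilibrium testing of copy-number
    genotypes for threshold tuning, concordance evaluation against reference
    CNV lists, group-association tests with false discovery rate control,
    principal component analysis of copy-number profiles, and a seedable
    simulator of segmented call tables with planted recurrent loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
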