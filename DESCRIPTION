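Package: pleioaudit
Title: Pleiotropy Audit of Candidate Gene-Editing Targets from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit the pleiotropic footprint of a single genetic
    variant (such as the CCR5-delta32 deletion) across a panel of binary
    disease phenotypes using publicly released GWAS summary statistics.
    Transforms observed-scale linear-model effects on 0/1 outcomes to odds
    ratios using disease prevalence and allele frequency, fits a symmetric
    three-component Gaussian mixture to association Z scores by maximum
    likelihood with bootstrap inference, computes directional enrichment and
    Benjamini-Hochberg FDR summaries, re-analyses genotype contingency
    tables by allele-dose logistic regression, and counts phenome-wide
    associations per SNP as a pleiotropy metric. Includes a synthetic-data
    generator emulating the statistical structure of biobank-scale GWAS
    extracts so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
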