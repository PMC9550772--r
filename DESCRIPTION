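Package: monoallelix
Title: Allele-Specific Expression-State Analysis for F1 Hybrid RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies genes in allele-resolved F1-hybrid bulk and
    single-cell RNA-seq count tables into biallelic, deterministic
    maternal/paternal monoallelic (DeMA) and random autosomal monoallelic
    (RaMA) expression states under allelic dropout; quantifies
    maternal:paternal imbalance, nascent-versus-mature transcript
    discordance, cross-population sharing and allele switching; and
    provides Fisher-exact/Benjamini-Hochberg gene-set enrichment with a
    rank-deviation combined score. A negative-binomial simulator with
    full ground truth makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
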