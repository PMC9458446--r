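Package: mtbsaudit
Title: Diagnostics for Strand and Coverage Bias in Mitochondrial
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Audits bisulfite-sequencing evidence for mitochondrial DNA
    methylation. Provides a generative simulator of bisulfite library
    preparation on circular mtDNA (per-molecule methylation states,
    incomplete conversion, selective degradation of unmethylated
    cytosine-rich fragments), strand-aware per-read methylation calling
    against a circular reference, per-read C-content diagnostics against
    a uniform-coverage null (heavy/light strand coverage bias, cytosine
    coverage bias, observed versus expected per-read C-count
    distributions), and the position-level threshold calling model
    (proportion cutoff plus coverage floor) whose pathological behaviour
    the diagnostics expose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
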