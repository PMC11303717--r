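Package: switchbackdna
Title: Design and Analysis of Switchback DNA Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing and analysing switchback DNA, a
    globally left-handed, parallel-stranded two-strand structure built
    from laterally stacked B-DNA half-turn domains. Provides the
    switchback complement operator alongside the conventional duplex
    (reverse) complement, pair classification and mismatch-variant
    design, screening of short tandem repeat motifs and genomic
    sequence for switchback compatibility, nearest-neighbor
    thermodynamics with a junction (eliminated-stack) correction,
    free-energy/dissociation-constant conversion, Boltzmann melt-curve
    fitting, equilibrium models of strand competition and toehold-less
    displacement, and generation of complete strand sets for
    homodimer/heterodimer switchback constructs and a double-crossover
    (DX) scaffold reporter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
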