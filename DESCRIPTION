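Package: rsaevol
Title: Solvent-Accessibility-Dependent Codon Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood fitting of codon substitution models whose
    parameters depend on the relative solvent accessibility (RSA) of the
    encoded residue. Implements the Goldman-Yang (GY94) and Muse-Gaut (MG94)
    model families with constant, linear, or per-bin RSA dependency for the
    rate ratio omega, the transition-transversion ratio kappa, and the branch
    length t (or the synonymous and nonsynonymous rates alpha and beta),
    fitted to pairwise codon alignments. Provides AIC ranking over all 27
    GY94 parameterizations, likelihood-ratio tests, grouped fits with tied
    parameters across gene classes, per-bin dN/dS under the
    mutational-opportunity and physical-sites definitions, conversion of
    absolute to relative solvent accessibility (including a DSSP output
    reader), and a forward simulator of RSA-structured pairwise alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
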