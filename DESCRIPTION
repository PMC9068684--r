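Package: genomealg
Title: Maximum Likelihood Rearrangement Distances in the Circular Genome Algebra
Version: 0.1.0
Authors@R: person("genomealg", "developers", role = c("aut", "cre"),
    email = "genomealg@example.org")
Description: Models unsigned circular genomes as permutation clouds in the
    genome algebra, the subalgebra of the symmetric group algebra obtained by
    projecting with the normalized sum over a physical symmetry subgroup
    (dihedral by default). Builds symmetry-closed, reversible rearrangement
    models, computes rearrangement path probabilities and likelihood curves
    spectrally via reduced Young-orthogonal representations, and returns the
    maximum likelihood estimate of evolutionary time (or an explicit
    no-finite-MLE flag). A brute-force Markov chain on genome clouds serves
    as an independent oracle for every spectral quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
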