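Package: oemsim
Title: Spiking Circuit Simulator of Odorant Encoding in the Fruit Fly
    Early Olfactory System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end spiking simulation of the first three stages of the
    Drosophila early olfactory system: odorant transduction in the antenna
    (competitive receptor binding of mixtures, co-receptor channel with calcium
    feedback), the antennal lobe with presynaptic and postsynaptic local-neuron
    divisive normalization, and the mushroom body calyx with a random
    projection-neuron to Kenyon-cell expansion under anterior-paired-lateral
    feedback. Neurons are Noisy Connor-Stevens point neurons. Includes synthetic
    odorant-affinity generators, concentration-, claw-count- and mixture-ratio
    sweep experiments, and first-spike-sequence readouts that quantify
    concentration-invariant odorant-identity coding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
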