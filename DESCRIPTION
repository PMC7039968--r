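Package: mbstereo
Title: Stereotypy of Odor Responses in Randomly Wired Mushroom-Body Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies across-individual stereotypy of neural odor responses with the
    pairwise relative distance (PRED) metric and the Pearson-correlation metric, and
    simulates a rectified-linear projection-neuron to Kenyon-cell to output-neuron
    network of the insect mushroom body to study how convergence over random
    connectivity produces stereotyped readout responses. Includes controls, input
    noise, synaptic learning, fixed-input-drive manipulations, sparseness parameter
    sweeps, a convergence-by-randomness grid with a Hill-equation fit, and an exact /
    Monte-Carlo expectation calculator for a binary threshold network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
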