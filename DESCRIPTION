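Package: l23pipe
Title: Dendritic Excitability and Activity Pipelines for Layer-2/3 Pyramidal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable analysis pipelines for studying thalamocortical control of
    layer-2/3 pyramidal neuron excitability: morphological classification of
    broad-tufted (BT) versus slender-tufted (ST) neurons from SWC
    reconstructions with axo-dendritic overlap scoring against laminar afferent
    profiles; detection and classification of NMDA spikes and delayed sustained
    dendritic potentials (DSDPs) in dendritic voltage recordings; a ratiometric
    two-channel calcium-trace correction chain with permutation-based
    modulation statistics; and single-neuron movement decoding with
    time-shifted inferred firing rates and random-forest regression. A
    synthetic-data module generates every input with known ground truth so all
    stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    Rcpp,
    signal,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
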