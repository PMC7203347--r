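Package: stdpwta
Title: Digital STDP Winner-Take-All Networks for Continual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for a hybrid supervised-unsupervised spiking network
    that clusters never-trained image classes on-line without forgetting
    trained ones.  A bank of 16 integer-weight 20x20 convolutional filters
    (class filters and feature filters) turns a 28x28 grayscale image into a
    16-bit binary feature map; a combinational equalization stage maps each
    feature map to a density-equalized 4x4 pattern; and a digital
    winner-take-all spiking layer with 8-bit counter synapses learns the
    patterns by falling-edge spike-timing-dependent plasticity, driven by
    alternating pattern frames and 1-pixel pseudo-random noise frames from a
    4-bit linear feedback shift register.  Lateral inhibition, spike-frequency
    adaptation and neuronal redundancy stabilise the unsupervised clustering.
    Includes synthetic stroke-image and feature-map generators, IDX-format
    readers, incremental per-neuron accuracy bookkeeping, confusion matrices
    and a fully seeded end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
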