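Package: eesnn
Title: Recurrent Convolutional Spiking Neural Networks for Cross-Patient
    Seizure Detection from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a recurrent convolutional spiking neural network of
    leaky integrate-and-fire neurons for detecting epileptic seizures in
    multichannel scalp EEG, with an emphasis on generalization to unseen
    patients. Training is available either by implicit differentiation on
    the network's equilibrium firing-rate state or by surrogate-gradient
    backpropagation through time. The package covers the full cross-patient
    pipeline: EEG ingestion (EDF and CSV), cleaning, downsampling,
    windowing and class-ratio rebalancing; multivariate-Gaussian seizure
    augmentation; adversarial patient-identity confusion training;
    leave-one-out patient-disjoint evaluation with sensitivity,
    specificity, GMean, rebalanced accuracy and AUC; theoretical
    neuromorphic energy estimation from synaptic operation counts; and
    gradient-based saliency maps. A seeded synthetic multi-patient EEG
    generator supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
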