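Package: vitalign
Title: Exemplar-Free Class-Incremental Learning for Vision Transformers
    via Attention-Map Alignment
Version: 0.1.0
Authors@R:
    person("vitalign", "developers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A compact Vision Transformer classifier for plant-disease
    style image recognition, trained class-incrementally without storing
    exemplars of past classes. Forgetting is mitigated by regularizing the
    current model's post-softmax attention distributions toward those of a
    frozen snapshot of the previous stage, using the Total Variation
    distance (with Jensen-Shannon, Hellinger and Bhattacharyya variants).
    Includes the full training engine (finetuning, freezing and
    attention-alignment strategies), continual-learning metrics such as
    Average Accuracy, a deterministic synthetic lesion-texture image
    benchmark, and a command-line interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
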