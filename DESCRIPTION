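Package: mutformer
Title: Convolution-Augmented Protein Language Models for Missense Variant
    Deleteriousness Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the deleteriousness of missense protein
    variants with a convolution-augmented bidirectional transformer
    (protein language model). Provides amino-acid tokenization with
    boundary sentinels, masked-residue pre-training with dynamic
    re-masking, three fine-tuning formulations (per-residue, single
    sequence, paired sequence), fusion of external predictor scores,
    evaluation statistics (ROC, precision-recall-gain, DeLong test,
    corner-threshold specificity), and a synthetic proteome/variant
    generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
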