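Package: radqn
Title: Metaheuristic Radiomics Feature Selection and Deep Q-Learning for
    Glioma Grading and Survival Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reward-driven classification of radiomics feature
    tables. Implements wrapper feature selection with binary-encoded
    Harris Hawks, modified Gorilla Troops and Zebra optimizers, majority-vote
    ensembling with Shapley-value cumulative-threshold refinement, leakage-safe
    grouped and stratified data splitting, MRI-modality feature fusion, an
    episodic classification environment with unit rewards, and a family of
    deep Q-network agents up to a dueling architecture with context-attention
    fusion of the value and advantage streams, trained by experience replay
    with a target network. Includes a synthetic radiomics generator with
    planted class signal for end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
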