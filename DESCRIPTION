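Package: weightask
Title: Mining Weight-Perception Questions from Social Q&A Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying body-weight self-perception in community
    question-and-answer forums. Identifies "Am I <skinny|thin|fat|obese>?"
    inquiries, extracts self-reported age, gender, height and weight from
    free text with a precision-first rule set, classifies actual weight
    status (adult BMI bands; LMS BMI-for-age percentiles for teens),
    estimates stratified future-posting ratios against the pooled asker
    population with Benjamini-Hochberg false-discovery-rate control,
    relates weight inquiries to later bullying-related posts, and links
    askers to county-level obesity prevalence and median income for
    ecological analyses. A fully parameterised synthetic-corpus generator
    with planted effect sizes makes every stage testable end to end
    without access to any proprietary forum data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
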