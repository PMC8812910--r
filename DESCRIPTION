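Package: mmnstream
Title: Simulation and ERP Analysis of Statistical-Learning Triplet Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing auditory statistical-learning
    oddball experiments based on Markov triplet streams. Generates stimulus
    sequences with exact category quotas (standards, statistical deviants,
    location deviants, double deviants), controllable stimulus-onset
    predictability (isochronous versus jittered presentation), cover-task
    targets and familiarity-test trials; characterises the design in
    information-theoretic terms (surprisal, conditional entropy, timing
    entropy); synthesises multichannel scalp EEG with injectable
    event-related potential ground truth for validation by parameter
    recovery; implements a standard preprocessing chain (zero-phase FIR
    low-pass, mastoid re-referencing, gliding-window artifact rejection,
    epoching with cover-task exclusion rules, region-of-interest averaging);
    and fits repeated-measures and mixed-design analyses of variance for
    mismatch negativity contrasts, with tidy accessors and ggplot2
    visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
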