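Package: carematch
Title: Identifying Care-Home Addresses in Routine Health Data
Version: 0.1.0
Authors@R:
    person("carematch", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying care-home residents from free-text
    addresses held in routine healthcare registers. Implements five index
    tests (an institution flag, exact concatenated-address matching,
    postcode matching, a phonetic Phonics score built on Metaphone and
    Soundex encodings, and a Markov word/word-pair naive-Bayes score), a
    complete diagnostic-test-accuracy evaluation framework (two-by-two
    tables, exact Clopper-Pearson confidence intervals, ROC curves, AUROC
    with Wald limits, three cut-off selection rules, prevalence and sample
    size), and a seeded synthetic-data generator emulating a care-home
    registry and population address extracts so the whole pipeline runs
    end-to-end with no confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
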