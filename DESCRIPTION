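Package: actrlba
Title: Estimating ACT-R Declarative Memory Parameters with the Linear
    Ballistic Accumulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps the parameters of ACT-R's declarative memory retrieval
    equation onto a linear ballistic accumulator (LBA) with lognormal
    drift rates, so that chunk activations, the latency factor, and
    non-retrieval time can be estimated from choice/response-time data
    by maximum likelihood.  Provides exact closed-form single-accumulator
    densities, defective race densities for both an independent-start and
    a shared-distance race, simulators for both generative processes,
    multi-start maximum-likelihood fitting with a fixed activation-noise
    scale, trial-table preprocessing for retrieval-practice data, and a
    parameter-recovery simulation study with tidy summaries and plots.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
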