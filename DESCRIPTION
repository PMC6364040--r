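Package: admixring
Title: Circular Visualization of Ancestry Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Displays the ancestry composition of many populations or
    individuals as a circular stacked-bar graph. Each individual is drawn as
    a length-fixed bar partitioned into K colored segments proportional to
    its ancestry fractions (e.g. an ADMIXTURE .Q matrix); every population
    receives the same angular space regardless of its sample size;
    populations are grouped by their representative ancestry (the component
    with the largest mean proportion) and sorted in descending order of that
    proportion, as are individuals within each population. A population of
    interest can be highlighted as a pie chart in the center of the ring.
    Includes readers and writers for the plain-text formats involved, a
    deterministic plot-specification export for reproducibility, a synthetic
    Q-matrix generator based on Dirichlet sampling, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
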