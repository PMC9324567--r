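Package: morphosys
Title: Morphogenetic Tile Self-Assembly Models of Bacterial Growth, Division and Self-Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, continuous-3D-space self-assembly engine in which
    polygonal and rod-shaped tiles carrying glued connectors and protein-like
    transport channels (protions) interact with floating objects through four
    classes of reaction rules (metabolic, creation, destruction, division) to
    grow, divide by septum fission, and self-heal simulated bacterial cells.
    Includes a calibrated bacterial cell model for three species, injury and
    survival experiment drivers, a graph-theoretic self-healing framework on
    configuration-space digraphs (homeostatic-component decomposition, injury
    degree, sustainability, self-healing degree), and growth-kinetics tools
    (doubling time, growth rate, Gompertz and logistic curve fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
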