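Package: fsabm
Title: Agent-Based Simulation of Faecal Sludge Reuse Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-step agent-based models for urban faecal sludge (FS)
    management economics. One model simulates household adoption of Skyloo
    composting toilets driven by business marketing and word-of-mouth on a
    small-world contact network, with loan-financed construction, waiting
    lists and un-adoption; the other simulates the operation of a municipal
    FS disposal site where vacuum-tanker companies, a site guard and farmers
    adapt their behaviour (legal versus illegal disposal, enforcement versus
    bribery, purchase versus theft) through a payoff-learning rule.
    Includes a synthetic household-population generator, a Watts-Strogatz
    network builder, a Monte-Carlo scenario-grid runner with CSV/JSON
    outputs, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
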